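# Seeded generators for exchange-experiment time series and field
# observations with known ground truth. These emulate the laboratory
# designs the fitters were built for: 5% 2H2O incubation media (a huge
# isotopic contrast, so even tiny exchange extents produce tens of permil
# of signal), paired -50 / +110 permil waters for equilibrium bracketing,
# and triplicate-level Gaussian analytical noise applied in delta space
# (measurements are reported as deltas, so that is where the error lives).

#' Simulate a first-order exchange time series
#'
#' Forward model of the approach to equilibrium:
#' F_t = F_e - (F_e - F_i) exp(-k t), converted to delta values with
#' Gaussian noise of sd `noise_sd` (permil) added in delta space.
#'
#' Supply the rate either directly (`k`) or through Arrhenius parameters
#' (`E_A`, `lnA`) evaluated at `temperature_K`. The equilibrium end-member
#' comes from `water_d2H` and `eie` (a [fractionation] or an [eie_curve()]
#' evaluated at the series temperature).
#'
#' @param temperature_K Incubation temperature, K.
#' @param time_s Sampling times, seconds, strictly increasing.
#' @param water_d2H Water d2H, permil VSMOW (constant, excess reservoir).
#'   Use [abundance_to_delta()] to express a 5% 2H2O medium as a delta.
#' @param initial_acetate_d2H Starting acetate d2H, permil VSMOW.
#' @param eie [fractionation] or [eie_curve()] giving the EIE.
#' @param k Rate constant, 1/s; omit when giving `E_A`/`lnA`.
#' @param E_A,lnA Arrhenius parameters (J/mol, ln 1/s).
#' @param noise_sd Analytical sd in permil (default 2, the order of a
#'   triplicate delta-2H sd); 0 for noiseless.
#' @param seed Optional integer for reproducibility.
#' @return An [exchange_series()] with attributes `k_true` and `F_e_true`.
#' @export
#' @examples
#' s <- simulate_exchange_series(473.15, 3600 * (0:24), water_d2H = 110,
#'                               initial_acetate_d2H = -127,
#'                               eie = fractionation(alpha = 0.882),
#'                               k = log(2) / (3 * 3600), noise_sd = 0)
simulate_exchange_series <- function(temperature_K, time_s, water_d2H,
                                     initial_acetate_d2H, eie,
                                     k = NULL, E_A = NULL, lnA = NULL,
                                     noise_sd = 2, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(k)) {
    if (is.null(E_A) || is.null(lnA)) stop("supply k or (E_A, lnA)")
    k <- exp(lnA - E_A / (.R_GAS * temperature_K))
  }
  stopifnot(k > 0)
  if (inherits(eie, "eie_curve")) eie <- eie_at(eie, temperature_K)
  F_e <- equilibrium_abundance(water_d2H, eie)
  F_i <- delta_to_abundance(iso_delta(initial_acetate_d2H))
  F_t <- F_e - (F_e - F_i) * exp(-k * time_s)
  d_t <- abundance_to_delta(F_t)$value
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    d_t <- d_t + stats::rnorm(length(d_t), sd = noise_sd)
    d_t <- pmax(d_t, -999.999)  # keep within the delta domain
  }
  out <- exchange_series(temperature_K, time_s, d_t, water_d2H,
                         sd_permil = if (noise_sd > 0) rep(noise_sd, length(time_s)) else NULL)
  attr(out, "k_true") <- k
  attr(out, "F_e_true") <- F_e
  out
}

#' Simulate a convergence pair of exchange experiments
#'
#' Two series at the same temperature and EIE but with waters of opposite
#' isotopic offset from the acetate (classically -50 and +110 permil):
#' each converges to its own water-specific equilibrium delta, and the
#' apparent acetate--water fractionation of both converges to the same
#' EIE. This is the equilibrium-bracketing design used to validate a
#' calculated EIE experimentally.
#'
#' @param temperature_K Temperature, K.
#' @param time_s Sampling times, seconds.
#' @param waters_d2H Length-2 vector of water deltas, permil (default
#'   c(-50, 110)).
#' @param initial_acetate_d2H Common starting acetate delta, permil.
#' @param eie [fractionation] or [eie_curve()].
#' @param k Rate constant, 1/s.
#' @param noise_sd Permil.
#' @param seed Optional integer.
#' @return List of two [exchange_series()] (`low`, `high`).
#' @export
simulate_convergence_pair <- function(temperature_K, time_s,
                                      waters_d2H = c(-50, 110),
                                      initial_acetate_d2H = -127,
                                      eie, k, noise_sd = 2, seed = NULL) {
  stopifnot(length(waters_d2H) == 2)
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  list(
    low = simulate_exchange_series(temperature_K, time_s, waters_d2H[1],
                                   initial_acetate_d2H, eie, k = k,
                                   noise_sd = noise_sd, seed = seeds[[1]]),
    high = simulate_exchange_series(temperature_K, time_s, waters_d2H[2],
                                    initial_acetate_d2H, eie, k = k,
                                    noise_sd = noise_sd, seed = seeds[[2]])
  )
}

#' Simulate a field site observation with a chosen true fractionation
#'
#' The acetate delta is placed at the chosen apparent fractionation from
#' the water (in ratio space) plus Gaussian analytical noise; a downstream
#' clock run recovers the fractionation to within the noise.
#'
#' @param true_epsilon True apparent fractionation, permil.
#' @param water_d2H Water delta, permil VSMOW.
#' @param acetate_conc mol/L.
#' @param temperature_K Site temperature, K.
#' @param noise_sd Permil sd on the acetate delta.
#' @param seed Optional integer.
#' @param site Label.
#' @return A [site_observation()] with attribute `true_epsilon`.
#' @export
simulate_site_observation <- function(true_epsilon, water_d2H, acetate_conc,
                                      temperature_K = 298.15, noise_sd = 2,
                                      seed = NULL, site = "synthetic") {
  d_ac <- equilibrium_partner_delta(iso_delta(water_d2H),
                                    fractionation(epsilon = true_epsilon))$value
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    d_ac <- d_ac + stats::rnorm(1, sd = noise_sd)
  }
  out <- site_observation(site, temperature_K, water_d2H, d_ac, acetate_conc)
  attr(out, "true_epsilon") <- true_epsilon
  out
}

#' Simulate the full multi-temperature experiment campaign
#'
#' Eight incubations matching the laboratory design the Arrhenius fit
#' rests on: triplicates at 60 C sampled over a month, one month-long run
#' at 100 C, a week-long and a month-long run at 150 C, and two three-day
#' runs at 200 C sampled hourly at first. Rates come from the supplied
#' Arrhenius parameters; all series share a 5% 2H2O medium except the
#' 200 C pair, which uses natural-abundance waters of -50/+110 permil.
#'
#' @param E_A Activation energy, J/mol.
#' @param lnA ln pre-exponential factor (1/s).
#' @param eie [eie_curve()] used at each temperature.
#' @param noise_sd Permil (0 for noiseless).
#' @param seed Optional integer.
#' @return List of [exchange_series()].
#' @export
simulate_campaign <- function(E_A, lnA, eie = eie_curve(), noise_sd = 2,
                              seed = NULL) {
  day <- 86400
  medium_5pct <- abundance_to_delta(0.05)$value
  plan <- list(
    list(T = 333.15, t = day * seq(0, 28, by = 4), w = medium_5pct),
    list(T = 333.15, t = day * seq(0, 28, by = 4), w = medium_5pct),
    list(T = 333.15, t = day * seq(0, 28, by = 4), w = medium_5pct),
    list(T = 373.15, t = day * seq(0, 28, by = 4), w = medium_5pct),
    list(T = 423.15, t = day * 0:7, w = medium_5pct),
    list(T = 423.15, t = day * seq(0, 28, by = 4), w = medium_5pct),
    list(T = 473.15, t = 3600 * c(0:6, seq(12, 72, by = 12)), w = -50),
    list(T = 473.15, t = 3600 * c(0:6, seq(12, 72, by = 12)), w = 110)
  )
  lapply(seq_along(plan), function(i) {
    p <- plan[[i]]
    simulate_exchange_series(p$T, p$t, p$w, initial_acetate_d2H = -127,
                             eie = eie, E_A = E_A, lnA = lnA,
                             noise_sd = noise_sd,
                             seed = if (is.null(seed)) NULL else seed + i)
  })
}
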