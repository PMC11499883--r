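# Temperature-dependent equilibrium isotope effect (EIE) between acetate
# methyl-H and water, with brine "salt effect" and Ca-acetate complexation
# corrections. The DFT work that produces beta factors is out of scope:
# anchors (or a beta-factor table) are inputs.

#' Temperature-dependent EIE curve from anchor points
#'
#' Builds a curve of ln(alpha) against 1/T^2 through the supplied anchors.
#' The 1/T^2 form is the standard high-temperature limit of reduced
#' partition function ratios; with the default anchors (-192 permil at
#' 25 C, -108 permil at 250 C) it reproduces the independently calculated
#' 200 C value (alpha = 0.882) to better than 0.001. Between anchors the
#' curve is piecewise linear in 1/T^2; beyond the outermost anchors the
#' nearest segment is extended.
#'
#' @param anchors Data frame with columns `temperature_K` and
#'   `epsilon_permil`; at least two rows at distinct temperatures.
#' @return Object of class `eie_curve` with fields `anchors` and
#'   `form_params` (A, B of ln alpha = A + B/T^2 through the outermost
#'   anchors).
#' @export
#' @examples
#' crv <- eie_curve()
#' eie_at(crv, 473.15)$alpha   # ~0.8826
eie_curve <- function(anchors = default_eie_anchors()) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("temperature_K", "epsilon_permil") %in% names(anchors)))
  if (nrow(anchors) < 2 || anyDuplicated(anchors$temperature_K)) {
    stop("need >= 2 anchors at distinct temperatures")
  }
  if (any(anchors$temperature_K <= 0)) stop("temperatures must be positive (K)")
  ord <- order(1 / anchors$temperature_K^2)
  anchors <- anchors[ord, , drop = FALSE]
  x <- 1 / anchors$temperature_K^2
  y <- log(anchors$epsilon_permil / 1000 + 1)
  n <- length(x)
  B <- (y[n] - y[1]) / (x[n] - x[1])
  A <- y[1] - B * x[1]
  structure(list(anchors = anchors, x = x, y = y, form_params = c(A = A, B = B)),
            class = "eie_curve")
}

#' Default acetate--water EIE anchors
#'
#' The two calculated end-members of the free-acetate/pure-water EIE:
#' -192 permil at 25 C and -108 permil at 250 C.
#'
#' @return Data frame of anchors for [eie_curve()].
#' @export
default_eie_anchors <- function() {
  data.frame(temperature_K = c(298.15, 523.15), epsilon_permil = c(-192, -108))
}

#' Evaluate an EIE curve at a temperature
#'
#' Interpolates ln(alpha) linearly in 1/T^2 through the anchors. Outside
#' the guard range a warning is raised (the parameterization is only
#' trusted where it was anchored and validated).
#'
#' @param curve An [eie_curve()].
#' @param temperature_K Temperature in kelvin.
#' @param guard_range Two-element vector (K); temperatures outside it warn.
#' @return A [fractionation] with the interpolated alpha and epsilon.
#' @export
eie_at <- function(curve, temperature_K, guard_range = c(250, 600)) {
  stopifnot(inherits(curve, "eie_curve"), temperature_K > 0)
  if (temperature_K < guard_range[1] || temperature_K > guard_range[2]) {
    warning(sprintf("EIE extrapolation: %.1f K outside guard range [%g, %g] K",
                    temperature_K, guard_range[1], guard_range[2]))
  }
  xq <- 1 / temperature_K^2
  x <- curve$x; y <- curve$y; n <- length(x)
  if (xq <= x[1]) {
    i <- 1L
  } else if (xq >= x[n]) {
    i <- n - 1L
  } else {
    i <- findInterval(xq, x, rightmost.closed = TRUE)
  }
  slope <- (y[i + 1] - y[i]) / (x[i + 1] - x[i])
  lna <- y[i] + slope * (xq - x[i])
  fractionation(alpha = exp(lna))
}

#' Salt-effect correction to the water beta factor
#'
#' In concentrated CaCl2 brine the effective reduced partition function
#' ratio of water shifts; empirically a 15 permil effect at 25 C for a 3 M
#' brine, applied as beta_brine = 1.015 x beta_water. The multiplier is
#' temperature-independent here (the 25 C value is applied throughout); a
#' warning flags use away from 298.15 K.
#'
#' @param beta_water Water beta factor, > 0.
#' @param salt_multiplier Dimensionless multiplier, default 1.015.
#' @param temperature_K Optional; warns when not 298.15 K.
#' @return Brine beta factor.
#' @export
brine_beta <- function(beta_water, salt_multiplier = 1.015, temperature_K = 298.15) {
  if (any(beta_water <= 0) || any(salt_multiplier <= 0)) {
    stop("invalid-beta: beta factors and multipliers must be positive")
  }
  if (!isTRUE(all.equal(temperature_K, 298.15))) {
    warning("salt multiplier is the 25 C value; applied at a different temperature")
  }
  salt_multiplier * beta_water
}

#' EIE between an acetate species and brine water from beta factors
#'
#' alpha = beta_species / (salt_multiplier x beta_water); epsilon follows.
#' Used for both free acetate and the Ca-acetate bidentate complex against
#' a CaCl2 brine. Conservatively assuming fully Ca-ligated acetate, the
#' complex--brine EIE at 25 C is -167 permil, ~25 permil less negative
#' than the free-acetate/pure-water value.
#'
#' @param beta_species Beta factor of the acetate species (free or
#'   complexed), > 0.
#' @param beta_water Beta factor of pure water, > 0.
#' @param salt_multiplier Brine correction, default 1.015 (set to 1 for
#'   pure water).
#' @param temperature_K Passed to [brine_beta()] for the off-25 C warning.
#' @return A [fractionation].
#' @export
#' @examples
#' complex_brine_eie(beta_species = 0.8455, beta_water = 1)$epsilon  # ~ -167
complex_brine_eie <- function(beta_species, beta_water, salt_multiplier = 1.015,
                              temperature_K = 298.15) {
  if (any(beta_species <= 0)) stop("invalid-beta: beta factors must be positive")
  bb <- brine_beta(beta_water, salt_multiplier, temperature_K)
  fractionation(alpha = beta_species / bb)
}

#' Build an EIE curve from a beta-factor table
#'
#' When per-temperature beta factors are available (columns
#' `temperature_K`, `beta_water`, plus `beta_acetate` and/or
#' `beta_ca_acetate`), they take precedence over the two-anchor
#' parameterization: each row becomes an anchor with
#' alpha = beta_species/(salt_multiplier x beta_water).
#'
#' @param betas Data frame as above.
#' @param species `"acetate"` or `"ca_acetate"`.
#' @param salt_multiplier Brine correction; 1 for pure water.
#' @return An [eie_curve()].
#' @export
eie_curve_from_betas <- function(betas, species = c("acetate", "ca_acetate"),
                                 salt_multiplier = 1) {
  species <- match.arg(species)
  col <- paste0("beta_", species)
  stopifnot(all(c("temperature_K", "beta_water", col) %in% names(betas)))
  alpha <- betas[[col]] / (salt_multiplier * betas$beta_water)
  eie_curve(data.frame(temperature_K = betas$temperature_K,
                       epsilon_permil = (alpha - 1) * 1000))
}
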