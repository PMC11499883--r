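# First-order H-exchange kinetics: fit rate constants from incubation time
# series, regress ln k against 1/T (Arrhenius) and extrapolate with a
# +/- 2 RMSD band on ln k.
#
# The fitted model is the classic approach-to-equilibrium form
#   (F_e - F_t)/(F_e - F_i) = exp(-k t)
# in fractional-abundance (mole fraction) space: a linearized
# ln(F_e - F_t) vs t fit for initialization, refined by nonlinear least
# squares in F space. Points within discard_fraction of full equilibration
# are excluded because ln(F_e - F_t) is ill-conditioned near zero.

#' Exchange-experiment time series
#'
#' One incubation: constant temperature, sampled acetate d2H over time,
#' with the water d2H held constant by the excess reservoir.
#'
#' @param temperature_K Incubation temperature, K.
#' @param time_s Sampling times in seconds, strictly increasing, >= 0.
#' @param acetate_d2H Acetate methyl d2H (permil VSMOW) per time point.
#' @param water_d2H Water d2H (permil VSMOW), scalar.
#' @param sd_permil Optional per-point analytical sd (permil).
#' @return Object of class `exchange_series`.
#' @export
exchange_series <- function(temperature_K, time_s, acetate_d2H, water_d2H,
                            sd_permil = NULL) {
  stopifnot(length(temperature_K) == 1, temperature_K > 0)
  if (length(time_s) < 3) stop("need >= 3 time points for fitting")
  if (any(diff(time_s) <= 0) || any(time_s < 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  if (length(acetate_d2H) != length(time_s)) {
    stop("acetate_d2H must match time_s in length")
  }
  if (!is.null(sd_permil) && length(sd_permil) != length(time_s)) {
    stop("sd_permil must match time_s in length")
  }
  # constructor validation of the delta ranges
  iso_delta(acetate_d2H); iso_delta(water_d2H)
  structure(list(temperature_K = temperature_K, time_s = as.numeric(time_s),
                 acetate_d2H = as.numeric(acetate_d2H),
                 water_d2H = as.numeric(water_d2H)[1],
                 sd_permil = sd_permil),
            class = "exchange_series")
}

#' @export
print.exchange_series <- function(x, ...) {
  cat(sprintf("<exchange_series> %.2f K, %d points over %.3g s, water d2H = %g permil\n",
              x$temperature_K, length(x$time_s), max(x$time_s), x$water_d2H))
  invisible(x)
}

#' Equilibrium fractional abundance of acetate methyl-H
#'
#' The equilibrium end-member F_e of the exchange model, from the water's
#' fractional abundance and the equilibrium isotope effect at the series
#' temperature: R_e = alpha x R_water, F_e = R_e/(1 + R_e).
#'
#' @param water_d2H Water delta ([iso_delta] or numeric, permil VSMOW).
#' @param eie [fractionation]: the EIE at the relevant temperature.
#' @return Fractional abundance (scalar).
#' @export
#' @examples
#' equilibrium_abundance(-36, fractionation(epsilon = -192))
equilibrium_abundance <- function(water_d2H, eie) {
  stopifnot(inherits(eie, "fractionation"))
  R_w <- delta_to_ratio(.as_iso_delta(water_d2H))
  ratio_to_abundance(eie$alpha * R_w)
}

#' Fit a first-order exchange rate constant
#'
#' Two-stage fit. First, ordinary least squares of ln(F_e - F_t) on time
#' gives a starting value for k (minus the slope). Second, unless
#' `method = "linearized"` or the data are an exact exponential, the
#' estimate is refined by nonlinear least squares in abundance space,
#' F_t = F_e - A exp(-k t), with the amplitude A and k free and F_e held
#' at its EIE-derived value. The refinement matters: measurement noise is
#' additive in delta (hence, nearly, in F), and the log transform both
#' skews that noise and interacts with the near-equilibrium discard rule
#' to bias the linearized k estimate downward for small-amplitude series.
#'
#' Points within `discard_fraction` of full equilibration (i.e. with
#' |F_e - F_t| < discard_fraction x |F_e - F_i|) are excluded from both
#' stages, as are any points that overshoot F_e; both are counted in
#' `n_discarded`. A series showing no net exchange returns k = 0 with a
#' `"no-exchange"` flag rather than an error.
#'
#' @param series An [exchange_series()].
#' @param F_e Equilibrium fractional abundance (from
#'   [equilibrium_abundance()]).
#' @param discard_fraction Near-equilibrium discard threshold; default
#'   0.05 keeps the logarithm well conditioned.
#' @param method `"nls"` (linearized start + nonlinear refinement, the
#'   default) or `"linearized"` (log-linear OLS only).
#' @return Object of class `rate_fit`: `k` (1/s), `k_stderr`, `F_e_used`,
#'   `F_i`, `n_retained`, `n_discarded`, `flags` (character vector; may
#'   include `"no-exchange"`, `"overshoot"`, `"non-monotonic"`).
#' @export
fit_rate_constant <- function(series, F_e, discard_fraction = 0.05,
                              method = c("nls", "linearized")) {
  stopifnot(inherits(series, "exchange_series"))
  method <- match.arg(method)
  if (!is.numeric(F_e) || F_e <= 0 || F_e >= 1) {
    stop("invalid-abundance: F_e must lie in (0, 1)")
  }
  F_t <- delta_to_abundance(iso_delta(series$acetate_d2H))
  F_i <- F_t[1]
  denom <- F_e - F_i
  if (denom == 0) stop("degenerate series: initial abundance equals F_e")
  frac_remaining <- (F_e - F_t) / denom
  flags <- character()
  near_eq <- frac_remaining < discard_fraction & frac_remaining > 0
  overshoot <- frac_remaining <= 0
  if (any(overshoot)) flags <- c(flags, "overshoot")
  keep <- !near_eq & !overshoot
  n_retained <- sum(keep)
  n_discarded <- sum(!keep)
  if (n_retained < 2) stop("insufficient-data: fewer than 2 points retained")
  t_k <- series$time_s[keep]
  y <- log(frac_remaining[keep])
  if (is.unsorted(rev(y), strictly = FALSE)) flags <- c(flags, "non-monotonic")
  fit <- stats::lm(y ~ t_k)
  slope <- unname(stats::coef(fit)[2])
  se <- tryCatch(suppressWarnings(unname(summary(fit)$coefficients[2, 2])),
                 error = function(e) NA_real_)
  k <- -slope
  if (!is.finite(k) || k <= 0) {
    flags <- unique(c(flags, "no-exchange"))
    return(structure(list(k = max(k, 0), k_stderr = se, F_e_used = F_e,
                          F_i = F_i, n_retained = n_retained,
                          n_discarded = n_discarded,
                          temperature_K = series$temperature_K, flags = flags),
                     class = "rate_fit"))
  }
  if (method == "nls") {
    F_k <- F_t[keep]
    pred <- F_e - denom * exp(-k * t_k)
    # skip refinement when the linearized fit is already exact (noiseless data)
    if (sum((F_k - pred)^2) > (1e-12 * abs(denom))^2) {
      ref <- tryCatch({
        nfit <- suppressWarnings(stats::nls(F_k ~ F_e - A * exp(-kk * t_k),
                           start = list(A = denom, kk = k),
                           control = stats::nls.control(warnOnly = TRUE,
                                                        maxiter = 500)))
        list(k = stats::coef(nfit)[["kk"]],
             se = suppressWarnings(summary(nfit)$coefficients["kk", 2]))
      }, error = function(e) NULL)
      if (!is.null(ref) && is.finite(ref$k) && ref$k > 0) {
        k <- ref$k
        se <- ref$se
      } else {
        flags <- c(flags, "nls-fallback")
      }
    }
  }
  structure(list(k = k, k_stderr = se, F_e_used = F_e, F_i = F_i,
                 n_retained = n_retained, n_discarded = n_discarded,
                 temperature_K = series$temperature_K, flags = flags),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.4g /s (t1/2 = %.4g s), %d kept / %d discarded%s\n",
              x$k, if (x$k > 0) log(2) / x$k else Inf,
              x$n_retained, x$n_discarded,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Half-time of a first-order exchange reaction
#'
#' @param k Rate constant, 1/s; must be positive.
#' @return t1/2 = ln(2)/k, seconds.
#' @export
half_time <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("invalid-rate: k must be positive")
  log(2) / k
}

#' Arrhenius regression of rate constants against temperature
#'
#' Unweighted OLS of ln k on 1/T. E_A = -slope x R_gas, lnA the intercept.
#' Replicate experiments enter as separate points. `rmsd_lnk` is the root
#' mean square residual of ln k, the quantity whose doubled value forms
#' the extrapolation band.
#'
#' @param temperature_K Temperatures, K (>= 2 distinct).
#' @param k Rate constants, 1/s, matched to `temperature_K`.
#' @return Object of class `arrhenius_fit`: `E_A` (J/mol), `lnA`
#'   (ln of 1/s), `rmsd_lnk`, `n_points`, `r_squared`.
#' @export
#' @examples
#' spy <- iso_constants()$seconds_per_year
#' fit_arrhenius(c(473.15, 333.15), c(log(2)/(3*3600), log(2)/(810*spy)))
fit_arrhenius <- function(temperature_K, k) {
  stopifnot(length(temperature_K) == length(k))
  if (length(k) < 2) stop("need >= 2 points")
  if (any(temperature_K <= 0)) stop("temperatures must be positive (K)")
  if (any(k <= 0)) stop("invalid-rate: k must be positive")
  if (length(unique(temperature_K)) < 2) {
    stop("degenerate-regression: all temperatures identical")
  }
  invT <- 1 / temperature_K
  lnk <- log(k)
  fit <- stats::lm(lnk ~ invT)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  r2 <- if (stats::var(lnk) > 0) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(E_A = unname(-cf[2]) * .R_GAS, lnA = unname(cf[1]),
                 rmsd_lnk = sqrt(mean(res^2)), n_points = length(k),
                 r_squared = r2),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> E_A = %.1f kJ/mol, lnA = %.3f, RMSD(ln k) = %.3g, n = %d\n",
              x$E_A / 1000, x$lnA, x$rmsd_lnk, x$n_points))
  invisible(x)
}

#' Extrapolate an Arrhenius fit to a temperature
#'
#' ln k = lnA - E_A/(R_gas T); the uncertainty band is ln k +/- 2 x
#' RMSD(ln k), reproducing the shaded-band convention of an Arrhenius plot
#' rather than a formal prediction interval (a deliberate choice,
#' documented in the methods vignette).
#'
#' @param fit An [arrhenius_fit][fit_arrhenius].
#' @param temperature_K Target temperature, K.
#' @return List `k`, `k_low`, `k_high` (1/s), `ln_k`.
#' @export
extrapolate_rate <- function(fit, temperature_K) {
  stopifnot(inherits(fit, "arrhenius_fit"), temperature_K > 0)
  ln_k <- fit$lnA - fit$E_A / (.R_GAS * temperature_K)
  band <- 2 * fit$rmsd_lnk
  list(k = exp(ln_k), k_low = exp(ln_k - band), k_high = exp(ln_k + band),
       ln_k = ln_k)
}

#' Equilibration time at a temperature
#'
#' Full H-isotope equilibration is taken as `n_half_times` (default 4)
#' half-times of the extrapolated rate: after 4 half-times less than
#' 1/16 of the initial disequilibrium remains.
#'
#' @inheritParams extrapolate_rate
#' @param n_half_times Number of half-times defining "equilibrated".
#' @return Seconds.
#' @export
equilibration_time <- function(fit, temperature_K, n_half_times = 4) {
  ex <- extrapolate_rate(fit, temperature_K)
  n_half_times * half_time(ex$k)
}
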