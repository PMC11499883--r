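# Exact arithmetic between delta notation, isotope ratios, fractional
# abundances and fractionation factors. All per-mil arithmetic is done in
# ratio space, never by adding epsilon values: the 5% 2H2O experiments sit
# at enrichments where the first-order approximation drifts badly.

.reference_ratios <- list(
  H = c(VSMOW = 1.5576e-4),
  C = c(VPDB = 1.11802e-2)
)

#' Isotope delta value on a named reference scale
#'
#' Light container for delta-notation isotope values (per mil). `value`
#' may be a vector; `element` and `scale` apply to all of it. Values at or
#' below -1000 permil would imply a non-positive isotope ratio and are
#' rejected.
#'
#' @param value Numeric vector, per mil.
#' @param element `"H"` or `"C"`.
#' @param scale Reference scale; defaults to `"VSMOW"` for H, `"VPDB"` for C.
#' @return An object of class `iso_delta`.
#' @export
#' @examples
#' iso_delta(-142)                 # d2H, VSMOW
#' iso_delta(-27, element = "C")   # d13C, VPDB
iso_delta <- function(value, element = c("H", "C"), scale = NULL) {
  element <- match.arg(element)
  if (is.null(scale)) scale <- names(.reference_ratios[[element]])[1]
  scale <- match.arg(scale, names(.reference_ratios[[element]]))
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("invalid-delta: value must be finite numeric (per mil)")
  }
  if (any(value <= -1000)) {
    stop("invalid-delta: delta must exceed -1000 permil (ratio must be positive)")
  }
  structure(list(value = as.numeric(value), element = element, scale = scale),
            class = "iso_delta")
}

#' @export
print.iso_delta <- function(x, ...) {
  cat(sprintf("<iso_delta> d%s (%s): %s permil\n",
              if (x$element == "H") "2H" else "13C", x$scale,
              paste(signif(x$value, 6), collapse = ", ")))
  invisible(x)
}

.as_iso_delta <- function(x, element = "H", scale = NULL) {
  if (inherits(x, "iso_delta")) x else iso_delta(x, element = element, scale = scale)
}

#' Reference isotope ratio of a standard
#'
#' @param element `"H"` or `"C"`.
#' @param scale Scale name (`"VSMOW"`, `"VPDB"`).
#' @return Rare/abundant isotope ratio of the standard.
#' @export
reference_ratio <- function(element = c("H", "C"), scale = NULL) {
  element <- match.arg(element)
  tab <- .reference_ratios[[element]]
  if (is.null(scale)) scale <- names(tab)[1]
  scale <- match.arg(scale, names(tab))
  unname(tab[[scale]])
}

#' Convert a delta value to an isotope ratio
#'
#' R = R_standard x (delta/1000 + 1). The inverse, [ratio_to_delta()],
#' recovers the delta bit-for-bit.
#'
#' @param d An [iso_delta] (or numeric per mil, taken as d2H VSMOW unless
#'   `element`/`scale` say otherwise).
#' @param R_standard Reference ratio override; defaults to the scale's
#'   standard value from [reference_ratio()].
#' @param element,scale Used only when `d` is bare numeric.
#' @return Numeric isotope ratio(s).
#' @export
#' @examples
#' delta_to_ratio(iso_delta(0))     # exactly R_VSMOW
#' delta_to_ratio(-36)              # 1.50152e-4
delta_to_ratio <- function(d, R_standard = NULL, element = "H", scale = NULL) {
  d <- .as_iso_delta(d, element = element, scale = scale)
  if (is.null(R_standard)) R_standard <- reference_ratio(d$element, d$scale)
  stopifnot(R_standard > 0)
  R_standard * (d$value / 1000 + 1)
}

#' Convert an isotope ratio back to a delta value
#'
#' @inheritParams delta_to_ratio
#' @param R Numeric isotope ratio(s), > 0.
#' @return An [iso_delta].
#' @export
ratio_to_delta <- function(R, R_standard = NULL, element = "H", scale = NULL) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("invalid-ratio: R must be positive")
  element <- match.arg(element, c("H", "C"))
  if (is.null(scale)) scale <- names(.reference_ratios[[element]])[1]
  if (is.null(R_standard)) R_standard <- reference_ratio(element, scale)
  iso_delta((R / R_standard - 1) * 1000, element = element, scale = scale)
}

#' Isotope ratio to fractional abundance of the rare isotope
#'
#' F = R/(1+R), the mole fraction of the rare isotope.
#'
#' @param R Numeric isotope ratio(s), > 0.
#' @return Fractional abundance(s) in (0, 1).
#' @export
#' @examples
#' ratio_to_abundance(1)          # 0.5
#' abundance_to_ratio(0.05)       # 5% 2H2O medium -> R = 0.05263
ratio_to_abundance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("invalid-ratio: R must be positive")
  R / (1 + R)
}

#' @rdname ratio_to_abundance
#' @param F_ab Fractional abundance(s) strictly inside (0, 1).
#' @export
abundance_to_ratio <- function(F_ab) {
  if (any(!is.finite(F_ab)) || any(F_ab <= 0) || any(F_ab >= 1)) {
    stop("invalid-abundance: F must lie strictly in (0, 1)")
  }
  F_ab / (1 - F_ab)
}

#' Delta value to fractional abundance (and back)
#'
#' Convenience composition of [delta_to_ratio()] and
#' [ratio_to_abundance()]; exact round trip.
#'
#' @inheritParams delta_to_ratio
#' @return Fractional abundance(s).
#' @export
delta_to_abundance <- function(d, R_standard = NULL, element = "H", scale = NULL) {
  ratio_to_abundance(delta_to_ratio(d, R_standard, element, scale))
}

#' @rdname delta_to_abundance
#' @param F_ab Fractional abundance(s).
#' @export
abundance_to_delta <- function(F_ab, R_standard = NULL, element = "H", scale = NULL) {
  ratio_to_delta(abundance_to_ratio(F_ab), R_standard, element, scale)
}

#' Fractionation factor between two phases or compounds
#'
#' Stores alpha (ratio of isotope ratios) and epsilon = (alpha - 1) x 1000
#' together; supply exactly one of the two.
#'
#' @param alpha Dimensionless fractionation factor, > 0.
#' @param epsilon Per-mil fractionation, > -1000.
#' @return Object of class `fractionation` with fields `alpha`, `epsilon`.
#' @export
#' @examples
#' fractionation(epsilon = -192)$alpha   # 0.808
fractionation <- function(alpha = NULL, epsilon = NULL) {
  if (is.null(alpha) == is.null(epsilon)) {
    stop("supply exactly one of alpha or epsilon")
  }
  if (is.null(alpha)) alpha <- epsilon / 1000 + 1
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("invalid-fractionation: alpha must be positive")
  }
  structure(list(alpha = alpha, epsilon = (alpha - 1) * 1000),
            class = "fractionation")
}

#' @export
print.fractionation <- function(x, ...) {
  cat(sprintf("<fractionation> alpha = %s, epsilon = %s permil\n",
              paste(signif(x$alpha, 6), collapse = ", "),
              paste(signif(x$epsilon, 6), collapse = ", ")))
  invisible(x)
}

#' Apparent fractionation between two measured delta values
#'
#' alpha = (d_a + 1000)/(d_b + 1000); epsilon = (alpha - 1) x 1000. Both
#' deltas must be on the same element and scale.
#'
#' @param d_a,d_b [iso_delta] values (numerator and denominator phases; for
#'   the acetate--water clock, acetate and water).
#' @return A [fractionation].
#' @export
#' @examples
#' apparent_alpha(iso_delta(-142), iso_delta(-36))$epsilon  # -109.96
apparent_alpha <- function(d_a, d_b) {
  d_a <- .as_iso_delta(d_a); d_b <- .as_iso_delta(d_b)
  if (d_a$element != d_b$element || d_a$scale != d_b$scale) {
    stop("incompatible-scales: deltas must share element and reference scale")
  }
  fractionation(alpha = (d_a$value + 1000) / (d_b$value + 1000))
}

#' Delta value of the partner phase at a given fractionation
#'
#' Inverse of [apparent_alpha()] in its first argument:
#' d_a = alpha x (d_b + 1000) - 1000. Used to form the equilibrium
#' end-member delta of acetate from a water delta and an equilibrium
#' isotope effect.
#'
#' @param d_b [iso_delta] of the reference phase (water).
#' @param frac A [fractionation] (e.g. an EIE).
#' @return [iso_delta] of the partner phase on the same scale.
#' @export
#' @examples
#' equilibrium_partner_delta(iso_delta(-36), fractionation(epsilon = -192))
equilibrium_partner_delta <- function(d_b, frac) {
  d_b <- .as_iso_delta(d_b)
  stopifnot(inherits(frac, "fractionation"))
  iso_delta(frac$alpha * (d_b$value + 1000) - 1000,
            element = d_b$element, scale = d_b$scale)
}
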