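# Activity-corrected reaction energetics and supportable cell densities.
# Activity-model internals (Pitzer/HMW, Debye-Hueckel) are out of scope:
# gamma values are inputs, defaulting to 1.

#' Metabolic reaction with standard free energy
#'
#' @param name Label.
#' @param stoichiometry Named numeric vector of signed coefficients,
#'   negative for reactants (e.g. `c(acetate = -1, sulfate = -1,
#'   bicarbonate = 2, sulfide = 1)`). Coefficients must be nonzero.
#' @param dG0 Standard Gibbs energy of reaction, J/mol, at the stated
#'   temperature/pressure (pressure enters only through this value).
#' @return Object of class `reaction`.
#' @export
reaction <- function(name, stoichiometry, dG0) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  if (any(stoichiometry == 0) || any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometric coefficients must be nonzero and named")
  }
  structure(list(name = name, stoichiometry = stoichiometry, dG0 = dG0),
            class = "reaction")
}

#' Default acetotrophic reactions
#'
#' Acetoclastic sulfate reduction (acetate- + SO4^2- -> 2 HCO3- + HS-;
#' dG0 = -47.6 kJ/mol at 25 C) and acetoclastic methanogenesis
#' (acetate- + H2O -> CH4 + HCO3-; dG0 = -31.0 kJ/mol at 25 C). The dG0
#' values are standard literature defaults; override by constructing a
#' [reaction()] directly or through the site config.
#'
#' @return Named list of two [reaction()] objects.
#' @export
default_reactions <- function() {
  list(
    sulfate_reduction = reaction(
      "sulfate_reduction",
      c(acetate = -1, sulfate = -1, bicarbonate = 2, sulfide = 1),
      dG0 = -47600),
    methanogenesis = reaction(
      "methanogenesis",
      c(acetate = -1, water = -1, methane = 1, bicarbonate = 1),
      dG0 = -31000)
  )
}

#' Species activities from concentrations and activity coefficients
#'
#' a_i = concentration_i x gamma_i. Gammas default to 1 for every species;
#' supply site-specific values (e.g. from an HMW model run elsewhere) as a
#' named vector.
#'
#' @param concentrations Named numeric vector, mol/L, > 0. Water should be
#'   included with its activity (concentration 1, gamma = activity).
#' @param gammas Named numeric vector of activity coefficients; names not
#'   present default to 1.
#' @return Named numeric vector of activities.
#' @export
species_activities <- function(concentrations, gammas = NULL) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  g <- rep(1, length(concentrations))
  names(g) <- names(concentrations)
  if (!is.null(gammas)) {
    if (any(gammas <= 0)) stop("activity coefficients must be positive")
    common <- intersect(names(gammas), names(g))
    g[common] <- gammas[common]
  }
  concentrations * g
}

#' Reaction quotient
#'
#' Q = prod(a_i ^ v_i) over the reaction's species, with activities a_i and
#' signed stoichiometric coefficients v_i.
#'
#' @param rxn A [reaction()].
#' @param activities Named numeric vector (see [species_activities()]);
#'   must cover every species in the reaction.
#' @return Dimensionless Q.
#' @export
#' @examples
#' rxn <- default_reactions()$sulfate_reduction
#' a <- species_activities(c(acetate = 1.3e-3, sulfate = 620e-6,
#'                           bicarbonate = 57e-6, sulfide = 10e-9))
#' reaction_quotient(rxn, a)   # 4.03e-11
reaction_quotient <- function(rxn, activities) {
  stopifnot(inherits(rxn, "reaction"))
  missing <- setdiff(names(rxn$stoichiometry), names(activities))
  if (length(missing)) {
    stop("incomplete-activities: missing species ", paste(missing, collapse = ", "))
  }
  prod(activities[names(rxn$stoichiometry)] ^ rxn$stoichiometry)
}

#' Activity-corrected Gibbs energy
#'
#' dG = dG0 + R_gas x T x ln(Q).
#'
#' @param rxn A [reaction()].
#' @param Q Reaction quotient, > 0.
#' @param temperature_K Temperature, K.
#' @return J/mol.
#' @export
gibbs_energy <- function(rxn, Q, temperature_K = 298.15) {
  stopifnot(inherits(rxn, "reaction"), Q > 0, temperature_K > 0)
  rxn$dG0 + .R_GAS * temperature_K * log(Q)
}

#' Metabolic power density supplied by a turnover rate
#'
#' P = rate (mol/L/s) x |dG| for exergonic reactions; an endergonic
#' reaction supplies no power (P = 0, flagged via the `"endergonic"`
#' attribute).
#'
#' @param turnover_rate_M_yr Acetate turnover rate, mol/L/yr, >= 0.
#' @param dG Gibbs energy, J/mol (negative = exergonic).
#' @return W/L, with attribute `endergonic`.
#' @export
#' @examples
#' log10(power_density(1e-9, -107e3))   # ~ -11.5
power_density <- function(turnover_rate_M_yr, dG) {
  if (turnover_rate_M_yr < 0) stop("turnover rate must be non-negative")
  p <- turnover_rate_M_yr / .SECONDS_PER_YEAR * max(0, -dG)
  attr(p, "endergonic") <- dG > 0
  p
}

#' Supportable cell density over a maintenance-power grid
#'
#' rho = P / ME for each maintenance power: the density at which the
#' supplied power exactly covers every cell's maintenance demand. The
#' default grid, 1e-21 to 1e-17 W/cell in decade steps, spans reported
#' subsurface maintenance-power estimates.
#'
#' @param power_W_L Power supply, W/L, >= 0.
#' @param maintenance_powers_W_cell Grid of per-cell maintenance powers,
#'   W/cell, > 0.
#' @return Named numeric vector, cells/L (names = maintenance powers).
#' @export
supportable_cell_density <- function(power_W_L,
                                     maintenance_powers_W_cell = 10^seq(-21, -17)) {
  if (power_W_L < 0) stop("power must be non-negative")
  if (any(maintenance_powers_W_cell <= 0)) {
    stop("maintenance powers must be positive")
  }
  stats::setNames(power_W_L / maintenance_powers_W_cell,
                  format(maintenance_powers_W_cell, scientific = TRUE))
}

#' Full energetics chain for one reaction at a site
#'
#' @param rxn A [reaction()].
#' @param concentrations,gammas See [species_activities()].
#' @param turnover_rate_M_yr mol/L/yr.
#' @param temperature_K K.
#' @param maintenance_powers_W_cell W/cell grid.
#' @return Object of class `energetics_result`: `Q`, `dG`, `power_W_L`,
#'   `cell_density_per_L`, `cell_density_per_mL`, plus the inputs echoed.
#' @export
run_energetics <- function(rxn, concentrations, gammas = NULL,
                           turnover_rate_M_yr, temperature_K = 298.15,
                           maintenance_powers_W_cell = 10^seq(-21, -17)) {
  a <- species_activities(concentrations, gammas)
  Q <- reaction_quotient(rxn, a)
  dG <- gibbs_energy(rxn, Q, temperature_K)
  P <- power_density(turnover_rate_M_yr, dG)
  rho <- supportable_cell_density(as.numeric(P), maintenance_powers_W_cell)
  structure(list(reaction = rxn$name, dG0 = rxn$dG0, Q = Q, dG = dG,
                 power_W_L = as.numeric(P),
                 endergonic = attr(P, "endergonic"),
                 cell_density_per_L = rho, cell_density_per_mL = rho / 1000,
                 turnover_rate_M_yr = turnover_rate_M_yr,
                 temperature_K = temperature_K,
                 activities = a,
                 maintenance_powers_W_cell = maintenance_powers_W_cell),
            class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, ...) {
  cat(sprintf("<energetics_result> %s: Q = %.3g, dG = %.1f kJ/mol, log10 P = %s W/L\n",
              x$reaction, x$Q, x$dG / 1000,
              if (x$power_W_L > 0) sprintf("%.2f", log10(x$power_W_L)) else "-Inf"))
  cat(sprintf("  cells/mL over ME grid: %s\n",
              paste(signif(x$cell_density_per_mL, 2), collapse = ", ")))
  invisible(x)
}
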