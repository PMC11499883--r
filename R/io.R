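# Plain-text IO: CSV time series, CSV site tables, JSON configs.

#' Read an exchange time series from CSV
#'
#' Expected columns: `time_s`, `acetate_d2H_permil`, optionally
#' `sd_permil`; header row mandatory. Experiment metadata (temperature,
#' water delta) lives in a sidecar config or is passed here.
#'
#' @param path CSV file path.
#' @param temperature_C Incubation temperature, Celsius.
#' @param water_d2H Water d2H, permil VSMOW.
#' @return An [exchange_series()].
#' @export
read_exchange_csv <- function(path, temperature_C, water_d2H) {
  df <- utils::read.csv(path)
  req <- c("time_s", "acetate_d2H_permil")
  if (!all(req %in% names(df))) {
    stop("exchange CSV must have columns ", paste(req, collapse = ", "))
  }
  exchange_series(celsius_to_kelvin(temperature_C), df$time_s,
                  df$acetate_d2H_permil, water_d2H,
                  sd_permil = df$sd_permil)
}

#' Write an exchange time series to CSV
#'
#' @param series An [exchange_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exchange_csv <- function(series, path) {
  stopifnot(inherits(series, "exchange_series"))
  df <- data.frame(time_s = series$time_s,
                   acetate_d2H_permil = series$acetate_d2H)
  if (!is.null(series$sd_permil)) df$sd_permil <- series$sd_permil
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read site observations from CSV
#'
#' Expected columns: `site`, `temperature_C`, `water_d2H`, `acetate_d2H`,
#' `acetate_conc_M`, optionally `acetate_d13C`. Rows sharing a site label
#' are merged into one observation with a vector of acetate deltas.
#'
#' @param path CSV file path.
#' @return List of [site_observation()].
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("site", "temperature_C", "water_d2H", "acetate_d2H", "acetate_conc_M")
  if (!all(req %in% names(df))) {
    stop("site CSV must have columns ", paste(req, collapse = ", "))
  }
  lapply(split(df, df$site), function(g) {
    site_observation(g$site[1], celsius_to_kelvin(g$temperature_C[1]),
                     g$water_d2H[1], g$acetate_d2H, g$acetate_conc_M[1],
                     acetate_d13C = g$acetate_d13C)
  })
}

#' Read a beta-factor table from CSV
#'
#' Columns: `temperature_K`, `beta_water`, and `beta_acetate` and/or
#' `beta_ca_acetate`. See [eie_curve_from_betas()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_beta_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("temperature_K", "beta_water") %in% names(df))) {
    stop("beta table must have columns temperature_K, beta_water")
  }
  df
}

#' Read a site configuration (JSON)
#'
#' Structured per-site configuration: deltas, concentrations, reactions
#' with dG0 values, radiolysis constants, EIE anchors. Missing required
#' keys are enumerated in a single error.
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_site_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  req <- c("site", "temperature_C", "water_d2H", "acetate_d2H", "acetate_conc_M")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) {
    stop("site config missing keys: ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Paths to the shipped reference configurations
#'
#' `"kidd_creek"` and `"birchtree"` hold only the published site values
#' (the Birchtree acetate concentration is a supplementary-sourced
#' placeholder of 0.1 mM, marked in the file).
#'
#' @param name `"kidd_creek"` or `"birchtree"`.
#' @return File path.
#' @export
isoclock_example_config <- function(name = c("kidd_creek", "birchtree")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".json"), package = "isoclock",
              mustWork = TRUE)
}

#' Celsius to kelvin
#'
#' @param temperature_C Celsius.
#' @return Kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15
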