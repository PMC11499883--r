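# Shared fixture builders. Everything is generated in code; no data files.

spy <- function() iso_constants()$seconds_per_year
rgas <- function() iso_constants()$R_gas

# Arrhenius parameters matching a 3 h half-time at 200 C with E_A = 138 kJ/mol
campaign_truth <- function() {
  E_A <- 138000
  lnA <- log(log(2) / (3 * 3600)) + E_A / (rgas() * 473.15)
  list(E_A = E_A, lnA = lnA,
       half_time_25C_s = log(2) / exp(lnA - E_A / (rgas() * 298.15)))
}

# noiseless exponential-approach series from explicit (k, F_i, F_e)
noiseless_series <- function(k, F_i, F_e, time_s, temperature_K = 373.15) {
  F_t <- F_e - (F_e - F_i) * exp(-k * time_s)
  exchange_series(temperature_K, time_s, abundance_to_delta(F_t)$value,
                  water_d2H = 0)
}
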