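# Analytic oracles and frozen reference values shared across tests.

key_wts <- c("ventilation", "gas_prevention_fire", "blasting", "electrician")

# Published per-working-type citation totals and percentage shares of the
# 200-accident study.
frozen_type_totals <- c(ventilation = 82, gas_prevention_fire = 59,
                        blasting = 37, electrician = 22)
frozen_type_shares <- c(ventilation = 41, gas_prevention_fire = 29.5,
                        blasting = 18.5, electrician = 11)

# Published mean correction factors (3 d.p.). The blasting value is the
# formula value; the source table's 1.78 is inconsistent with its own
# revised probabilities.
frozen_cf_3dp <- c(ventilation = 1.376, gas_prevention_fire = 1.391,
                   blasting = 1.378, electrician = 1.376)

# Published revised probabilities (2 d.p.), per working type and behavior.
frozen_revised_2dp <- list(
  ventilation = c(OIW = 0.22, FSD = 0.13, UUD = 0.10, VDP = 0.04, RIW = 0.07),
  gas_prevention_fire = c(OIW = 0.15, FSD = 0.06, UUD = 0.12, VDP = 0.02,
                          WHD = 0.01, MFE = 0.06),
  blasting = c(OIW = 0.06, FSD = 0.03, UUD = 0.09, VDP = 0.01, RIW = 0.01,
               MFE = 0.05),
  electrician = c(OIW = 0.05, FSD = 0.01, UUD = 0.02, VDP = 0.03, RIW = 0.01,
                  PPE = 0.02))

# Direct arithmetic evaluation of the correction factor (independent of the
# package's grouping code path).
oracle_cf <- function(v, w = c(0.2, 0.6, 0.2), slope = 0.0167,
                      intercept = 1.5) {
  intercept - slope * ((w[1] * v[["a"]] + w[2] * v[["b"]] + w[3] * v[["c"]]) +
                         (v[["d"]] + v[["e"]] + v[["f"]]) / 3 +
                         (v[["g"]] + v[["h"]]) / 2)
}

tri_mean_oracle <- function(l, u, m = (l + u) / 2) (l + m + u) / 3
tri_var_oracle <- function(l, u, m = (l + u) / 2) {
  (l^2 + m^2 + u^2 - l * m - l * u - m * u) / 18
}

# Moment propagation for R = (p * F) * I with F linear in independent
# triangular factors and I normal, all independent: the closed-form mean
# and SD of the simulated risk.
oracle_risk_moments <- function(p_raw, profile, hz_mean, hz_sd,
                                w = c(0.2, 0.6, 0.2), slope = 0.0167,
                                intercept = 1.5) {
  wk <- c(w, rep(1 / 3, 3), rep(1 / 2, 2))
  mu <- tri_mean_oracle(profile$lower, profile$upper, profile$mode)
  v <- tri_var_oracle(profile$lower, profile$upper, profile$mode)
  ES <- sum(wk * mu)
  VS <- sum(wk^2 * v)
  EF <- intercept - slope * ES
  VF <- slope^2 * VS
  EP <- p_raw * EF
  VP <- p_raw^2 * VF
  ER <- EP * hz_mean
  ER2 <- (EP^2 + VP) * (hz_mean^2 + hz_sd^2)
  list(mean = ER, sd = sqrt(ER2 - ER^2))
}

# hazard spec lookup helper for fixture-based tests
fixture_hazard_cell <- function(study, wt, bc) {
  hz <- study$hazard[study$hazard$working_type == wt &
                       study$hazard$behavior == bc, ]
  list(mean = hz$mean[1], sd = hz$sd[1])
}

midpoint_values <- function(profile) {
  stats::setNames((profile$lower + profile$upper) / 2, profile$factor)
}
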