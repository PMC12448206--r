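# Shared fixtures: parameter sets and small, quickly simulated designs.

pfos_monkey <- tk_params("pfos_monkey")
pfoa_human <- tk_params("pfoa_human")
pfos_human <- tk_params("pfos_human")
pfhxs_human <- tk_params("pfhxs_human")

# A small 2-group study (one short oral regimen, one IV bolus) for unit
# tests where the full default design would be wastefully slow.
small_design <- function(residual_sd = 0, n_subjects = 2) {
  study_design(
    groups = tibble::tibble(
      route = c("oral", "iv"),
      dose_mg_per_kg = c(0.15, 2),
      regimen = c("daily", "single"),
      duration_weeks = c(4, NA)
    ),
    n_subjects = n_subjects,
    residual_sd = residual_sd
  )
}

# Random valid parameter draws around the PFOS monkey values (log-uniform
# within a factor of 3), used by property-style tests.
random_chem <- function() {
  jitter3 <- function(x) x * 3^stats::runif(1, -1, 1)
  chemical_params(
    bioAv = min(1, jitter3(0.9)),
    VCC = jitter3(0.24),
    Tmc = jitter3(2.5),
    Kt = jitter3(0.004),
    Free = min(1, jitter3(4.5e-3)),
    k12 = jitter3(3.3),
    k21 = jitter3(3.4),
    ka = jitter3(132)
  )
}
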