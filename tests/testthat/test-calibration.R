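toy_dataset <- function() {
  gen_primate_study(pfos_monkey$physio, pfos_monkey$chemical,
                    small_design(residual_sd = 0), seed = 5)
}

test_that("objective is zero at self-consistent predictions", {
  ds <- toy_dataset()
  # replace observations with the package's own predictions
  pred <- predict_pk(ds, pfos_monkey$physio, pfos_monkey$chemical)
  ds$observations$conc_ug_per_mL <- pred$pred_ug_per_mL
  expect_lt(tk_objective(ds, pfos_monkey$physio, pfos_monkey$chemical),
            1e-8)

  # a uniform 10x bias contributes one squared decade per point
  ds$observations$conc_ug_per_mL <- pred$pred_ug_per_mL * 10
  n <- nrow(ds$observations)
  expect_equal(tk_objective(ds, pfos_monkey$physio, pfos_monkey$chemical),
               n, tolerance = 1e-4)
})

test_that("objective matches a naive reimplementation on a toy dataset", {
  ds <- gen_primate_study(pfos_monkey$physio, pfos_monkey$chemical,
                          small_design(residual_sd = 0.2), seed = 13)
  obs5 <- ds$observations[c(1, 5, 9, 30, 44), ]
  ds5 <- pk_dataset(obs5, ds$doses, ds$body_weights)
  got <- tk_objective(ds5, pfos_monkey$physio, pfos_monkey$chemical)

  # independent route: R right-hand side engine, hand-rolled residuals
  naive <- 0
  for (k in seq_len(nrow(obs5))) {
    g <- obs5$group[k]
    dg <- ds$doses[ds$doses$group == g, ]
    bw <- ds$body_weights$bw_kg[ds$body_weights$group == g]
    ph <- pfos_monkey$physio
    ph$BW <- bw
    sim <- simulate_tk(dose_schedule(dg$time_h, dg$route,
                                     dg$dose_mg_per_kg),
                       ph, pfos_monkey$chemical,
                       times = obs5$time_h[k], engine = "r")
    naive <- naive +
      (log10(sim$conc_serum) - log10(obs5$conc_ug_per_mL[k]))^2
  }
  expect_equal(got, naive, tolerance = 1e-4)
})

test_that("objective is order-invariant and additive over datasets", {
  ds <- toy_dataset()
  base <- tk_objective(ds, pfos_monkey$physio, pfos_monkey$chemical)

  perm <- sample(nrow(ds$observations))
  ds_shuf <- pk_dataset(ds$observations[perm, ], ds$doses,
                        ds$body_weights)
  expect_equal(tk_objective(ds_shuf, pfos_monkey$physio,
                            pfos_monkey$chemical), base)

  half <- nrow(ds$observations) %/% 2
  ds_a <- pk_dataset(ds$observations[seq_len(half), ], ds$doses,
                     ds$body_weights)
  ds_b <- pk_dataset(ds$observations[-seq_len(half), ], ds$doses,
                     ds$body_weights)
  expect_equal(
    tk_objective(ds_a, pfos_monkey$physio, pfos_monkey$chemical) +
      tk_objective(ds_b, pfos_monkey$physio, pfos_monkey$chemical),
    base, tolerance = 1e-10)
})

test_that("collinearity index matches a dense linear-algebra oracle", {
  # orthonormal sensitivity columns
  expect_equal(pfastk:::collin_gamma(diag(3)), 1)

  # duplicated column: exact collinearity
  S <- cbind(1:6, (1:6) * 2, stats::rnorm(6))
  expect_gt(pfastk:::collin_gamma(S), 1e6)

  # zero column reported as infinite
  expect_equal(pfastk:::collin_gamma(cbind(1:4, 0)), Inf)

  # random matrix vs direct eigen decomposition
  set.seed(9)
  for (i in 1:5) {
    S <- matrix(stats::rnorm(18), 6, 3)
    Sn <- sweep(S, 2, sqrt(colSums(S^2)), "/")
    oracle <- 1 / sqrt(min(eigen(t(Sn) %*% Sn)$values))
    expect_equal(pfastk:::collin_gamma(S), oracle, tolerance = 1e-10)
  }
})

test_that("collinearity scaling invariance and dataset-level behavior", {
  ds <- toy_dataset()
  S <- pfastk:::sensitivity_matrix(ds, pfos_monkey$physio,
                                   pfos_monkey$chemical,
                                   c("VCC", "Tmc", "Kt"), 1e-3)
  g1 <- pfastk:::collin_gamma(S)
  g2 <- pfastk:::collin_gamma(sweep(S, 2, c(100, 0.01, 7), "*"))
  expect_equal(g1, g2, tolerance = 1e-9)

  # Free is structurally confounded with the resorption parameters
  g_free <- collinearity_index(ds, pfos_monkey$physio,
                               pfos_monkey$chemical,
                               c("Tmc", "Kt", "Free"))
  expect_gt(g_free, 20)

  rep <- collinearity_report(ds, pfos_monkey$physio, pfos_monkey$chemical,
                             params = c("VCC", "Tmc", "Kt", "Free"),
                             sizes = 2:3)
  expect_true(all(c("subset", "size", "gamma", "identifiable") %in%
                    names(rep)))
  expect_equal(nrow(rep), choose(4, 2) + choose(4, 3))
  expect_error(collinearity_index(ds, pfos_monkey$physio,
                                  pfos_monkey$chemical, "VCC"),
               "subset")
})

test_that("fitting with every parameter fixed returns the fixed values", {
  ds <- toy_dataset()
  spec <- fit_spec(pfos_monkey$chemical, free = character(0))
  fit <- tk_fit(ds, spec, pfos_monkey$physio)
  expect_length(fit$estimates, 0)
  expect_equal(fit$ssr,
               tk_objective(ds, pfos_monkey$physio,
                            pfos_monkey$chemical),
               tolerance = 1e-8)
})

test_that("noise-free fits recover the generating parameters", {
  ds <- toy_dataset()
  spec <- fit_spec(pfos_monkey$chemical, free = c("VCC", "Tmc", "Kt"))
  spec$start <- c(VCC = 0.5, Tmc = 1, Kt = 0.01)  # start off-truth
  fit <- tk_fit(ds, spec, pfos_monkey$physio)
  truth <- c(VCC = 0.24, Tmc = 2.5, Kt = 0.004)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates / truth - 1)), 0.01)

  td <- tidy(fit)
  expect_equal(td$term, c("VCC", "Tmc", "Kt"))
  gl <- glance(fit)
  expect_equal(gl$msle, fit$ssr / fit$n_obs)
  expect_equal(unclass(fitted_chem(fit))[c("VCC", "Tmc", "Kt")],
               as.list(fit$estimates))
})

test_that("recovery error shrinks as residual noise shrinks", {
  spec <- fit_spec(pfos_monkey$chemical, free = c("VCC", "Tmc", "Kt"))
  truth <- c(VCC = 0.24, Tmc = 2.5, Kt = 0.004)
  err <- vapply(c(0.2, 0.05, 0), function(sd) {
    ds <- gen_primate_study(pfos_monkey$physio, pfos_monkey$chemical,
                            small_design(residual_sd = sd, n_subjects = 4),
                            seed = 21)
    fit <- tk_fit(ds, spec, pfos_monkey$physio)
    stats::median(abs(fit$estimates / truth - 1))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("fixed-parameter sensitivity reports zero at factor one", {
  ds <- toy_dataset()
  spec <- fit_spec(pfos_monkey$chemical, free = c("VCC", "Tmc", "Kt"))
  base <- tk_fit(ds, spec, pfos_monkey$physio)
  out <- fixed_param_sensitivity(ds, spec, pfos_monkey$physio, "ka",
                                 factors = 1, baseline = base)
  expect_equal(out$pct_change, rep(0, 3), tolerance = 1e-6)
})

test_that("estimates are robust to the absorption rate but not k12/k21", {
  # perturbing ka 100-fold barely moves the estimates; inflating the
  # deep-exchange ratio 100-fold shifts the central volume
  ds <- gen_primate_study(pfos_monkey$physio, pfos_monkey$chemical,
                          small_design(residual_sd = 0.05, n_subjects = 3),
                          seed = 31)
  spec <- fit_spec(pfos_monkey$chemical, free = c("VCC", "Tmc", "Kt"))
  base <- tk_fit(ds, spec, pfos_monkey$physio)
  out <- fixed_param_sensitivity(ds, spec, pfos_monkey$physio, "ka",
                                 factors = 100, baseline = base)
  expect_lt(mean(abs(out$pct_change)), 10)

  sp2 <- spec
  sp2$values$k12 <- spec$values$k12 * 100   # k12/k21 ratio >= 100
  refit <- tk_fit(ds, sp2, pfos_monkey$physio)
  vcc_change <- abs(refit$estimates[["VCC"]] /
                      base$estimates[["VCC"]] - 1) * 100
  expect_gt(vcc_change, 10)
})

test_that("fit metrics follow their closed forms", {
  x <- c(0.5, 1, 3, 10)
  expect_equal(msle(x, x), 0)
  expect_equal(factor_coverage(x, x), 1)

  expect_equal(msle(2 * x, x), log10(2)^2, tolerance = 1e-12)
  expect_equal(factor_coverage(2 * x, x), 1)  # boundary inclusive

  # a uniform half-decade bias sits outside the factor-2 band
  expect_equal(factor_coverage(10^0.5 * x, x), 0)
  expect_equal(msle(10^0.5 * x, x), 0.25, tolerance = 1e-12)

  expect_equal(msle(2 * x, x, base = 2), 1)
  expect_error(msle(c(0, 1), c(1, 1)), "positive")
  expect_error(factor_coverage(1:3, 1:4), "length")
})
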