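test_that("steady-state serum is zero at zero dose and errors below it", {
  expect_equal(steady_state_serum(0, pfoa_human$physio,
                                  pfoa_human$chemical), 0)
  expect_error(steady_state_serum(-1, pfoa_human$physio,
                                  pfoa_human$chemical), "non-negative")
  expect_equal(pod_hed(0, pfoa_human$physio, pfoa_human$chemical), 0)
})

test_that("human PFOA steady state inverts the published hepatic PODs", {
  # the dose associated with a 100 mg/L steady-state serum level
  d100 <- pod_hed(100, pfoa_human$physio, pfoa_human$chemical)
  expect_equal(d100, 2.10e-2, tolerance = 0.005)
  expect_equal(steady_state_serum(d100, pfoa_human$physio,
                                  pfoa_human$chemical), 100,
               tolerance = 1e-10)
  expect_equal(pod_hed(10, pfoa_human$physio, pfoa_human$chemical),
               1.84e-3, tolerance = 0.005)
  expect_equal(pod_hed(36, pfoa_human$physio, pfoa_human$chemical),
               6.86e-3, tolerance = 0.005)
})

test_that("reverse dosimetry is the exact inverse of the steady state", {
  doses <- 10^seq(-9, 2, length.out = 45)
  for (p in list(pfoa_human, pfos_human, pfhxs_human)) {
    css <- steady_state_serum(doses, p$physio, p$chemical)
    back <- pod_hed(css, p$physio, p$chemical)
    expect_lt(max(abs(back / doses - 1)), 1e-10)
    # monotonicity: Css strictly increasing, Css/dose non-increasing
    expect_true(all(diff(css) > 0))
    expect_true(all(diff(css / doses) < 1e-12))
  }
})

test_that("closed-form steady state agrees with long-horizon simulation", {
  set.seed(11)
  for (i in 1:6) {
    chem <- random_chem()
    dose <- 10^stats::runif(1, -6, 0)
    css <- steady_state_serum(dose, pfos_human$physio, chem)
    t_half_h <- half_life(pfos_human$physio, chem,
                          method = "eigenvalue") * 24 * 365.25
    sim <- simulate_tk(NULL, pfos_human$physio, chem,
                       times = 20 * t_half_h,
                       oral_rate = dose * 70 / 24)  # administered, mg/h
    expect_lt(abs(sim$conc_serum / css - 1), 0.005)
  }
})

test_that("pod_hed_table appends human-equivalent doses to a POD table", {
  pods <- tibble::tibble(
    endpoint = c("focal necrosis", "single cell death"),
    pod_mg_per_L = c(10, 100)
  )
  out <- pod_hed_table(pods, pfoa_human$physio, pfoa_human$chemical)
  expect_named(out, c("endpoint", "pod_mg_per_L", "pod_hed_mg_kg_day"))
  expect_equal(out$pod_hed_mg_kg_day,
               pod_hed(c(10, 100), pfoa_human$physio,
                       pfoa_human$chemical))
})

test_that("clearance has the expected limits and monotonicity", {
  # no resorption, free chemical: whole-body clearance equals Qfil
  chem <- pfos_human$chemical
  chem$Tmc <- 0
  chem$Free <- 1
  r <- derive_rates(pfos_human$physio, chem)
  expect_equal(clearance(pfos_human$physio, chem),
               r$Qfil * 1000 * 24 / 70, tolerance = 1e-10)

  # linear-limit clearance invariant under (Tm, Kt) -> (c Tm, c Kt)
  chem2 <- pfos_human$chemical
  chem2$Tmc <- chem2$Tmc * 7
  chem2$Kt <- chem2$Kt * 7
  expect_equal(clearance(pfos_human$physio, pfos_human$chemical),
               clearance(pfos_human$physio, chem2), tolerance = 1e-12)

  # CL(dose) non-decreasing, bounded by the filtration ceiling Qfil*Free
  doses <- 10^seq(-6, 2, length.out = 30)
  cl <- clearance(pfos_human$physio, pfos_human$chemical, dose = doses)
  expect_true(all(diff(cl) > -1e-9))
  r <- derive_rates(pfos_human$physio, pfos_human$chemical)
  ceiling_ml_kg_day <- r$Qfil * pfos_human$chemical$Free * 1000 * 24 / 70
  expect_true(all(cl <= ceiling_ml_kg_day * (1 + 1e-9)))
})

test_that("PFHxS linear-limit clearance computes near 0.07 mL/kg/day", {
  cl <- clearance(pfhxs_human$physio, pfhxs_human$chemical)
  expect_equal(cl, 0.0706, tolerance = 0.01)
})

test_that("half-life methods agree on sub-saturating parameter sets", {
  set.seed(3)
  for (i in 1:4) {
    chem <- random_chem()
    hl_e <- half_life(pfos_human$physio, chem, method = "eigenvalue")
    hl_s <- half_life(pfos_human$physio, chem, method = "terminal_slope")
    expect_lt(abs(hl_s / hl_e - 1), 0.01)
  }
})

test_that("half-life is increasing in Tmc and calibration inverts it", {
  tmcs <- c(0.1, 0.5, 1, 2)
  hl <- vapply(tmcs, function(tm) {
    ch <- pfos_human$chemical
    ch$Tmc <- tm
    half_life(pfos_human$physio, ch, method = "eigenvalue")
  }, 0)
  expect_true(all(diff(hl) > 0))

  target <- 2.0
  tmc <- calibrate_tmc(pfos_human$physio, pfos_human$chemical, target)
  ch <- pfos_human$chemical
  ch$Tmc <- tmc
  expect_equal(half_life(pfos_human$physio, ch), target,
               tolerance = 1e-4)
})

test_that("infeasible half-life targets are refused", {
  # the Tmc = 0 floor for human PFOS parameters is ~0.013 years
  expect_error(
    calibrate_tmc(pfos_human$physio, pfos_human$chemical, 0.001),
    "floor"
  )
})

test_that("human scaling carries parameters and recalibrates Tmc", {
  human <- scale_to_human(pfos_monkey$chemical, target_half_life_years = 2,
                          human_physio = physio_params())
  # everything except Tmc carried over
  for (nm in setdiff(names(unclass(human)), "Tmc")) {
    expect_equal(human[[nm]], pfos_monkey$chemical[[nm]], label = nm)
  }
  expect_equal(half_life(physio_params(), human), 2, tolerance = 1e-4)

  # identity scaling: animal physiology + the animal's own half-life
  hl_animal <- half_life(pfos_monkey$physio, pfos_monkey$chemical)
  same <- scale_to_human(pfos_monkey$chemical, hl_animal,
                         human_physio = pfos_monkey$physio)
  expect_equal(same$Tmc, pfos_monkey$chemical$Tmc, tolerance = 0.01)

  # overrides route for PFOA-style refits
  ov <- scale_to_human(tk_params("pfoa_monkey_bioav90")$chemical,
                       target_half_life_years = 2.7,
                       overrides = list(bioAv = 0.9, Kt = 0.008))
  expect_equal(ov$bioAv, 0.9)
  expect_equal(ov$Kt, 0.008)
})
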