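rates_m <- derive_rates(pfos_monkey$physio, pfos_monkey$chemical)

zero_state <- stats::setNames(numeric(6),
                              c("Agut", "Aprim", "Adeep", "Cfil",
                                "Aurine", "Aunabs"))

test_that("rhs vanishes at the origin and saturates at high filtrate", {
  d0 <- tk_rhs(0, zero_state, rates_m, pfos_monkey$chemical)
  expect_equal(unname(d0), rep(0, 6))

  # Michaelis-Menten limit: with Cfil >> Kt the resorption flux -> Tm
  st <- zero_state
  st["Cfil"] <- 1e6 * pfos_monkey$chemical$Kt
  d <- tk_rhs(0, st, rates_m, pfos_monkey$chemical)
  expect_equal(d[["Aprim"]], rates_m$Tm, tolerance = 1e-5)
})

test_that("rhs conserves mass up to the explicit absorption sink", {
  # counting Vfil*dCfil as amount flux, the state derivatives must sum to
  # oral_rate: filtration, resorption, exchange and the unabsorbed
  # fraction all cancel internally
  set.seed(42)
  for (i in 1:20) {
    st <- zero_state
    st[c("Agut", "Aprim", "Adeep")] <- stats::runif(3, 0, 10)
    st["Cfil"] <- stats::runif(1, 0, 0.1)
    rate <- stats::runif(1, 0, 5)
    chem <- random_chem()
    r <- derive_rates(pfos_monkey$physio, chem)
    d <- tk_rhs(0, st, r, chem, oral_rate = rate)
    total <- d[["Agut"]] + d[["Aprim"]] + d[["Adeep"]] +
      r$Vfil * d[["Cfil"]] + d[["Aurine"]] + d[["Aunabs"]]
    expect_equal(total, rate, tolerance = 1e-10)
  }
})

test_that("empty schedules give identically zero serum", {
  sim <- simulate_tk(dose_schedule(), pfos_monkey$physio,
                     pfos_monkey$chemical, times = c(0, 10, 100))
  expect_equal(sim$conc_serum, rep(0, 3))
  sim2 <- simulate_tk(NULL, pfos_monkey$physio, pfos_monkey$chemical,
                      times = c(0, 10, 100))
  expect_equal(sim2$conc_serum, rep(0, 3))
})

test_that("an IV bolus dilutes instantaneously into the central volume", {
  D <- 2 * pfos_monkey$physio$BW   # mg
  sim <- simulate_tk(dose_schedule(0, "iv", 2), pfos_monkey$physio,
                     pfos_monkey$chemical, times = 1e-4)
  expect_equal(sim$conc_serum, D / rates_m$Vc, tolerance = 1e-3)
})

test_that("mass balance holds for random schedules (property)", {
  set.seed(7)
  for (i in 1:5) {
    n_ev <- sample(1:6, 1)
    sched <- dose_schedule(
      time_h = sort(stats::runif(n_ev, 0, 500)),
      route = sample(c("oral", "iv"), n_ev, replace = TRUE),
      dose = stats::runif(n_ev, 0.01, 2)
    )
    chem <- random_chem()
    r <- derive_rates(pfos_monkey$physio, chem)
    tt <- sort(c(stats::runif(5, 0, 1000), 1000))
    sim <- simulate_tk(sched, pfos_monkey$physio, chem, times = tt)
    total <- sim$Agut + sim$Aprim + sim$Adeep + r$Vfil * sim$Cfil +
      sim$Aurine + sim$Aunabs
    adm <- administered_mass(sched, pfos_monkey$physio, tt)
    expect_lt(max(abs(total - adm) / pmax(adm, 1e-12)), 1e-6)
    expect_true(all(sim$conc_serum >= 0))
    expect_true(all(sim$Cfil >= 0))
  }
})

test_that("all integration engines agree on a mixed schedule", {
  sched <- dose_schedule(c(0, 24, 48, 100), c("oral", "oral", "iv", "oral"),
                         c(0.1, 0.1, 1, 0.2))
  tt <- c(1, 12, 30, 60, 120, 500)
  ref <- simulate_tk(sched, pfos_monkey$physio, pfos_monkey$chemical,
                     times = tt)
  for (eng in c("qss", "ros", "r")) {
    alt <- simulate_tk(sched, pfos_monkey$physio, pfos_monkey$chemical,
                       times = tt, engine = eng,
                       rtol = 1e-8, atol = 1e-12)
    expect_lt(max(abs(alt$conc_serum / ref$conc_serum - 1)), 1e-4,
              label = paste("engine", eng))
  }
})

test_that("continuous oral forcing matches the R-engine cross-check", {
  forc <- cbind(c(0, 100, 200), c(0.5, 1.0, 0.2))
  tt <- c(10, 50, 150, 200)
  a <- simulate_tk(NULL, pfos_monkey$physio, pfos_monkey$chemical,
                   times = tt, oral_rate = forc)
  b <- simulate_tk(NULL, pfos_monkey$physio, pfos_monkey$chemical,
                   times = tt, oral_rate = forc, engine = "r")
  d <- simulate_tk(NULL, pfos_monkey$physio, pfos_monkey$chemical,
                   times = tt, oral_rate = forc, engine = "ros",
                   rtol = 1e-8, atol = 1e-12)
  expect_equal(a$conc_serum, b$conc_serum, tolerance = 1e-7)
  expect_equal(a$conc_serum, d$conc_serum, tolerance = 1e-5)
})

test_that("with no resorption and full filtration, clearance is Qfil", {
  # Tm = 0, Free = 1: terminal slope = Qfil / Vc_eff,
  # Vc_eff = Vc * (1 + k12/k21) with the deep pool equilibrated; the
  # lumped-volume limit requires exchange fast against elimination, so
  # the exchange rates are scaled up while keeping their ratio
  chem <- pfos_monkey$chemical
  chem$Tmc <- 0
  chem$Free <- 1
  chem$k12 <- chem$k12 * 100
  chem$k21 <- chem$k21 * 100
  chem <- do.call(chemical_params, unclass(chem))
  r <- derive_rates(pfos_monkey$physio, chem)
  vc_eff <- r$Vc * (1 + chem$k12 / chem$k21)
  t_half_expected <- log(2) * vc_eff / r$Qfil / (24 * 365.25)
  t_half_sim <- half_life(pfos_monkey$physio, chem)
  expect_lt(abs(t_half_sim / t_half_expected - 1), 0.02)
})

test_that("doubling Tm and Kt together leaves low-dose kinetics unchanged", {
  chem2 <- pfos_monkey$chemical
  chem2$Tmc <- chem2$Tmc * 2
  chem2$Kt <- chem2$Kt * 2
  chem2 <- do.call(chemical_params, unclass(chem2))
  sched <- dose_schedule(0, "oral", 1e-6)  # far below saturation
  tt <- c(1, 24, 240, 2400)
  a <- simulate_tk(sched, pfos_monkey$physio, pfos_monkey$chemical,
                   times = tt)
  b <- simulate_tk(sched, pfos_monkey$physio, chem2, times = tt)
  expect_equal(a$conc_serum, b$conc_serum, tolerance = 1e-5)
})

test_that("solver reports failure rather than silently returning", {
  # an absurd forcing discontinuity density cannot break the interface:
  # instead check the error path via an unsorted times precondition
  expect_error(
    simulate_tk(NULL, pfos_monkey$physio, pfos_monkey$chemical,
                times = c(10, 1)),
    "unsorted|sorted|times"
  )
})
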