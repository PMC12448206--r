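#' Synthetic primate study designs
#'
#' Describes a multi-group primate PK study: dose groups (route, dose,
#' regimen), subjects per group, observation times and a multiplicative
#' lognormal residual error. The default design is shaped like the
#' repeated-dose oral and single IV-bolus cynomolgus-monkey studies used
#' for PFAS model calibration: three oral dose groups (0.03, 0.15 and
#' 0.75 mg/kg/day, spanning the onset of resorption saturation) dosed
#' daily for 26 weeks with sparse sampling through dosing and a one-year
#' recovery period, plus one single 2 mg/kg IV bolus group followed for a
#' year, six subjects each.
#'
#' @param groups A data frame with columns `route` (`"oral"`/`"iv"`),
#'   `dose_mg_per_kg`, `regimen` (`"single"` or `"daily"`) and
#'   `duration_weeks` (dosing duration for daily regimens).
#' @param n_subjects Subjects per group.
#' @param obs_times_h Observation times, h. `NULL` picks a sparse default
#'   per group: every other week during a daily regimen plus washout
#'   samples, or a bolus decay series.
#' @param residual_sd Residual standard deviation, log10 units.
#' @param bw_kg Group body weight, kg (recycled).
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = NULL, n_subjects = 6, obs_times_h = NULL,
                         residual_sd = 0.1, bw_kg = 5) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      route = c("oral", "oral", "oral", "iv"),
      dose_mg_per_kg = c(0.03, 0.15, 0.75, 2),
      regimen = c("daily", "daily", "daily", "single"),
      duration_weeks = c(26, 26, 26, NA)
    )
  }
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("route", "dose_mg_per_kg", "regimen") %in% names(groups)),
            n_subjects >= 1, residual_sd >= 0)
  if (!"duration_weeks" %in% names(groups)) groups$duration_weeks <- NA
  groups$group <- paste0("g", seq_len(nrow(groups)))
  groups$bw_kg <- rep_len(bw_kg, nrow(groups))
  structure(list(groups = groups, n_subjects = n_subjects,
                 obs_times_h = obs_times_h, residual_sd = residual_sd),
            class = "study_design")
}

default_obs_times <- function(route, regimen, duration_weeks) {
  wk <- 24 * 7
  if (regimen == "daily") {
    # biweekly through dosing (just before the day's dose), then a
    # one-year recovery period: the washout through the resorption
    # saturation transition carries most of the affinity information
    c(seq(2, duration_weeks, by = 2) * wk,
      (duration_weeks + c(2, 4, 8, 13, 19, 26, 39, 52)) * wk)
  } else {
    c(1, 6, 24, 72, 24 * c(7, 14, 28, 56, 84, 126, 168, 252, 365))
  }
}

group_schedule <- function(g) {
  if (g$regimen == "daily") {
    sched <- daily_oral_schedule(g$dose_mg_per_kg, g$duration_weeks)
    if (g$route == "iv") sched$route <- "iv"
    sched
  } else {
    dose_schedule(0, g$route, g$dose_mg_per_kg)
  }
}

#' Generate a synthetic primate PK study
#'
#' Simulates the model at a [study_design()]'s observation design under
#' known ("truth") parameters and applies i.i.d. multiplicative lognormal
#' residual error per subject and time point:
#' `serum_obs = serum_pred * 10^e`, `e ~ N(0, residual_sd)`.
#' Deterministic given `seed`; the generating parameters are attached as
#' a `truth` attribute.
#'
#' @param physio,chem Ground-truth parameter objects (`physio$BW` is
#'   overridden by the design's group body weights).
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A [pk_dataset()] with attribute `truth` (list of `physio`,
#'   `chem`, `design`, `seed`).
#' @examples
#' p <- tk_params("pfos_monkey")
#' ds <- gen_primate_study(p$physio, p$chemical, study_design(), seed = 1)
#' ds
#' @export
gen_primate_study <- function(physio, chem, design = study_design(),
                              seed = 1) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  obs_list <- list()
  dose_list <- list()
  for (i in seq_len(nrow(design$groups))) {
    g <- design$groups[i, ]
    sched <- group_schedule(g)
    tt <- design$obs_times_h %||%
      default_obs_times(g$route, g$regimen, g$duration_weeks)
    tt <- sort(unique(tt))
    ph <- physio
    ph$BW <- g$bw_kg
    sim <- simulate_tk(sched, ph, chem, times = tt)
    for (s in seq_len(design$n_subjects)) {
      eps <- stats::rnorm(length(tt), 0, design$residual_sd)
      obs_list[[length(obs_list) + 1L]] <- tibble::tibble(
        subject = sprintf("%s_s%d", g$group, s),
        group = g$group,
        route = g$route,
        time_h = tt,
        conc_ug_per_mL = sim$conc_serum * 10^eps
      )
    }
    dose_list[[i]] <- tibble::tibble(
      group = g$group, time_h = sched$time_h, route = sched$route,
      dose_mg_per_kg = sched$dose
    )
  }
  ds <- pk_dataset(
    observations = dplyr::bind_rows(obs_list),
    doses = dplyr::bind_rows(dose_list),
    body_weights = dplyr::select(design$groups, "group", "bw_kg")
  )
  attr(ds, "truth") <- list(physio = physio, chem = chem, design = design,
                            seed = seed)
  ds
}

#' Synthetic biomonitoring panel designs
#'
#' The default panel mirrors the national survey structure the pipeline
#' consumes: three survey cycles (1999, 2003, 2017) with one serum mean
#' per single year of age over the full adult range 21-79.
#'
#' @param survey_years Survey years of the panel.
#' @param ages Ages sampled in each survey (21-79).
#' @param noise_sd Lognormal noise on cell means, log10 units.
#' @return An object of class `panel_design`.
#' @export
panel_design <- function(survey_years = c(1999, 2003, 2017),
                         ages = 21:79, noise_sd = 0.05) {
  stopifnot(all(ages >= 21), all(ages <= 79), noise_sd >= 0)
  structure(list(survey_years = survey_years, ages = ages,
                 noise_sd = noise_sd),
            class = "panel_design")
}

#' Generate a synthetic biomonitoring panel
#'
#' Simulates population mean serum levels over a (survey year x age) grid
#' from a known intake trajectory via [predict_survey()], then perturbs
#' each cell mean with multiplicative lognormal noise. Standard errors are
#' populated from the noise level by the delta method
#' (`se = mean * noise_sd * ln 10`).
#'
#' @param traj Ground-truth [intake_trajectory()].
#' @param physio,chem Human parameter objects.
#' @param design A [panel_design()].
#' @param seed Integer seed.
#' @return A tibble of biomonitoring records (`survey_year`, `age`,
#'   `mean_serum_ppb`, `se_ppb`) with a `truth` attribute.
#' @export
gen_biomonitoring <- function(traj, physio, chem,
                              design = panel_design(), seed = 1) {
  stopifnot(inherits(design, "panel_design"))
  pred <- predict_survey(traj, physio, chem, design$survey_years,
                         design$ages)
  set.seed(seed)
  eps <- stats::rnorm(nrow(pred), 0, design$noise_sd)
  out <- tibble::tibble(
    survey_year = pred$survey_year,
    age = pred$age,
    mean_serum_ppb = pred$pred_serum_ppb * 10^eps,
    se_ppb = pred$pred_serum_ppb * 10^eps * design$noise_sd * log(10)
  )
  attr(out, "truth") <- list(trajectory = traj, design = design, seed = seed)
  out
}
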