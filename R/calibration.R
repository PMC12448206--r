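#' Pharmacokinetic calibration datasets
#'
#' Bundle serum observations, per-group dosing schedules and per-group
#' body weights into a calibration dataset. Groups share a dosing schedule
#' and (study-average) body weight; subjects within a group contribute
#' independent observations.
#'
#' @param observations Data frame with columns `subject`, `group`,
#'   `route`, `time_h`, `conc_ug_per_mL` (serum concentration; µg/mL is
#'   identical to mg/L).
#' @param doses Data frame with columns `group`, `time_h`, `route`,
#'   `dose_mg_per_kg`.
#' @param body_weights Data frame with columns `group`, `bw_kg`.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(observations, doses, body_weights) {
  observations <- tibble::as_tibble(observations)
  doses <- tibble::as_tibble(doses)
  body_weights <- tibble::as_tibble(body_weights)
  stopifnot(
    all(c("subject", "group", "route", "time_h", "conc_ug_per_mL") %in%
          names(observations)),
    all(c("group", "time_h", "route", "dose_mg_per_kg") %in% names(doses)),
    all(c("group", "bw_kg") %in% names(body_weights))
  )
  if (!all(observations$group %in% body_weights$group)) {
    stop("every observation must reference a group with a body weight",
         call. = FALSE)
  }
  if (!all(observations$group %in% doses$group)) {
    stop("every observation must reference a group with a dose schedule",
         call. = FALSE)
  }
  if (any(observations$conc_ug_per_mL < 0)) {
    stop("serum concentrations must be non-negative", call. = FALSE)
  }
  structure(list(observations = observations, doses = doses,
                 body_weights = body_weights),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("<pk_dataset> ", nrow(x$observations), "observations,",
      length(unique(x$observations$subject)), "subjects,",
      nrow(x$body_weights), "groups\n")
  invisible(x)
}

#' Model predictions at the observation design of a dataset
#'
#' Simulates each dose group of a `pk_dataset` at its observed time points
#' and joins the predicted serum concentration onto the observation rows.
#'
#' @param dataset A [pk_dataset()].
#' @param physio A [physio_params()]; its `BW` is replaced per group by the
#'   group body weight.
#' @param chem A [chemical_params()].
#' @param rtol,atol Solver tolerances (the calibration default `1e-6` is
#'   looser than the simulation default; residuals are insensitive at this
#'   level and objective evaluations are several-fold faster).
#' @param engine Simulation engine (see [simulate_tk()]); calibration
#'   defaults to the quasi-steady-state reduction for speed.
#' @return The observation tibble with an added `pred_ug_per_mL` column.
#' @export
predict_pk <- function(dataset, physio, chem, rtol = 1e-6, atol = 1e-9,
                       engine = "ros") {
  obs <- dataset$observations
  pred <- rep(NA_real_, nrow(obs))
  for (g in unique(obs$group)) {
    idx <- which(obs$group == g)
    bw <- dataset$body_weights$bw_kg[match(g, dataset$body_weights$group)]
    ph <- physio
    ph$BW <- bw
    dg <- dataset$doses[dataset$doses$group == g, , drop = FALSE]
    sched <- dose_schedule(dg$time_h, dg$route, dg$dose_mg_per_kg)
    tt <- sort(unique(obs$time_h[idx]))
    sim <- simulate_tk(sched, ph, chem, times = tt, rtol = rtol,
                       atol = atol, engine = engine)
    pred[idx] <- sim$conc_serum[match(obs$time_h[idx], sim$time_h)]
  }
  dplyr::mutate(obs, pred_ug_per_mL = pred)
}

# Precompiled residual evaluator: per-group event tables, solver time
# grids and observation lookups are built once, so repeated objective
# evaluations (optimizer and MCMC loops) reduce to one compiled
# Rosenbrock call per group.
build_residual_fun <- function(dataset, physio, rtol = 1e-6,
                               atol = 1e-9) {
  obs <- dataset$observations
  keep <- obs$conc_ug_per_mL > 0
  if (!all(keep)) {
    message("dropping ", sum(!keep), " non-positive observation(s)")
  }
  groups <- unique(obs$group)
  prep <- lapply(groups, function(g) {
    idx <- which(obs$group == g & keep)
    bw <- dataset$body_weights$bw_kg[match(g, dataset$body_weights$group)]
    dg <- dataset$doses[dataset$doses$group == g, , drop = FALSE]
    dg <- dg[order(dg$time_h), , drop = FALSE]
    tt <- sort(unique(obs$time_h[idx]))
    solve_times <- sort(unique(c(0, tt, dg$time_h[dg$time_h <= max(tt)])))
    list(
      bw = bw,
      ev_time = as.double(dg$time_h),
      ev_var = ifelse(dg$route == "oral", 1L, 2L),
      ev_amt = as.double(dg$dose_mg_per_kg * bw),
      solve_times = as.double(solve_times),
      pick = match(obs$time_h[idx], solve_times),
      log_obs = log10(obs$conc_ug_per_mL[idx])
    )
  })
  n_out <- sum(keep)
  function(chem) {
    out <- numeric(0)
    for (p in prep) {
      ph <- physio
      ph$BW <- p$bw
      r <- derive_rates(ph, chem)
      parms <- c(chem$ka, chem$bioAv, chem$k12, chem$k21, r$Qfil,
                 chem$Free, r$Vc, r$Vfil, r$Tm, chem$Kt)
      m <- .Call("C_rk_sim_qss", p$solve_times, parms, p$ev_time,
                 p$ev_var, p$ev_amt, NULL, as.double(rtol),
                 as.double(atol), PACKAGE = "pfastk")
      conc <- m[p$pick, 2] / r$Vc
      if (any(conc <= 0)) return(rep(1e3, n_out))
      out <- c(out, log10(conc) - p$log_obs)
    }
    out
  }
}

# log10 residual vector (pred - obs); non-positive observations are
# dropped with a message, as censoring is not modeled.
log10_residuals <- function(dataset, physio, chem, rtol = 1e-6,
                            engine = "ros") {
  pred <- predict_pk(dataset, physio, chem, rtol = rtol, engine = engine)
  keep <- pred$conc_ug_per_mL > 0
  if (!all(keep)) {
    message("dropping ", sum(!keep), " non-positive observation(s)")
  }
  if (any(pred$pred_ug_per_mL[keep] <= 0)) {
    return(rep(1e3, sum(keep)))  # penalty: simulation collapsed to zero
  }
  log10(pred$pred_ug_per_mL[keep]) - log10(pred$conc_ug_per_mL[keep])
}

#' Sum-of-squared-log-residuals objective
#'
#' The calibration objective: the sum over observations of squared
#' differences between log10 predicted and log10 observed serum
#' concentrations. Log-scale residuals keep high-dose groups from
#' dominating the fit and match the multiplicative error structure of
#' serum assays.
#'
#' @inheritParams predict_pk
#' @return The scalar sum of squared log10 residuals.
#' @export
tk_objective <- function(dataset, physio, chem, rtol = 1e-6) {
  sum(log10_residuals(dataset, physio, chem, rtol = rtol)^2)
}

#' Fit specifications
#'
#' Declares which of the eight chemical parameters are estimated and which
#' are held fixed, with starting values and (log10-scale) box bounds.
#' The default split mirrors common identifiability findings for PFAS
#' primate data: `VCC`, `Tmc` and `Kt` free; `Free`, `ka`, `k12`, `k21`
#' (and usually `bioAv`) fixed at literature values.
#'
#' @param values A [chemical_params()] (or complete named list) giving the
#'   fixed values and the starting values of the free parameters.
#' @param free Character vector of free parameter names.
#' @param lower,upper Optional named vectors of bounds for free parameters
#'   (natural units); default is start values divided/multiplied by 1e3.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(values, free = c("VCC", "Tmc", "Kt"),
                     lower = NULL, upper = NULL) {
  values <- as.list(values)
  if (!setequal(names(values), chem_param_names())) {
    stop("`values` must cover all 8 chemical parameters", call. = FALSE)
  }
  if (!all(free %in% chem_param_names())) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, chem_param_names()), collapse = ", "),
         call. = FALSE)
  }
  start <- unlist(values[free])
  lo <- start / 1e3
  up <- start * 1e3
  # fraction-type parameters stay physical
  up[names(up) %in% c("bioAv", "Free")] <-
    pmin(up[names(up) %in% c("bioAv", "Free")], 1)
  lo[names(lower)] <- unlist(lower)
  up[names(upper)] <- unlist(upper)
  structure(list(values = values, free = free, start = start,
                 lower = lo, upper = up),
            class = "fit_spec")
}

spec_chem <- function(spec, free_values) {
  v <- spec$values
  v[spec$free] <- as.list(unname(free_values))
  structure(v, class = "chemical_params")
}

#' Fit chemical parameters to a PK dataset
#'
#' Least-squares estimation of the free parameters of a [fit_spec()] in
#' log10-parameter space, minimizing [tk_objective()] with the
#' Levenberg-Marquardt algorithm (`minpack.lm::nls.lm`). Deterministic
#' given the starting point.
#'
#' @param dataset A [pk_dataset()].
#' @param spec A [fit_spec()].
#' @param physio A [physio_params()] (group body weights come from the
#'   dataset).
#' @param rtol Solver tolerance used in objective evaluations.
#' @return An object of class `tk_fit` with elements `estimates` (named
#'   vector), `ssr`, `converged`, `message`, `spec`, `n_obs`.
#' @export
tk_fit <- function(dataset, spec, physio, rtol = 1e-6) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(spec, "fit_spec"))
  if (length(spec$free) == 0L) {
    chem <- spec_chem(spec, numeric())
    ssr <- tk_objective(dataset, physio, chem, rtol = rtol)
    return(structure(list(
      estimates = numeric(), ssr = ssr, converged = TRUE,
      message = "all parameters fixed", spec = spec,
      n_obs = nrow(dataset$observations), physio = physio
    ), class = "tk_fit"))
  }
  rf <- build_residual_fun(dataset, physio, rtol = rtol)
  resid_fun <- function(theta) rf(spec_chem(spec, 10^theta))
  fit <- minpack.lm::nls.lm(
    par = log10(spec$start), fn = resid_fun,
    lower = log10(spec$lower), upper = log10(spec$upper),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-10, epsfcn = 1e-8)
  )
  est <- stats::setNames(10^fit$par, spec$free)
  structure(list(
    estimates = est, ssr = fit$deviance,
    converged = fit$info %in% 1:4, message = fit$message,
    spec = spec, n_obs = length(fit$fvec), physio = physio
  ), class = "tk_fit")
}

#' @export
print.tk_fit <- function(x, ...) {
  cat("<tk_fit> SSR =", signif(x$ssr, 5), "on", x$n_obs, "observations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$estimates)) print(signif(x$estimates, 5))
  invisible(x)
}

#' @export
tidy.tk_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates))
}

#' @export
glance.tk_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, msle = x$ssr / x$n_obs, n_obs = x$n_obs,
                 converged = x$converged)
}

#' Fitted chemical parameters of a fit
#'
#' @param fit A `tk_fit` object.
#' @return A [chemical_params()] combining fixed values and estimates.
#' @export
fitted_chem <- function(fit) {
  stopifnot(inherits(fit, "tk_fit"))
  do.call(chemical_params,
          unclass(spec_chem(fit$spec, fit$estimates[fit$spec$free])))
}

# ---- identifiability ------------------------------------------------------

#' Collinearity index of a parameter subset
#'
#' Identifiability diagnostic from normalized local sensitivities. Each
#' column of the sensitivity matrix holds the finite-difference derivative
#' of log10 predicted serum (at the observation design) with respect to a
#' log10 parameter; columns are normalized to unit Euclidean norm and the
#' index is `gamma = 1 / sqrt(min eigenvalue of t(S) %*% S)`. A subset
#' with `gamma` above the threshold (conventionally 20) cannot be jointly
#' estimated from the design.
#'
#' @inheritParams predict_pk
#' @param subset Character vector (length >= 2) of chemical parameter
#'   names.
#' @param rel_step Finite-difference half-step, log10 units.
#' @return The scalar collinearity index (`Inf` for an exactly
#'   zero-sensitivity column).
#' @export
collinearity_index <- function(dataset, physio, chem, subset,
                               rel_step = 1e-3) {
  stopifnot(length(subset) >= 2)
  S <- sensitivity_matrix(dataset, physio, chem, subset, rel_step)
  collin_gamma(S)
}

#' @rdname collinearity_index
#' @param params Parameter names over which to enumerate subsets.
#' @param sizes Subset sizes to evaluate.
#' @param threshold Identifiability threshold on `gamma`.
#' @return For `collinearity_report()`: a tibble with one row per subset
#'   (`subset`, `size`, `gamma`, `identifiable`).
#' @export
collinearity_report <- function(dataset, physio, chem,
                                params = c("bioAv", "VCC", "Tmc", "Kt",
                                           "Free", "ka"),
                                sizes = 2:length(params), threshold = 20,
                                rel_step = 1e-3) {
  S <- sensitivity_matrix(dataset, physio, chem, params, rel_step)
  rows <- purrr::map(sizes[sizes <= length(params)], function(k) {
    combos <- utils::combn(params, k, simplify = FALSE)
    tibble::tibble(
      subset = purrr::map_chr(combos, paste, collapse = "+"),
      size = k,
      gamma = purrr::map_dbl(combos, ~ collin_gamma(S[, .x, drop = FALSE]))
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, identifiable = .data$gamma <= threshold)
}

sensitivity_matrix <- function(dataset, physio, chem, params, rel_step) {
  base_pred <- function(ch) {
    p <- predict_pk(dataset, physio, ch)
    log10(pmax(p$pred_ug_per_mL, 1e-300))
  }
  S <- vapply(params, function(nm) {
    up <- chem; up[[nm]] <- chem[[nm]] * 10^rel_step
    dn <- chem; dn[[nm]] <- chem[[nm]] * 10^(-rel_step)
    (base_pred(up) - base_pred(dn)) / (2 * rel_step)
  }, numeric(nrow(dataset$observations)))
  colnames(S) <- params
  S
}

collin_gamma <- function(S) {
  norms <- sqrt(colSums(S^2))
  if (any(norms == 0)) return(Inf)
  Sn <- sweep(S, 2, norms, "/")
  ev <- eigen(crossprod(Sn), symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min <= 1e-12) return(Inf)
  1 / sqrt(lam_min)
}

# ---- MCMC -----------------------------------------------------------------

#' Adaptive-Metropolis posterior sampling
#'
#' Random-walk Metropolis in log10-parameter space targeting the posterior
#' implied by independent Gaussian errors on log10 serum concentrations.
#' The error variance is Gibbs-sampled under a vague inverse-gamma prior;
#' the parameter prior is flat (in log10) within the `fit_spec` bounds.
#' The proposal covariance is adapted to the running chain covariance
#' (scaled by 2.38^2/d) after an initial learning phase.
#'
#' @inheritParams tk_fit
#' @param n_iter Number of MCMC iterations.
#' @param seed Integer seed; the chain is reproducible given the seed.
#' @param init Optional named starting values (natural units); defaults to
#'   a point-estimate fit via [tk_fit()].
#' @param burn Burn-in fraction discarded for summaries (default 0.2).
#' @return An object of class `tk_mcmc`: posterior draws (`chain`, natural
#'   units), `sigma` draws, 95% credible intervals, acceptance rate and
#'   split-chain R-hat.
#' @export
tk_mcmc <- function(dataset, spec, physio, n_iter = 5000, seed = 1,
                    init = NULL, burn = 0.2, rtol = 1e-6) {
  stopifnot(length(spec$free) >= 1, n_iter >= 100)
  if (is.null(init)) {
    init <- tk_fit(dataset, spec, physio, rtol = rtol)$estimates
  }
  d <- length(spec$free)
  lo <- log10(spec$lower)[spec$free]
  up <- log10(spec$upper)[spec$free]
  rf <- build_residual_fun(dataset, physio, rtol = rtol)
  ssr_fun <- function(theta) sum(rf(spec_chem(spec, 10^theta))^2)
  set.seed(seed)
  theta <- pmin(pmax(log10(unlist(init[spec$free])), lo), up)
  ssr <- ssr_fun(theta)
  n_res <- length(rf(spec_chem(spec, 10^theta)))
  a0 <- b0 <- 1e-3
  sigma2 <- 1 / stats::rgamma(1, a0 + n_res / 2, b0 + ssr / 2)

  chain <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, spec$free))
  sig <- numeric(n_iter)
  prop_sd <- rep(0.05, d)
  prop_chol <- diag(prop_sd, d)
  accept <- 0L
  for (i in seq_len(n_iter)) {
    cand <- theta + drop(prop_chol %*% stats::rnorm(d))
    if (all(cand >= lo & cand <= up)) {
      ssr_cand <- ssr_fun(cand)
      log_alpha <- (ssr - ssr_cand) / (2 * sigma2)
      if (log(stats::runif(1)) < log_alpha) {
        theta <- cand
        ssr <- ssr_cand
        accept <- accept + 1L
      }
    }
    sigma2 <- 1 / stats::rgamma(1, a0 + n_res / 2, b0 + ssr / 2)
    chain[i, ] <- theta
    sig[i] <- sqrt(sigma2)
    if (i >= 200 && i %% 100 == 0) {
      # Haario-style adaptation on the full history (diminishing, since
      # the running covariance converges)
      cv <- stats::cov(chain[seq_len(i), , drop = FALSE])
      cv <- 2.38^2 / d * cv + 1e-8 * diag(d)
      ch <- tryCatch(chol(cv), error = function(e) NULL)
      if (!is.null(ch)) prop_chol <- t(ch)
    }
  }
  acc_rate <- accept / n_iter
  if (acc_rate < 0.05 || acc_rate > 0.6) {
    warning("MCMC acceptance rate ", signif(acc_rate, 3),
            " outside [0.05, 0.6]; inspect the chain")
  }
  keep <- seq.int(floor(burn * n_iter) + 1L, n_iter)
  post <- 10^chain[keep, , drop = FALSE]
  cri <- tibble::tibble(
    term = spec$free,
    estimate = apply(post, 2, stats::median),
    conf.low = apply(post, 2, stats::quantile, 0.025),
    conf.high = apply(post, 2, stats::quantile, 0.975)
  )
  structure(list(
    chain = post, sigma = sig[keep], cri = cri,
    acceptance_rate = acc_rate,
    rhat = apply(chain[keep, , drop = FALSE], 2, split_rhat),
    n_iter = n_iter, seed = seed, spec = spec
  ), class = "tk_mcmc")
}

split_rhat <- function(x) {
  n <- length(x) %/% 2
  halves <- cbind(x[seq_len(n)], x[seq.int(length(x) - n + 1, length(x))])
  m <- colMeans(halves)
  w <- mean(apply(halves, 2, stats::var))
  b <- n * stats::var(m)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.tk_mcmc <- function(x, ...) {
  cat("<tk_mcmc>", x$n_iter, "iterations, acceptance",
      signif(x$acceptance_rate, 3), ", max R-hat",
      signif(max(x$rhat), 4), "\n")
  print(x$cri)
  invisible(x)
}

#' @export
tidy.tk_mcmc <- function(x, ...) x$cri

#' @export
glance.tk_mcmc <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter,
                 acceptance_rate = x$acceptance_rate,
                 max_rhat = max(x$rhat))
}

# ---- fixed-parameter sensitivity ------------------------------------------

#' Sensitivity of estimates to a fixed parameter
#'
#' Refits the free parameters after perturbing one fixed parameter by each
#' of a set of multiplicative factors, reporting the relative change of
#' every estimate against the baseline fit.
#'
#' @inheritParams tk_fit
#' @param param Name of the fixed parameter to perturb.
#' @param factors Multiplicative perturbation factors.
#' @param baseline Optional precomputed baseline `tk_fit`.
#' @return A tibble with columns `param`, `factor`, `term`, `estimate`,
#'   `baseline`, `pct_change` (and `error` for failed refits).
#' @export
fixed_param_sensitivity <- function(dataset, spec, physio, param,
                                    factors = c(0.01, 0.1, 10, 100),
                                    baseline = NULL, rtol = 1e-6) {
  stopifnot(param %in% names(spec$values), !param %in% spec$free)
  if (is.null(baseline)) baseline <- tk_fit(dataset, spec, physio, rtol = rtol)
  purrr::map_dfr(factors, function(f) {
    sp <- spec
    sp$values[[param]] <- spec$values[[param]] * f
    res <- tryCatch(tk_fit(dataset, sp, physio, rtol = rtol),
                    error = function(e) e)
    base_est <- unname(baseline$estimates)
    if (inherits(res, "error")) {
      return(tibble::tibble(param = param, factor = f,
                            term = spec$free, estimate = NA_real_,
                            baseline = base_est,
                            pct_change = NA_real_,
                            error = conditionMessage(res)))
    }
    est <- unname(res$estimates)
    tibble::tibble(
      param = param, factor = f, term = spec$free,
      estimate = est, baseline = base_est,
      pct_change = 100 * (est / base_est - 1),
      error = NA_character_
    )
  })
}

# ---- fit metrics ----------------------------------------------------------

#' Fit-quality metrics
#'
#' `msle()` is the mean of squared log10 prediction errors;
#' `factor_coverage()` is the fraction of predictions within a
#' multiplicative factor of the observations (boundary inclusive). A
#' uniform 2-fold bias gives `msle = (log10 2)^2 ~ 0.0906` and factor-2
#' coverage 1.
#'
#' @param pred,obs Positive numeric vectors of equal length.
#' @param base Logarithm base for `msle` (default 10).
#' @param factor Coverage factor (default 2).
#' @return A scalar.
#' @export
msle <- function(pred, obs, base = 10) {
  check_pos(pred, obs)
  mean((log(pred, base) - log(obs, base))^2)
}

#' @rdname msle
#' @export
factor_coverage <- function(pred, obs, factor = 2) {
  check_pos(pred, obs)
  ratio <- pred / obs
  mean(ratio >= 1 / factor & ratio <= factor)
}

check_pos <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("`pred` and `obs` must have equal length", call. = FALSE)
  }
  if (any(pred <= 0) || any(obs <= 0)) {
    stop("`pred` and `obs` must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}
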