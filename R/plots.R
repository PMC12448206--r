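#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed-versus-predicted plot for a PK dataset
#'
#' Log-log scatter of predicted against observed serum concentrations,
#' with the identity line and dashed half-log10 bands (the conventional
#' adequacy envelope; a factor of 10^0.5 ~ 3.16).
#'
#' @param dataset A [pk_dataset()].
#' @param physio,chem Parameter objects.
#' @return A ggplot object.
#' @export
plot_obs_pred <- function(dataset, physio, chem) {
  d <- predict_pk(dataset, physio, chem)
  d <- d[d$conc_ug_per_mL > 0 & d$pred_ug_per_mL > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$conc_ug_per_mL,
                                  .data$pred_ug_per_mL,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-0.5, 0.5),
                         linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observed serum (µg/mL)",
                  y = "predicted serum (µg/mL)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tk_mcmc <- function(object, ...) {
  d <- tibble::as_tibble(as.data.frame(object$chain))
  d$iteration <- seq_len(nrow(d))
  d <- tidyr::pivot_longer(d, -"iteration", names_to = "term",
                           values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "parameter value (post burn-in draws)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exposure_fit <- function(object, ...) {
  d <- object$fitted
  d <- tidyr::pivot_longer(d, c("mean_serum_ppb", "pred_serum_ppb"),
                           names_to = "which", values_to = "serum_ppb")
  d$which <- ifelse(d$which == "mean_serum_ppb", "observed", "predicted")
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$serum_ppb,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~survey_year) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "serum (ppb)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.intake_trajectory <- function(object, ...) {
  yrs <- seq(1945, 2025, by = 0.25)
  d <- tibble::tibble(year = yrs, intake = intake_at(object, yrs))
  ggplot2::ggplot(d[d$intake > 0, ],
                  ggplot2::aes(.data$year, .data$intake)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "calendar year",
                  y = "intake (ng/kg BW/day)") +
    ggplot2::theme_minimal()
}
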