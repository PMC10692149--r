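#' Forest plot of SDT coefficients
#'
#' Posterior medians with 95% quantile intervals for the population-level
#' parameters of a fitted SDT model.
#'
#' @param object an `sdt_fit`.
#' @param parameters optional subset of parameter names.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sdt_fit <- function(object, parameters = NULL, ...) {
  td <- tidy(object)
  if (!is.null(parameters)) {
    td <- dplyr::filter(td, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$median,
                                   y = stats::reorder(.data$parameter,
                                                      .data$median))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "posterior median (95% quantile interval)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Valence plot for a calibration fit
#'
#' Expected pro-Left and pro-Right congruence per statement, ordered by the
#' implied political valence.
#'
#' @param object a `zoib_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.zoib_fit <- function(object, ...) {
  cong <- expected_statement_congruence(object)
  long <- cong |>
    dplyr::mutate(valence = political_valence(.data$congR, .data$congL)) |>
    tidyr::pivot_longer(c("congL", "congR"), names_to = "side",
                        values_to = "congruence")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$statement_id,
                                                  .data$valence),
                               y = .data$congruence,
                               colour = .data$side)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(congL = "#2166ac", congR = "#b2182b"),
      labels = c(congL = "pro-Left", congR = "pro-Right")) +
    ggplot2::labs(x = "statement (ordered by valence)",
                  y = "expected congruence", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Recovery scatter: true versus estimated parameters
#'
#' @param object a `recovery_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$true, y = .data$median)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior median (CI95)") +
    ggplot2::theme_minimal()
}

#' Bayes factor against sample size
#'
#' @param object a `power_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.power_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n, y = .data$median_bf10,
                               colour = .data$parameter)) +
    ggplot2::geom_hline(yintercept = object$bf_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample size", y = "median BF10") +
    ggplot2::theme_minimal()
}

#' Posterior-predictive calibration by concordance bin
#'
#' Observed "true"-response rates by political-concordance bin against the
#' posterior-predictive distribution of the same rates.
#'
#' @param fit an `sdt_fit`.
#' @param bins number of concordance bins.
#' @param ndraws posterior draws for the predictive.
#' @param seed optional seed.
#' @return A ggplot object.
#' @export
plot_predictive_calibration <- function(fit, bins = 6, ndraws = 100,
                                        seed = NULL) {
  pp <- posterior_predictive(fit, ndraws = ndraws, seed = seed)
  data <- fit$data
  bin <- cut(data$pol_concord_z, breaks = bins)
  obs <- tapply(data$say_true, bin, mean)
  pred <- apply(pp$yrep, 1, function(y) tapply(y, bin, mean))
  df <- tibble::tibble(
    bin = factor(names(obs), levels = names(obs)),
    observed = as.numeric(obs),
    pred_low = apply(pred, 1, stats::quantile, 0.025, na.rm = TRUE),
    pred_high = apply(pred, 1, stats::quantile, 0.975, na.rm = TRUE),
    pred_mean = rowMeans(pred, na.rm = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$pred_mean,
                                          ymin = .data$pred_low,
                                          ymax = .data$pred_high),
                             colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red") +
    ggplot2::labs(x = "political concordance bin",
                  y = "P(respond 'true')") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
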