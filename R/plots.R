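# ggplot2 displays for study results and fits.

#' Relative-error summary plot for a replicate study
#'
#' Boxplots of the per-replicate relative errors by estimation method,
#' faceted by exposure measure, with a reference line at zero.
#'
#' @param object a `tk_study`.
#' @param measures which measures to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tk_study <- function(object,
                              measures = unique(object$results$measure),
                              ...) {
  df <- object$results |>
    filter(.data$measure %in% measures,
           !is.na(.data$estimate), .data$truth != 0,
           is.na(.data$converged) | .data$converged) |>
    mutate(rel_err = (.data$estimate - .data$truth) / .data$truth * 100)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$rel_err)) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative error (%)",
                  title = object$config$scenario_id) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Goodness-of-fit plot for a FOCE-I fit
#'
#' Observed concentrations against population and individual predictions.
#'
#' @param object a `tk_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tk_fit <- function(object, ...) {
  df <- augment(object) |>
    tidyr::pivot_longer(c(".pred", ".ipred"), names_to = "kind",
                        values_to = "pred")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$dv)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "predicted concentration (mg/ml)",
                  y = "observed concentration (mg/ml)") +
    ggplot2::theme_bw()
}
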