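# Plotting helpers: Kaplan-Meier curves per model and forest plots for
# stratified/multivariate Cox summaries.

#' Kaplan-Meier plot of one model's risk groups
#'
#' @param model_set A `cna_model_set` from [build_all_models()].
#' @param model_id Which model to plot (default: first).
#' @return A ggplot object: survival step curves per risk group.
#' @export
plot_km <- function(model_set, model_id = NULL) {
  ids <- levels(model_set$assignments$model_id)
  if (is.null(model_id)) model_id <- ids[1]
  model_id <- match.arg(model_id, ids)
  labels <- dplyr::filter(model_set$assignments,
                          .data$model_id == !!model_id)$label
  km <- km_curve(model_set$clinical$time, model_set$clinical$event, labels)
  # anchor every curve at (0, 1)
  km0 <- dplyr::bind_rows(
    tibble::tibble(group = unique(km$group), time = 0, surv = 1),
    dplyr::select(km, "group", "time", "surv"))
  ggplot2::ggplot(km0, ggplot2::aes(x = .data$time, y = .data$surv,
                                    color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = "Risk group", title = model_id) +
    ggplot2::theme_minimal()
}

#' Forest plot of stratified or multivariate Cox coefficients
#'
#' Dots mark the log hazard ratio (closed = significant at 0.05, open =
#' not), horizontal lines the 95% confidence interval; non-estimable terms
#' are omitted.
#'
#' @param report A tibble from [stratified_analysis()] (uses
#'   `stratum`/`term`) or [multivariate_cox()] (uses `term`).
#' @return A ggplot object.
#' @export
plot_forest <- function(report) {
  df <- report
  if ("estimable" %in% names(df)) df <- dplyr::filter(df, .data$estimable)
  df <- dplyr::mutate(
    df,
    row = if ("stratum" %in% names(df)) {
      paste(.data$stratum, .data$term, sep = ": ")
    } else .data$term,
    signif = .data$p_value <= 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$row)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$signif), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = expression(beta ~ "(log hazard ratio)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_km
#' @param object A `cna_model_set`.
#' @param ... Passed to [plot_km()].
#' @export
autoplot.cna_model_set <- function(object, ...) plot_km(object, ...)
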