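#' Tidy the eight model reports
#'
#' @param x A `cna_model_set` from [build_all_models()].
#' @param ... Unused.
#' @return One row per model: `model_id`, `algorithm`, `depth`, `n_groups`,
#'   `statistic`, `df`, `p_value`.
#' @export
tidy.cna_model_set <- function(x, ...) {
  dplyr::select(x$reports, "model_id", "algorithm", "depth", "n_groups",
                "statistic", "df", "p_value")
}

#' One-line summary of a model set
#'
#' @param x A `cna_model_set`.
#' @param ... Passed to [rank_models()].
#' @return A one-row tibble: `n_samples`, `n_events`, `n_models`,
#'   `selected_model`, `selected_p`.
#' @export
glance.cna_model_set <- function(x, ...) {
  rk <- rank_models(x, ...)
  sel_p <- if (is.na(rk$selected)) NA_real_ else {
    rk$ranking$p_value[match(rk$selected, rk$ranking$model_id)]
  }
  tibble::tibble(
    n_samples = nrow(x$clinical),
    n_events = sum(x$clinical$event),
    n_models = nrow(x$reports),
    selected_model = rk$selected,
    selected_p = sel_p)
}

#' Write model assignments and reports as plain text
#'
#' Emits `assignments.tsv` (sample, model, label), `model_reports.tsv` and
#' `model_reports.json` (per-model group counts and log-rank tests) into
#' `dir`.
#'
#' @param model_set A `cna_model_set`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_model_set <- function(model_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(assignments = file.path(dir, "assignments.tsv"),
             reports_tsv = file.path(dir, "model_reports.tsv"),
             reports_json = file.path(dir, "model_reports.json"))
  assignments <- dplyr::mutate(model_set$assignments,
                               model_id = as.character(.data$model_id))
  readr::write_tsv(assignments, paths[["assignments"]], progress = FALSE)
  flat <- tidy.cna_model_set(model_set)
  readr::write_tsv(flat, paths[["reports_tsv"]], progress = FALSE)
  full <- purrr::map(seq_len(nrow(model_set$reports)), function(i) {
    r <- model_set$reports[i, ]
    list(model_id = r$model_id, algorithm = r$algorithm, depth = r$depth,
         n_groups = r$n_groups, groups = r$groups[[1]],
         statistic = r$statistic, df = r$df, p_value = r$p_value)
  })
  jsonlite::write_json(full, paths[["reports_json"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
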