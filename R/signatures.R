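# Risk-assignment algorithms: per-sample coefficient sums, single-data
# labels, MaxSum labels, Combinations labels, and the eight-model builder.

.model_ids <- c("single_soft_del", "single_soft_amp", "single_deep_del",
                "single_deep_amp", "maxsum_soft", "maxsum_deep",
                "combinations_soft", "combinations_deep")

# relative-tolerance tie test for coefficient sums
.is_tie <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * pmax(abs(a), abs(b))
}

#' Per-sample coefficient sums for one alteration mode
#'
#' For every sample, sums the screened Cox coefficients of the gene regions
#' the sample carries: `sum_beta_high` adds the coefficients of high-risk
#' genes (beta > 0) and `sum_beta_low` adds the magnitudes `|beta|` of
#' low-risk genes (beta < 0), so both sums are non-negative and directly
#' comparable. A sample carrying no screened alteration scores (0, 0).
#'
#' @param screen A screening tibble from [screen_mode()] for the same mode.
#' @param am The (filtered) `alteration_matrix` the screen was run on.
#' @return A tibble with `sample_id`, `sum_beta_high`, `sum_beta_low`.
#' @export
score_samples <- function(screen, am) {
  stopifnot(all(screen$gene_id %in% am$gene_ids))
  if (nrow(screen) > 0 && !all(screen$mode == am$mode)) {
    stop("screen results and alteration matrix are from different modes.",
         call. = FALSE)
  }
  sums <- function(rows) {
    if (length(rows) == 0) return(rep(0, length(am$sample_ids)))
    idx <- match(screen$gene_id[rows], am$gene_ids)
    unname(drop(crossprod(am$indicator[idx, , drop = FALSE],
                          abs(screen$beta[rows]))))
  }
  tibble::tibble(
    sample_id = am$sample_ids,
    sum_beta_high = sums(which(screen$beta > 0)),
    sum_beta_low = sums(which(screen$beta < 0)))
}

#' Single-data risk labels
#'
#' Labels each sample `H` when its high-risk coefficient sum exceeds its
#' low-risk sum, `L` for the reverse, and `NA` (the no-risk group, a literal
#' label, not a missing value) on a tie — including samples with no screened
#' alterations at all, for which both sums are zero.
#'
#' @param scores A tibble from [score_samples()].
#' @param tie_tol Relative tolerance declaring the two sums tied.
#' @return A tibble with `sample_id`, `label` in `{"H","L","NA"}`.
#' @export
assign_single <- function(scores, tie_tol = 1e-9) {
  tibble::tibble(
    sample_id = scores$sample_id,
    label = dplyr::case_when(
      .is_tie(scores$sum_beta_high, scores$sum_beta_low, tie_tol) ~ "NA",
      scores$sum_beta_high > scores$sum_beta_low ~ "H",
      TRUE ~ "L"))
}

#' MaxSum risk labels
#'
#' Adds the amplification and deletion coefficient sums per direction and
#' assigns each sample to the direction with the greater total
#' (`H` vs `L`), or `NA` on a tie / no screened alterations. Amplification
#' and deletion scores must come from the same depth (soft with soft, deep
#' with deep).
#'
#' @param amp_scores,del_scores Tibbles from [score_samples()].
#' @param tie_tol Relative tolerance declaring the totals tied.
#' @return A tibble with `sample_id`, `label`.
#' @export
assign_maxsum <- function(amp_scores, del_scores, tie_tol = 1e-9) {
  stopifnot(identical(amp_scores$sample_id, del_scores$sample_id))
  high <- amp_scores$sum_beta_high + del_scores$sum_beta_high
  low <- amp_scores$sum_beta_low + del_scores$sum_beta_low
  tibble::tibble(
    sample_id = amp_scores$sample_id,
    label = dplyr::case_when(
      .is_tie(high, low, tie_tol) ~ "NA",
      high > low ~ "H",
      TRUE ~ "L"))
}

#' Combinations risk labels
#'
#' Crosses the single-data amplification label with the single-data
#' deletion label of the same depth, yielding up to nine groups
#' (`H`, `L`, `NA` for amplifications times the same three for deletions).
#' The combined label is written `"<amp>/<del>"`, e.g. `"H/L"`.
#'
#' @param amp_assign,del_assign Tibbles from [assign_single()].
#' @return A tibble with `sample_id`, `amp_label`, `del_label`, `label`.
#' @export
assign_combinations <- function(amp_assign, del_assign) {
  stopifnot(identical(amp_assign$sample_id, del_assign$sample_id))
  tibble::tibble(
    sample_id = amp_assign$sample_id,
    amp_label = amp_assign$label,
    del_label = del_assign$label,
    label = paste0(amp_assign$label, "/", del_assign$label))
}

#' Build the eight prognostic models of a cohort
#'
#' Runs the full signature stage: screens the four alteration modes, scores
#' every sample, and produces the eight candidate models — four single-data
#' models (one per mode), two MaxSum models (soft, deep) and two
#' Combinations models (soft, deep) — each evaluated with the multi-group
#' log-rank test.
#'
#' A mode whose screening returns no gene region still yields a model; all
#' its samples fall in the `NA` group and its log-rank p-value is reported
#' as missing.
#'
#' @param cohort A `cna_cohort` from [align_cohort()] (or from
#'   [simulate_cohort()] via [as_cohort()]).
#' @param alpha,engine,n_perm,seed,min_recurrence,... Passed to
#'   [screen_mode()].
#' @return An object of class `cna_model_set`: a list with `screens` (named
#'   list of screening tibbles), `assignments` (tibble: `sample_id`,
#'   `model_id`, `label`), `reports` (tibble: one row per model with group
#'   counts and the overall log-rank test) and `clinical`.
#' @export
build_all_models <- function(cohort, alpha = 0.05, engine = "permutation",
                             n_perm = 1000, seed = 1, min_recurrence = 4,
                             ...) {
  modes <- purrr::map(build_modes(cohort$cna), filter_recurrence,
                      min_recurrence = min_recurrence)
  screens <- purrr::map(modes, function(am) {
    screen_mode(am, cohort$clinical, alpha = alpha, engine = engine,
                n_perm = n_perm, seed = seed,
                min_recurrence = min_recurrence, ...)
  })
  scores <- purrr::map2(screens, modes, score_samples)
  singles <- purrr::map(scores, assign_single)
  assign_list <- list(
    single_soft_del = singles$soft_del,
    single_soft_amp = singles$soft_amp,
    single_deep_del = singles$deep_del,
    single_deep_amp = singles$deep_amp,
    maxsum_soft = assign_maxsum(scores$soft_amp, scores$soft_del),
    maxsum_deep = assign_maxsum(scores$deep_amp, scores$deep_del),
    combinations_soft = assign_combinations(singles$soft_amp, singles$soft_del),
    combinations_deep = assign_combinations(singles$deep_amp, singles$deep_del))
  assignments <- dplyr::bind_rows(
    purrr::imap(assign_list, function(a, id) {
      tibble::tibble(sample_id = a$sample_id, model_id = id, label = a$label)
    }))
  assignments$model_id <- factor(assignments$model_id, levels = .model_ids)
  reports <- dplyr::bind_rows(
    purrr::imap(assign_list, function(a, id) {
      evaluate_model(id, a$label, cohort$clinical)
    }))
  structure(list(screens = screens, assignments = assignments,
                 reports = reports, clinical = cohort$clinical),
            class = "cna_model_set")
}

#' @export
print.cna_model_set <- function(x, ...) {
  cat(sprintf("<cna_model_set> %d models over %d samples\n",
              dplyr::n_distinct(x$assignments$model_id), nrow(x$clinical)))
  print(dplyr::select(x$reports, "model_id", "n_groups", "p_value"))
  invisible(x)
}
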