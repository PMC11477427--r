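#' Screen one alteration mode for survival association
#'
#' For every recurrent gene region in an alteration-mode matrix, compares
#' carriers against non-carriers: the two-group log-rank statistic, a
#' p-value from the chosen engine, and the univariate Cox log hazard ratio
#' that supplies the risk direction (`high_risk` for beta > 0, `low_risk`
#' for beta < 0) and feeds the downstream coefficient sums.
#'
#' Following the screening protocol this package reproduces, gene regions
#' are retained at a raw `p <= alpha` without multiple-testing correction;
#' a Benjamini-Hochberg `fdr` column (computed over all tested genes) is
#' included for users who want it.
#'
#' @param am A filtered `alteration_matrix` aligned to `surv`.
#' @param surv A survival tibble with `time` and `event` columns, samples in
#'   the same order as `am`.
#' @param alpha Retention threshold on the raw p-value (default 0.05).
#' @param engine `"permutation"` (conditional permutation null, default),
#'   `"asymptotic"` (chi-square reference) or `"cox"` (likelihood-ratio test
#'   from the univariate Cox fit).
#' @param n_perm,exhaustive_threshold Permutation-engine controls, see
#'   [permutation_pvalue()].
#' @param seed Pipeline-level seed; fanned out deterministically per gene so
#'   results do not depend on gene order.
#' @param min_recurrence Genes with fewer carriers are skipped (they should
#'   already have been removed by [filter_recurrence()]).
#' @param keep_all If `TRUE`, return all tested genes, not only `p <= alpha`.
#' @param ties,beta_ceiling Passed to [cox_beta()].
#' @return A tibble sorted by p-value with one row per retained gene:
#'   `gene_id`, `mode`, `n_altered`, `statistic`, `score`, `p_value`, `fdr`,
#'   `beta`, `se`, `direction`, `monotone`.
#' @export
screen_mode <- function(am, surv, alpha = 0.05,
                        engine = c("permutation", "asymptotic", "cox"),
                        n_perm = 1000, exhaustive_threshold = 25000,
                        seed = 1, min_recurrence = 4, keep_all = FALSE,
                        ties = "efron", beta_ceiling = 10) {
  engine <- match.arg(engine)
  stopifnot(ncol(am$indicator) == nrow(surv))
  time <- surv$time
  event <- surv$event
  n <- length(time)
  empty <- tibble::tibble(
    gene_id = character(), mode = character(), n_altered = integer(),
    statistic = numeric(), score = numeric(), p_value = numeric(),
    fdr = numeric(), beta = numeric(), se = numeric(),
    direction = character(), monotone = logical())
  if (nrow(am$indicator) == 0 || sum(event) == 0) return(empty)
  prep <- .logrank_prep(time, event)
  rows <- purrr::map(seq_len(nrow(am$indicator)), function(i) {
    g <- am$indicator[i, ]
    k <- sum(g)
    if (k < min_recurrence || k >= n) return(NULL)
    st <- .logrank_stats(prep, matrix(g, ncol = 1))
    if (st$variance <= 0) return(NULL)
    cx <- cox_beta(time, event, g, ties = ties, beta_ceiling = beta_ceiling)
    p <- switch(engine,
      permutation = permutation_pvalue(
        time, event, g, n_perm = n_perm,
        seed = .gene_seed(seed, am$gene_ids[i]),
        exhaustive_threshold = exhaustive_threshold)$p_value,
      asymptotic = stats::pchisq(st$statistic, df = 1, lower.tail = FALSE),
      cox = cx$p_value)
    tibble::tibble(
      gene_id = am$gene_ids[i], mode = am$mode, n_altered = as.integer(k),
      statistic = st$statistic, score = st$score, p_value = p,
      beta = cx$beta, se = cx$se,
      direction = dplyr::if_else(cx$beta > 0, "high_risk", "low_risk"),
      monotone = cx$monotone)
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) return(empty)
  res <- dplyr::mutate(res, fdr = stats::p.adjust(.data$p_value, "BH"))
  res <- dplyr::relocate(res, "fdr", .after = "p_value")
  if (!keep_all) res <- dplyr::filter(res, .data$p_value <= alpha)
  dplyr::arrange(res, .data$p_value, .data$gene_id)
}

#' Screen all four alteration modes of a cohort
#'
#' Convenience wrapper: binarizes the cohort's CNA matrix into the four
#' modes, applies the per-mode recurrence filter, and screens each mode.
#'
#' @param cohort A `cna_cohort` from [align_cohort()].
#' @param min_recurrence Carrier threshold for [filter_recurrence()].
#' @param ... Passed to [screen_mode()].
#' @return A named list of four screening tibbles.
#' @export
screen_cohort <- function(cohort, min_recurrence = 4, ...) {
  modes <- build_modes(cohort$cna)
  purrr::map(modes, function(am) {
    screen_mode(filter_recurrence(am, min_recurrence), cohort$clinical,
                min_recurrence = min_recurrence, ...)
  })
}
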