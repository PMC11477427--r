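#' @keywords internal
.cna_modes <- c("soft_del", "soft_amp", "deep_del", "deep_amp")

#' Build a binary alteration mode from a CNA matrix
#'
#' The four alteration modes binarize GISTIC calls by sign and depth:
#' `soft_del` marks any deletion (call <= -1), `deep_del` only homozygous
#' deletions (call == -2), `soft_amp` any amplification (call >= +1) and
#' `deep_amp` only high-level amplifications (call == +2). Deep indicators
#' are by construction a subset of the corresponding soft indicators.
#'
#' @param cna A [cna_matrix()].
#' @param mode One of `"soft_del"`, `"soft_amp"`, `"deep_del"`, `"deep_amp"`.
#' @return An object of class `alteration_matrix`: a list with `mode`,
#'   `gene_ids`, `sample_ids` and a binary `indicator` matrix.
#' @export
build_mode <- function(cna, mode) {
  mode <- match.arg(mode, .cna_modes)
  ind <- switch(mode,
    soft_del = cna$values <= -1L,
    deep_del = cna$values == -2L,
    soft_amp = cna$values >= 1L,
    deep_amp = cna$values == 2L)
  storage.mode(ind) <- "integer"
  structure(list(mode = mode, gene_ids = cna$gene_ids,
                 sample_ids = cna$sample_ids, indicator = ind),
            class = "alteration_matrix")
}

#' Build all four alteration modes
#'
#' @param cna A [cna_matrix()].
#' @return A named list of four `alteration_matrix` objects.
#' @export
build_modes <- function(cna) {
  purrr::map(rlang::set_names(.cna_modes), function(m) build_mode(cna, m))
}

#' Remove low-recurrence gene regions from an alteration mode
#'
#' Keeps only gene regions altered (in the mode's own indicator) in at least
#' `min_recurrence` patients; gene order is preserved. The filter is applied
#' per mode so that, e.g., a gene with many heterozygous losses but too few
#' homozygous deletions does not enter deep-deletion screening.
#'
#' @param am An `alteration_matrix` from [build_mode()].
#' @param min_recurrence Minimum number of altered patients (default 4).
#' @return A filtered `alteration_matrix` (possibly with zero genes).
#' @export
filter_recurrence <- function(am, min_recurrence = 4) {
  keep <- rowSums(am$indicator) >= min_recurrence
  if (!any(keep)) {
    message(sprintf("filter_recurrence: no %s gene region reaches %d carriers",
                    am$mode, min_recurrence))
  }
  structure(list(mode = am$mode, gene_ids = am$gene_ids[keep],
                 sample_ids = am$sample_ids,
                 indicator = am$indicator[keep, , drop = FALSE]),
            class = "alteration_matrix")
}

#' Remove globally low-recurrence gene regions from a CNA matrix
#'
#' Optional global pre-filter dropping gene regions with any non-zero call
#' in fewer than `min_recurrence` patients, applied before mode
#' binarization. The per-mode [filter_recurrence()] remains the default
#' protocol; this variant is exposed for users who prefer filtering on the
#' raw calls once.
#'
#' @param cna A [cna_matrix()].
#' @param min_recurrence Minimum number of patients with a non-zero call.
#' @return A filtered [cna_matrix()].
#' @export
filter_recurrence_global <- function(cna, min_recurrence = 4) {
  keep <- rowSums(cna$values != 0L) >= min_recurrence
  cna_matrix(cna$values[keep, , drop = FALSE],
             gene_ids = cna$gene_ids[keep], sample_ids = cna$sample_ids,
             annotation = if (!is.null(cna$annotation)) cna$annotation[keep, ] else NULL)
}

#' Write an alteration mode matrix as TSV
#'
#' @param am An `alteration_matrix`.
#' @param dir Output directory; the file is named `mode_<mode>.tsv`.
#' @return The written path, invisibly.
#' @export
write_mode <- function(am, dir) {
  path <- file.path(dir, paste0("mode_", am$mode, ".tsv"))
  df <- dplyr::bind_cols(
    tibble::tibble(`Gene Symbol` = am$gene_ids),
    tibble::as_tibble(as.data.frame(am$indicator, check.names = FALSE)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("<alteration_matrix> mode=%s, %d gene regions x %d samples, %d altered cells\n",
              x$mode, nrow(x$indicator), ncol(x$indicator), sum(x$indicator)))
  invisible(x)
}
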