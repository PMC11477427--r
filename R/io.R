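#' Read a GISTIC "all_thresholded_by_genes" matrix
#'
#' Reads a tab-separated GISTIC 2 Level-4 thresholded matrix (rows = gene
#' regions, columns = samples, integer calls in -2..+2). Two dialects are
#' auto-detected: the full Firebrowse export whose first three columns are
#' gene symbol, locus id and cytoband, and a minimal dialect whose first
#' column is the gene symbol and all remaining columns are samples.
#' Annotation columns are stored as annotation, never as samples.
#'
#' Duplicate gene symbols keep the first occurrence (the rest are dropped
#' with a message); a duplicated sample column is an error, as is any cell
#' outside the five allowed integers.
#'
#' @param path Path to the TSV file.
#' @return A [cna_matrix()].
#' @export
read_gistic_thresholded <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal")
  if (ncol(df) < 2) stop("GISTIC file needs a gene column plus samples.", call. = FALSE)
  nm <- names(df)
  # Firebrowse dialect: columns 2-3 are "Locus ID" and "Cytoband"
  has_annot <- ncol(df) >= 4 &&
    grepl("locus", nm[2], ignore.case = TRUE) &&
    grepl("cytoband", nm[3], ignore.case = TRUE)
  annot_cols <- if (has_annot) 2:3 else integer(0)
  sample_cols <- setdiff(seq_along(nm)[-1], annot_cols)
  sample_ids <- nm[sample_cols]
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample column '%s'",
                 sample_ids[duplicated(sample_ids)][1]), call. = FALSE)
  }
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- duplicated(gene_ids)
    message(sprintf("read_gistic_thresholded: dropping %d duplicate gene row(s), keeping first occurrence", sum(dup)))
    df <- df[!dup, ]
    gene_ids <- df[[1]]
  }
  raw <- as.matrix(df[sample_cols])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | num != round(num) | num < -2 | num > 2)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(num))
    stop(sprintf("non-integer or out-of-range value '%s' at gene '%s', sample column '%s'",
                 raw[bad[1]], gene_ids[i[1]], sample_ids[i[2]]), call. = FALSE)
  }
  annotation <- if (has_annot) {
    tibble::tibble(locus_id = df[[2]], cytoband = df[[3]])
  } else NULL
  cna_matrix(num, gene_ids = gene_ids, sample_ids = sample_ids,
             annotation = annotation)
}

#' Write a CNA matrix in GISTIC dialect
#'
#' Writes the same TSV dialect that was read: if the matrix carries locus
#' annotation, the three-annotation-column Firebrowse layout is emitted,
#' otherwise the minimal gene + samples layout.
#'
#' @param cna A [cna_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gistic_thresholded <- function(cna, path) {
  df <- tibble::as_tibble(as.data.frame(cna$values, check.names = FALSE))
  if (!is.null(cna$annotation)) {
    df <- dplyr::bind_cols(
      tibble::tibble(`Gene Symbol` = cna$gene_ids,
                     `Locus ID` = cna$annotation$locus_id,
                     Cytoband = cna$annotation$cytoband),
      df)
  } else {
    df <- dplyr::bind_cols(tibble::tibble(`Gene Symbol` = cna$gene_ids), df)
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Reads a tab-separated clinical table with a sample identifier, a
#' time-to-event column (days) and an event indicator; every remaining
#' column is kept as a cofactor. Rows whose time or event cannot be parsed
#' are dropped with a message: only patients with valid survival
#' information enter any downstream analysis. Cofactor missingness is
#' retained as `NA` and handled per analysis, not per sample.
#'
#' @param path Path to the TSV file.
#' @param id_col,time_col,event_col Column names for sample id, survival
#'   time (days) and event indicator.
#' @param event_coding Named numeric vector mapping character event codes to
#'   0/1, e.g. `c(dead = 1, alive = 0)`. Numeric 0/1 columns pass through.
#' @return A tibble with columns `sample_id`, `time`, `event` plus cofactors.
#' @export
read_clinical <- function(path, id_col = "sample_id", time_col = "time",
                          event_col = "event",
                          event_coding = c(dead = 1, deceased = 1, "1" = 1,
                                           alive = 0, living = 0, "0" = 0)) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c(id_col, time_col, event_col), names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df[[time_col]]))
  ev_raw <- tolower(trimws(df[[event_col]]))
  event <- unname(event_coding[ev_raw])
  valid <- !is.na(time) & time >= 0 & !is.na(event) & event %in% c(0, 1)
  if (any(!valid)) {
    message(sprintf("read_clinical: dropping %d row(s) without valid survival information",
                    sum(!valid)))
  }
  cof <- df[valid, setdiff(names(df), c(id_col, time_col, event_col)), drop = FALSE]
  cof <- dplyr::mutate(cof, dplyr::across(
    dplyr::everything(),
    function(x) if (all(is.na(x) | grepl("^[-+0-9.eE]+$", x))) as.numeric(x) else x))
  dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(df[[id_col]])[valid],
                   time = time[valid], event = as.numeric(event[valid])),
    cof)
}

#' Align a CNA matrix with a clinical table
#'
#' Intersects samples between a CNA matrix and a clinical table after
#' truncating barcodes to a common granularity (Firebrowse CNA columns are
#' sample-level TCGA barcodes while clinical tables are patient-level; the
#' default truncation of 12 characters maps both to the patient barcode).
#' Both sides are returned with samples in identical order.
#'
#' @param cna A [cna_matrix()].
#' @param clinical A tibble from [read_clinical()].
#' @param truncate_barcode Number of leading characters used for matching;
#'   `Inf` disables truncation.
#' @return A list of class `cna_cohort` with elements `cna` (samples renamed
#'   to the truncated barcode), `clinical`, and `n`.
#' @export
align_cohort <- function(cna, clinical, truncate_barcode = 12) {
  shorten <- function(x) {
    if (is.finite(truncate_barcode)) substr(x, 1L, truncate_barcode) else x
  }
  cna_key <- shorten(cna$sample_ids)
  clin_key <- shorten(clinical$sample_id)
  # one sample per patient: keep the first barcode mapping to each key
  keep_cna <- !duplicated(cna_key)
  keep_clin <- !duplicated(clin_key)
  common <- intersect(cna_key[keep_cna], clin_key[keep_clin])
  if (length(common) == 0) {
    stop("no samples shared between CNA matrix and clinical table.", call. = FALSE)
  }
  dropped_cna <- length(cna$sample_ids) - length(common)
  dropped_clin <- nrow(clinical) - length(common)
  if (dropped_cna || dropped_clin) {
    message(sprintf("align_cohort: %d sample(s) dropped from CNA, %d from clinical",
                    dropped_cna, dropped_clin))
  }
  cna_idx <- match(common, cna_key)
  clin_idx <- match(common, clin_key)
  values <- cna$values[, cna_idx, drop = FALSE]
  colnames(values) <- common
  clinical_out <- clinical[clin_idx, , drop = FALSE]
  clinical_out$sample_id <- common
  structure(
    list(cna = cna_matrix(values, gene_ids = cna$gene_ids,
                          sample_ids = common, annotation = cna$annotation),
         clinical = clinical_out,
         n = length(common)),
    class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(sprintf("<cna_cohort> %d samples, %d gene regions, %d events\n",
              x$n, length(x$cna$gene_ids), sum(x$clinical$event)))
  invisible(x)
}
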