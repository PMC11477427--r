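#' CNA matrix of GISTIC threshold calls
#'
#' A light container for a gene-region-by-sample matrix of integer GISTIC
#' threshold calls: -2 homozygous deletion, -1 heterozygous loss, 0 diploid,
#' +1 one-copy gain, +2 high-level amplification.
#'
#' @param values Integer matrix, rows = gene regions, columns = samples.
#'   Every entry must be one of -2, -1, 0, 1, 2.
#' @param gene_ids Character vector of unique gene-region identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids Character vector of unique sample barcodes (defaults to
#'   `colnames(values)`).
#' @param annotation Optional tibble of per-gene locus annotation (e.g.
#'   `locus_id`, `cytoband`), one row per gene in the same order.
#'
#' @return An object of class `cna_matrix`.
#' @export
cna_matrix <- function(values, gene_ids = rownames(values),
                       sample_ids = colnames(values), annotation = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`gene_ids` and `sample_ids` are required (or set dimnames).",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions.", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids.", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids.", call. = FALSE)
  bad <- which(!(values %in% c(-2L, -1L, 0L, 1L, 2L)) | is.na(values))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "invalid GISTIC call %s at gene '%s', sample '%s' (allowed: -2..2)",
      values[bad[1]], gene_ids[i[1]], sample_ids[i[2]]), call. = FALSE)
  }
  if (!is.null(annotation)) {
    annotation <- tibble::as_tibble(annotation)
    stopifnot(nrow(annotation) == length(gene_ids))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids, values = values,
         annotation = annotation),
    class = "cna_matrix")
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat(sprintf("<cna_matrix> %d gene regions x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  tab <- table(factor(x$values, levels = -2:2))
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$annotation)) {
    cat("  annotation columns:",
        paste(names(x$annotation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cna_matrix <- function(x) dim(x$values)

#' Convert a CNA matrix to a long tibble
#'
#' @param x A [cna_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `call`.
#' @export
as_tibble.cna_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(x$gene_ids, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$gene_ids)),
    call = as.integer(x$values))
}
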