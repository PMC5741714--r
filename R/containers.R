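#' Bulk count matrix with stage/replicate design
#'
#' Container for a gene x sample matrix of integer read counts over the
#' five developmental stages, with the sample sheet and optional transcript
#' lengths (needed for RPKM).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample`, `stage`, `replicate`.
#'   Stages must be drawn from [STAGES].
#' @param gene_lengths optional named numeric vector of transcript lengths
#'   in base pairs.
#' @return object of class `bulk_data`.
#' @export
bulk_data <- function(counts, samples, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (is.null(colnames(counts))) stopf("counts must have sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (!all(c("sample", "stage", "replicate") %in% names(samples)))
    stopf("sample sheet needs columns sample, stage, replicate")
  if (!setequal(samples$sample, colnames(counts)))
    stopf("sample sheet does not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  if (!all(samples$stage %in% STAGES))
    stopf("unknown stage label(s): %s",
          paste(setdiff(samples$stage, STAGES), collapse = ", "))
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths))) stopf("gene_lengths must be named")
    if (any(gene_lengths <= 0)) stopf("gene lengths must be positive")
  }
  structure(list(counts = counts, samples = samples,
                 gene_lengths = gene_lengths),
            class = "bulk_data")
}

#' @export
print.bulk_data <- function(x, ...) {
  cat(sprintf("bulk_data: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", STAGES,
                            as.integer(table(factor(x$samples$stage,
                                                    STAGES)))),
                    collapse = " ")))
  invisible(x)
}

#' Labeled single-cell UMI count matrix
#'
#' Container for a gene x cell UMI count matrix where every cell carries a
#' cell-type and a cell-subtype label, and subtypes nest uniquely in types.
#'
#' @param counts integer matrix, genes in rows, cells in columns.
#' @param cells data.frame with columns `cell`, `type`, `subtype`.
#' @return object of class `sc_data`; the subtype-to-type nesting map is
#'   stored as attribute-like list element `nesting`.
#' @export
sc_data <- function(counts, cells) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (is.null(colnames(counts))) stopf("counts must have cell colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("UMI counts must be non-negative integers")
  if (!all(c("cell", "type", "subtype") %in% names(cells)))
    stopf("cell sheet needs columns cell, type, subtype")
  if (!setequal(cells$cell, colnames(counts)))
    stopf("cell sheet does not match count matrix columns")
  cells <- cells[match(colnames(counts), cells$cell), , drop = FALSE]
  nest <- unique(cells[, c("subtype", "type")])
  if (anyDuplicated(nest$subtype))
    stopf("subtype(s) mapped to more than one type: %s",
          paste(nest$subtype[duplicated(nest$subtype)], collapse = ", "))
  nesting <- stats::setNames(nest$type, nest$subtype)
  structure(list(counts = counts, cells = cells, nesting = nesting),
            class = "sc_data")
}

#' @export
print.sc_data <- function(x, ...) {
  cat(sprintf("sc_data: %d genes x %d cells, %d types / %d subtypes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$type)), length(unique(x$cells$subtype))))
  invisible(x)
}
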