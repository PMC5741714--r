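#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @return `read_gmt`: named list of gene sets; `write_gmt`: the path,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stopf("malformed GMT line: %s", substr(ln, 1, 40))
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stopf("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read bulk count data from TSV files
#'
#' @param counts_path genes x samples TSV (first column = gene id).
#' @param samples_path sample sheet TSV (sample, stage, replicate).
#' @param lengths_path optional two-column TSV (gene, length).
#' @return [bulk_data] object.
#' @export
read_bulk_tsv <- function(counts_path, samples_path, lengths_path = NULL) {
  cnt <- read_tsv(counts_path)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt[[1]]
  samples <- read_tsv(samples_path)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- read_tsv(lengths_path)
    lengths <- stats::setNames(lt[[2]], lt[[1]])
  }
  bulk_data(m, samples, lengths)
}

#' Read single-cell count data from TSV files
#'
#' @param counts_path genes x cells TSV (first column = gene id).
#' @param cells_path cell sheet TSV (cell, type, subtype).
#' @return [sc_data] object.
#' @export
read_sc_tsv <- function(counts_path, cells_path) {
  cnt <- read_tsv(counts_path)
  m <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(m) <- cnt[[1]]
  sc_data(m, read_tsv(cells_path))
}

## matrix -> TSV with the gene id as first column
write_counts_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write DE tables to a directory
#'
#' One TSV per comparison with the [nb_wald_test()] schema.
#' @param de_results named list of DE tables.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_de_tables <- function(de_results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in names(de_results))
    write_tsv(de_results[[lab]], file.path(dir, paste0("de_", lab, ".tsv")))
  invisible(dir)
}

#' Read DE tables from a directory (drop-in external results)
#'
#' Reads every `de_<comparison>.tsv` in a directory; tables only need the
#' columns gene, comparison, log2fc, pvalue, padj, z.
#' @param dir directory with DE TSVs.
#' @return named list of DE tables.
#' @export
read_de_tables <- function(dir) {
  files <- list.files(dir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stopf("no DE tables in %s", dir)
  out <- lapply(files, read_tsv)
  names(out) <- sub("^de_(.*)\\.tsv$", "\\1", basename(files))
  out
}
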