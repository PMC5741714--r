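#' Predict cell-type-specific differentiation drivers
#'
#' Drivers of a cell type are the genes that are exclusive markers of that
#' type (combined type + nested-subtype markers) AND belong to a
#' developmentally repressed (decreasing-direction) cluster. The
#' computation is an exact set intersection; no additional filters.
#'
#' @param catalog [derive_marker_catalog()] result.
#' @param clusters `trajectory_clustering` object, or a named cluster
#'   vector plus `directions`.
#' @param directions named per-cluster direction labels when `clusters`
#'   is a plain vector.
#' @return data.frame of class `driver_table`: gene, type, level,
#'   cluster, direction.
#' @export
predict_drivers <- function(catalog, clusters, directions = NULL) {
  if (inherits(clusters, "trajectory_clustering")) {
    directions <- clusters$directions
    cl <- clusters$assignment$cluster
  } else {
    cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
          else clusters
  }
  if (is.null(directions)) stopf("cluster directions required")
  dec_clusters <- as.integer(sub("^C", "", names(directions)))[
    directions == "decreasing"]
  if (!length(dec_clusters)) {
    warnf("no decreasing cluster: empty driver table")
    return(empty_driver_table())
  }
  unmatched <- setdiff(catalog$gene, names(cl))
  if (length(unmatched))
    message(sprintf("%d marker(s) not in the clustered bulk set",
                    length(unmatched)))
  keep <- catalog$gene %in% names(cl)[cl %in% dec_clusters]
  if (!any(keep)) return(empty_driver_table())
  out <- data.frame(gene = catalog$gene[keep],
                    type = catalog$owner_type[keep],
                    level = catalog$level[keep],
                    cluster = unname(cl[catalog$gene[keep]]),
                    direction = "decreasing",
                    stringsAsFactors = FALSE)
  out <- out[order(out$type, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("driver_table", "data.frame")
  out
}

empty_driver_table <- function() {
  out <- data.frame(gene = character(0), type = character(0),
                    level = character(0), cluster = integer(0),
                    direction = character(0), stringsAsFactors = FALSE)
  class(out) <- c("driver_table", "data.frame")
  out
}

#' Annotated driver profiles
#'
#' For every predicted driver: the five-stage bulk RPKM profile scaled to
#' its maximum (1 at the stage of highest expression) and the mean
#' normalized single-cell expression per cell type.
#'
#' @param drivers [predict_drivers()] result.
#' @param bulk [bulk_data] with gene lengths.
#' @param sc optional [sc_data] for the per-type expression columns.
#' @return data.frame: driver rows with `rpkm_<stage>` (max-normalized)
#'   and `sc_<type>` columns; genes without a length are flagged in
#'   `profile_ok`.
#' @export
profile_table <- function(drivers, bulk, sc = NULL) {
  if (!nrow(drivers)) return(drivers)
  out <- drivers
  out$profile_ok <- FALSE
  prof <- matrix(NA_real_, nrow(drivers), length(STAGES),
                 dimnames = list(drivers$gene, STAGES))
  if (!is.null(bulk$gene_lengths)) {
    have <- drivers$gene %in% names(bulk$gene_lengths) &
      drivers$gene %in% rownames(bulk$counts)
    if (any(!have))
      warnf("%d driver(s) without transcript length: profile omitted",
            sum(!have))
    if (any(have)) {
      g <- drivers$gene[have]
      rp <- rpkm(bulk$counts[g, , drop = FALSE], bulk$gene_lengths[g],
                 colSums(bulk$counts))
      stage <- factor(bulk$samples$stage, STAGES)
      stage_means <- vapply(STAGES, function(s)
        rowMeans(rp[, stage == s, drop = FALSE]), numeric(length(g)))
      if (length(g) == 1) stage_means <- matrix(stage_means, nrow = 1,
                                                dimnames = list(g, STAGES))
      mx <- apply(stage_means, 1, max)
      nz <- mx > 0
      prof[g[nz], ] <- stage_means[nz, , drop = FALSE] / mx[nz]
      out$profile_ok[have][nz] <- TRUE
      if (any(!nz)) warnf("%d driver(s) with all-zero profile", sum(!nz))
    }
  } else {
    warnf("no gene lengths in bulk data: profiles omitted")
  }
  colnames(prof) <- paste0("rpkm_", STAGES)
  out <- cbind(out, prof[out$gene, , drop = FALSE])
  if (!is.null(sc)) {
    norm <- umi_normalize(sc$counts)$normalized
    types <- sort(unique(sc$cells$type))
    scm <- vapply(types, function(tp)
      rowMeans(norm[, sc$cells$type == tp, drop = FALSE]),
      numeric(nrow(norm)))
    scm_rows <- matrix(NA_real_, nrow(out), length(types),
                       dimnames = list(out$gene, paste0("sc_", types)))
    have <- out$gene %in% rownames(scm)
    scm_rows[have, ] <- scm[out$gene[have], , drop = FALSE]
    out <- cbind(out, scm_rows)
  }
  rownames(out) <- NULL
  out
}
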