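#' Hypergeometric gene-set test
#'
#' Over- or under-representation of the overlap between a query and a
#' target set within a finite universe. Over-tail p = P(X >= overlap),
#' under-tail p = P(X <= overlap), X ~ Hypergeometric(|universe|,
#' |target|, |query|). Fold enrichment is overlap / expected overlap.
#'
#' @param query,target,universe character vectors of gene ids; query and
#'   target must be subsets of the universe.
#' @param tail "over" or "under".
#' @return list with `overlap`, `expected`, `fold`, `p`.
#' @export
hypergeom_test <- function(query, target, universe,
                           tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query); target <- unique(target)
  universe <- unique(universe)
  if (!all(query %in% universe) || !all(target %in% universe))
    stopf("query and target must be subsets of the universe")
  k <- length(intersect(query, target))
  N <- length(universe); K <- length(target); n <- length(query)
  expected <- n * K / N
  p <- if (tail == "over") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  list(overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_, p = p)
}

#' Marker-set enrichment across developmental clusters
#'
#' Over-representation of every cell type's combined marker list in every
#' developmental cluster (hypergeometric, Bonferroni corrected over the
#' whole type x cluster family by default), with the top three enriched
#' clusters reported per type. Types with no cluster significant at
#' `alpha` are reported as non-significant.
#'
#' @param clusters named cluster vector (or `cluster_assignment`).
#' @param marker_lists named list of per-type marker gene vectors.
#' @param universe gene universe (bulk-expressed genes).
#' @param alpha significance level on the corrected p.
#' @param family "matrix" (Bonferroni over all tests, default) or
#'   "per_type".
#' @return list with `table` (data.frame: type, cluster, overlap, expected,
#'   fold, p, p_corrected) and `top3` (data.frame: type, rank, cluster,
#'   n_markers, p_corrected, significant).
#' @export
cluster_marker_enrichment <- function(clusters, marker_lists, universe,
                                      alpha = 0.05,
                                      family = c("matrix", "per_type")) {
  family <- match.arg(family)
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  cl <- cl[names(cl) %in% universe]
  ids <- sort(unique(cl))
  rows <- list()
  for (tp in names(marker_lists)) {
    mk <- intersect(marker_lists[[tp]], universe)
    dropped <- setdiff(marker_lists[[tp]], universe)
    if (length(dropped))
      warnf("%s: %d marker(s) absent from the universe dropped",
            tp, length(dropped))
    if (!length(mk)) {
      rows[[length(rows) + 1]] <- data.frame(
        type = tp, cluster = NA_integer_, overlap = 0L,
        expected = NA_real_, fold = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    for (k in ids) {
      genes_k <- names(cl)[cl == k]
      h <- hypergeom_test(genes_k, mk, universe, "over")
      rows[[length(rows) + 1]] <- data.frame(
        type = tp, cluster = k, overlap = h$overlap,
        expected = h$expected, fold = h$fold, p = h$p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$p)
  tab$p_corrected <- NA_real_
  if (family == "matrix") {
    tab$p_corrected[ok] <- correct(tab$p[ok], "bonferroni")
  } else {
    for (tp in unique(tab$type)) {
      sel <- ok & tab$type == tp
      tab$p_corrected[sel] <- correct(tab$p[sel], "bonferroni")
    }
  }
  top <- lapply(names(marker_lists), function(tp) {
    sub <- tab[tab$type == tp & !is.na(tab$p), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(sub$p_corrected, sub$p), , drop = FALSE]
    top_n <- utils::head(sub, 3)
    data.frame(type = tp, rank = seq_len(nrow(top_n)),
               cluster = top_n$cluster, n_markers = top_n$overlap,
               p_corrected = top_n$p_corrected,
               significant = top_n$p_corrected < alpha,
               stringsAsFactors = FALSE)
  })
  list(table = tab, top3 = do.call(rbind, top))
}

#' GO-term x cell-type interaction matrix for one cluster
#'
#' Restricts the analysis to the genes of one developmental cluster,
#' keeps the terms enriched in that cluster (Benjamini-corrected p below
#' `term_alpha`), and tests every kept term against every cell type's
#' markers (and the non-marker set) for over- and under-representation
#' within the cluster. The signed output is the smaller-tail corrected p
#' with a positive sign for enrichment and negative for depletion;
#' Bonferroni correction spans the whole term x type matrix.
#'
#' @param cluster_genes character vector, the chosen cluster's genes.
#' @param terms named list of gene sets (GO-like annotations).
#' @param marker_lists named per-type marker lists; the non-marker set is
#'   taken from attribute `non_markers` (or passed via `non_markers`).
#' @param universe gene universe for the cluster-level term filter.
#' @param term_alpha Benjamini threshold for keeping terms (default 0.01).
#' @param non_markers optional explicit non-marker set.
#' @return list with `kept_terms`, `signed` (matrix terms x types of
#'   signed corrected p), and `table` (long data.frame with both tails).
#' @export
go_celltype_interaction <- function(cluster_genes, terms, marker_lists,
                                    universe, term_alpha = 0.01,
                                    non_markers = NULL) {
  if (is.null(non_markers)) non_markers <- attr(marker_lists, "non_markers")
  cluster_genes <- intersect(cluster_genes, universe)
  ## stage 1: which terms are enriched in the cluster at all
  term_p <- vapply(terms, function(tg)
    hypergeom_test(cluster_genes, intersect(tg, universe), universe,
                   "over")$p, numeric(1))
  term_q <- correct(term_p, "benjamini")
  kept <- names(terms)[term_q < term_alpha]
  groups <- c(marker_lists, list(non_marker = non_markers))
  rows <- list()
  for (tm in kept) {
    tg <- intersect(terms[[tm]], cluster_genes)
    if (!length(tg)) {
      warnf("term %s has no gene in the cluster; skipped", tm)
      next
    }
    for (gp in names(groups)) {
      target <- intersect(groups[[gp]], cluster_genes)
      over <- hypergeom_test(tg, target, cluster_genes, "over")
      under <- hypergeom_test(tg, target, cluster_genes, "under")
      rows[[length(rows) + 1]] <- data.frame(
        term = tm, group = gp, overlap = over$overlap,
        expected = over$expected, fold = over$fold,
        p_over = over$p, p_under = under$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(kept_terms = kept, signed = NULL,
                table = data.frame()))
  tab <- do.call(rbind, rows)
  n_tests <- 2 * nrow(tab)   # both tails counted in the family
  tab$q_over <- pmin(1, tab$p_over * n_tests)
  tab$q_under <- pmin(1, tab$p_under * n_tests)
  signed <- matrix(NA_real_, length(unique(tab$term)), length(groups),
                   dimnames = list(unique(tab$term), names(groups)))
  for (r in seq_len(nrow(tab))) {
    v <- if (tab$p_over[r] <= tab$p_under[r]) tab$q_over[r]
         else -tab$q_under[r]
    signed[tab$term[r], tab$group[r]] <- v
  }
  list(kept_terms = kept, signed = signed, table = tab)
}

#' Split an annotated gene set by cluster direction
#'
#' Partitions the genes of an annotated set that are developmentally
#' regulated (i.e. clustered) into the genes of decreasing, increasing,
#' and transient clusters. Genes outside the clustering are excluded.
#'
#' @param annotated character vector of gene ids (e.g. a GO term).
#' @param clusters `cluster_assignment` or named cluster vector.
#' @param directions named direction labels per cluster ("C1", ... as from
#'   [trajectory_cluster()]), or a `trajectory_clustering` object passed as
#'   `clusters`.
#' @return list with `decreasing`, `increasing`, `transient` gene vectors.
#' @export
split_by_direction <- function(annotated, clusters, directions = NULL) {
  if (inherits(clusters, "trajectory_clustering")) {
    directions <- clusters$directions
    clusters <- clusters$assignment$cluster
  } else if (inherits(clusters, "cluster_assignment")) {
    clusters <- clusters$cluster
  }
  if (is.null(directions)) stopf("cluster directions required")
  genes <- intersect(annotated, names(clusters))
  dir_of <- directions[paste0("C", clusters[genes])]
  list(decreasing = genes[dir_of == "decreasing"],
       increasing = genes[dir_of == "increasing"],
       transient = genes[dir_of == "transient"])
}
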