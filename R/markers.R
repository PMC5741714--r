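#' Pairwise differential expression over all cell subtypes
#'
#' Runs one NB Wald comparison per unordered subtype pair (s(s-1)/2 tables;
#' 1081 for 47 subtypes), with per-cell size factors from the library-size
#' normalization. Group A is the lexicographically first subtype, so
#' `log2fc > 0` means higher in the second subtype of the label.
#'
#' @param sc [sc_data] object.
#' @param alpha unused here; kept by callers.
#' @param ... passed to [nb_wald_test()].
#' @return named list of DE tables keyed by "A_vs_B".
#' @export
pairwise_subtype_de <- function(sc, ...) {
  subs <- sort(unique(sc$cells$subtype))
  sizes <- table(sc$cells$subtype)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stopf("subtype(s) with fewer than 2 cells: %s",
          paste(small, collapse = ", "))
  norm <- umi_normalize(sc$counts)
  sf <- norm$factors
  out <- vector("list", length(subs) * (length(subs) - 1) / 2)
  nm <- character(length(out))
  k <- 1
  for (i in seq_len(length(subs) - 1)) {
    a <- which(sc$cells$subtype == subs[i])
    for (j in seq((i + 1), length(subs))) {
      b <- which(sc$cells$subtype == subs[j])
      lab <- paste0(subs[i], "_vs_", subs[j])
      out[[k]] <- nb_wald_test(sc$counts, a, b,
                               size_factors = sf[c(a, b)],
                               comparison = lab, ...)
      nm[k] <- lab
      k <- k + 1
    }
  }
  names(out) <- nm
  out
}

## wins[g, s]: number of comparisons where gene g is significantly
## up-regulated in subtype s
subtype_win_matrix <- function(pairwise, subtypes, alpha) {
  genes <- pairwise[[1]]$gene
  wins <- matrix(0L, length(genes), length(subtypes),
                 dimnames = list(genes, subtypes))
  for (lab in names(pairwise)) {
    ab <- strsplit(lab, "_vs_", fixed = TRUE)[[1]]
    tab <- pairwise[[lab]]
    sig <- tab$padj < alpha
    ## log2fc > 0: higher in B;  < 0: higher in A
    wins[, ab[1]] <- wins[, ab[1]] + as.integer(sig & tab$log2fc < 0)
    wins[, ab[2]] <- wins[, ab[2]] + as.integer(sig & tab$log2fc > 0)
  }
  wins
}

#' Candidate subtype markers by pairwise-win voting
#'
#' A gene is a candidate marker of subtype S when it is significantly
#' up-regulated (adjusted p < alpha) in at least `(s-1) - allowed_losses`
#' of S's s-1 pairwise comparisons (44 of 46 for the 47-subtype design).
#' A gene may be a candidate of several subtypes (a "multiple marker");
#' see [resolve_multiple_markers()].
#'
#' @param pairwise result of [pairwise_subtype_de()].
#' @param alpha significance threshold on the adjusted p-value.
#' @param allowed_losses comparisons a marker may fail (default 2).
#' @return logical matrix genes x subtypes of candidacy, with the win
#'   counts as attribute `wins`.
#' @export
call_subtype_markers <- function(pairwise, alpha = 0.05,
                                 allowed_losses = 2) {
  subtypes <- sort(unique(unlist(strsplit(names(pairwise), "_vs_",
                                          fixed = TRUE))))
  wins <- subtype_win_matrix(pairwise, subtypes, alpha)
  min_wins <- (length(subtypes) - 1) - allowed_losses
  cand <- wins >= min_wins
  attr(cand, "wins") <- wins
  attr(cand, "min_wins") <- min_wins
  cand
}

#' Resolve multiple markers to a single owning subtype
#'
#' A gene that is a candidate marker of two or more subtypes is assigned
#' to the subtype where its mean library-size-normalized expression is
#' highest; exact ties go to the first subtype in label order, with a
#' warning.
#'
#' @param candidates logical matrix from [call_subtype_markers()].
#' @param sc [sc_data] object (for expression means).
#' @return data.frame: gene, owner_subtype, wins, mean_expr_owner.
#' @export
resolve_multiple_markers <- function(candidates, sc) {
  wins <- attr(candidates, "wins")
  norm <- umi_normalize(sc$counts)$normalized
  subtypes <- colnames(candidates)
  sub_means <- vapply(subtypes, function(s)
    rowMeans(norm[, sc$cells$subtype == s, drop = FALSE]),
    numeric(nrow(norm)))
  hits <- which(rowSums(candidates) > 0)
  if (!length(hits))
    return(data.frame(gene = character(0), owner_subtype = character(0),
                      wins = integer(0), mean_expr_owner = numeric(0),
                      stringsAsFactors = FALSE))
  out <- lapply(hits, function(g) {
    cand_s <- subtypes[candidates[g, ]]
    mu <- sub_means[rownames(candidates)[g], cand_s]
    best <- cand_s[which.max(mu)]
    if (length(cand_s) > 1 && sum(mu == max(mu)) > 1)
      warnf("gene %s: expression tie between subtypes; first label kept",
            rownames(candidates)[g])
    data.frame(gene = rownames(candidates)[g], owner_subtype = best,
               wins = wins[g, best], mean_expr_owner = max(mu),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cell-type markers by within-type homogeneity and cross-type up-regulation
#'
#' A gene is a marker of cell type T when (i) every pairwise comparison
#' between T's own subtypes is non-significant (adjusted p > alpha,
#' homogeneous expression; vacuous for single-subtype types) and (ii) it is
#' significantly up-regulated versus every other cell type in pooled
#' type-vs-type comparisons (`mode = "each"`, default) or versus all other
#' cells pooled (`mode = "rest"`).
#'
#' @param sc [sc_data] object.
#' @param pairwise result of [pairwise_subtype_de()] (condition (i)).
#' @param alpha significance threshold.
#' @param mode "each" or "rest" for condition (ii).
#' @return data.frame: gene, owner_type, mean_expr_owner.
#' @export
call_type_markers <- function(sc, pairwise, alpha = 0.05,
                              mode = c("each", "rest")) {
  mode <- match.arg(mode)
  genes <- rownames(sc$counts)
  types <- sort(unique(sc$cells$type))
  nesting <- sc$nesting
  norm <- umi_normalize(sc$counts)
  sf <- norm$factors

  ## (i) homogeneity: no significant difference within the type's subtypes
  homog <- matrix(TRUE, length(genes), length(types),
                  dimnames = list(genes, types))
  for (lab in names(pairwise)) {
    ab <- strsplit(lab, "_vs_", fixed = TRUE)[[1]]
    ta <- nesting[[ab[1]]]; tb <- nesting[[ab[2]]]
    if (identical(ta, tb))
      homog[, ta] <- homog[, ta] & (pairwise[[lab]]$padj > alpha)
  }

  ## (ii) up-regulation against other types
  up <- matrix(TRUE, length(genes), length(types),
               dimnames = list(genes, types))
  if (mode == "each") {
    for (i in seq_len(length(types) - 1)) {
      a <- which(sc$cells$type == types[i])
      for (j in seq((i + 1), length(types))) {
        b <- which(sc$cells$type == types[j])
        tab <- nb_wald_test(sc$counts, a, b, size_factors = sf[c(a, b)],
                            comparison = paste0(types[i], "_vs_", types[j]))
        sig <- tab$padj < alpha
        up[, types[i]] <- up[, types[i]] & sig & tab$log2fc < 0
        up[, types[j]] <- up[, types[j]] & sig & tab$log2fc > 0
      }
    }
  } else {
    for (tp in types) {
      a <- which(sc$cells$type == tp)
      b <- which(sc$cells$type != tp)
      tab <- nb_wald_test(sc$counts, b, a, size_factors = sf[c(b, a)],
                          comparison = paste0("rest_vs_", tp))
      up[, tp] <- tab$padj < alpha & tab$log2fc > 0
    }
  }

  marker <- homog & up
  hits <- which(rowSums(marker) > 0)
  type_means <- vapply(types, function(tp)
    rowMeans(norm$normalized[, sc$cells$type == tp, drop = FALSE]),
    numeric(length(genes)))
  out <- lapply(hits, function(g) {
    tps <- types[marker[g, ]]
    ## up-regulation vs every other type can hold for one type only
    data.frame(gene = genes[g], owner_type = tps[1],
               mean_expr_owner = type_means[g, tps[1]],
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(gene = character(0), owner_type = character(0),
                      mean_expr_owner = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build the full marker catalog
#'
#' Combines type-level and subtype-level marker calls into one catalog
#' with a unique owner per gene. A gene qualifying at both levels is kept
#' at the type level (the broader claim); remaining subtype candidates are
#' resolved by highest expression.
#'
#' @param sc [sc_data] object.
#' @param pairwise result of [pairwise_subtype_de()]; computed when NULL.
#' @param alpha significance threshold.
#' @param allowed_losses subtype-vote slack (default 2).
#' @param mode condition (ii) mode for type markers.
#' @return data.frame of class `marker_catalog`: gene, level
#'   ("type"|"subtype"), owner_type, owner_subtype (NA for type level),
#'   wins (NA for type level), mean_expr_owner.
#' @export
derive_marker_catalog <- function(sc, pairwise = NULL, alpha = 0.05,
                                  allowed_losses = 2, mode = "each") {
  if (is.null(pairwise)) pairwise <- pairwise_subtype_de(sc)
  type_m <- call_type_markers(sc, pairwise, alpha, mode)
  cand <- call_subtype_markers(pairwise, alpha, allowed_losses)
  sub_m <- resolve_multiple_markers(cand, sc)
  sub_m <- sub_m[!(sub_m$gene %in% type_m$gene), , drop = FALSE]
  cat_type <- if (nrow(type_m)) data.frame(
    gene = type_m$gene, level = "type", owner_type = type_m$owner_type,
    owner_subtype = NA_character_, wins = NA_integer_,
    mean_expr_owner = type_m$mean_expr_owner, stringsAsFactors = FALSE)
    else NULL
  cat_sub <- if (nrow(sub_m)) data.frame(
    gene = sub_m$gene, level = "subtype",
    owner_type = unname(sc$nesting[sub_m$owner_subtype]),
    owner_subtype = sub_m$owner_subtype, wins = as.integer(sub_m$wins),
    mean_expr_owner = sub_m$mean_expr_owner, stringsAsFactors = FALSE)
    else NULL
  out <- rbind(cat_type, cat_sub)
  if (is.null(out))
    out <- data.frame(gene = character(0), level = character(0),
                      owner_type = character(0), owner_subtype = character(0),
                      wins = integer(0), mean_expr_owner = numeric(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$owner_type, out$level, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_catalog", "data.frame")
  out
}

#' Combined per-type marker lists and the non-marker set
#'
#' The combined list of a cell type is the union of its type-level markers
#' and the subtype-level markers of its nested subtypes. Genes owned by no
#' type form the non-marker set (the depletion control of the GO/cell-type
#' interaction matrix).
#'
#' @param catalog [derive_marker_catalog()] result.
#' @param all_genes the gene universe (e.g. rownames of the SC matrix).
#' @return named list of per-type gene vectors, with the non-marker set as
#'   attribute `non_markers`.
#' @export
combined_type_marker_lists <- function(catalog, all_genes) {
  types <- sort(unique(catalog$owner_type))
  lists <- lapply(types, function(tp)
    sort(unique(catalog$gene[catalog$owner_type == tp])))
  names(lists) <- types
  attr(lists, "non_markers") <- setdiff(all_genes, catalog$gene)
  lists
}
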