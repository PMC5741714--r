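#' Canonical stage-pair comparison labels
#'
#' All unordered stage pairs in fixed order, earlier stage first:
#' `E15_vs_P1`, `E15_vs_P7`, ..., `P15_vs_P30` (10 labels for 5 stages).
#'
#' @param stages ordered stage labels.
#' @return character vector of comparison labels.
#' @export
stage_pair_labels <- function(stages = STAGES) {
  n <- length(stages)
  out <- character(0)
  for (i in seq_len(n - 1))
    for (j in seq((i + 1), n))
      out <- c(out, paste0(stages[i], "_vs_", stages[j]))
  out
}

## de_results: named list of de_result data.frames, names = comparison labels
de_z_lookup <- function(de_results, comparisons, transcripts) {
  missing_cmp <- setdiff(comparisons, names(de_results))
  if (length(missing_cmp))
    stopf("missing comparison(s): %s", paste(missing_cmp, collapse = ", "))
  z <- matrix(NA_real_, length(transcripts), length(comparisons),
              dimnames = list(transcripts, comparisons))
  for (cmp in comparisons) {
    tab <- de_results[[cmp]]
    idx <- match(transcripts, tab$gene)
    if (anyNA(idx))
      stopf("transcript(s) absent from comparison %s: %s", cmp,
            paste(utils::head(transcripts[is.na(idx)], 5), collapse = ", "))
    z[, cmp] <- tab$z[idx]
  }
  z
}

#' Assemble the signed Z-score matrix
#'
#' Builds the m x n matrix of signed Z-scores for the selected transcripts
#' over all stage-pair comparisons, columns in canonical order.
#'
#' @param de_results named list of [nb_wald_test()] results, one per
#'   stage-pair comparison, names matching [stage_pair_labels()].
#' @param selected transcripts to keep as rows (e.g. from
#'   [select_developmental()]).
#' @param stages ordered stage labels.
#' @return numeric matrix, rows = selected transcripts, columns = the
#'   canonical comparisons.
#' @export
build_z_matrix <- function(de_results, selected, stages = STAGES) {
  if (!length(selected)) stopf("no transcripts selected")
  de_z_lookup(de_results, stage_pair_labels(stages), selected)
}

#' Select developmentally regulated transcripts
#'
#' A transcript is developmentally regulated when |Z| meets the threshold
#' in at least `min_comparisons` of the stage-pair comparisons
#' (direction-agnostic). The default threshold Z = 5 corresponds to an
#' adjusted p-value of about 3e-7.
#'
#' @param de_results named list of DE tables (one per stage pair).
#' @param z_threshold minimum |Z|.
#' @param min_comparisons minimum number of comparisons reaching it.
#' @param stages ordered stage labels.
#' @return character vector of selected transcript ids.
#' @export
select_developmental <- function(de_results, z_threshold = 5,
                                 min_comparisons = 2, stages = STAGES) {
  cmp <- stage_pair_labels(stages)
  transcripts <- de_results[[1]]$gene
  z <- de_z_lookup(de_results, cmp, transcripts)
  hits <- rowSums(abs(z) >= z_threshold)
  transcripts[hits >= min_comparisons]
}

#' Percentile discretization of the Z matrix
#'
#' Reduces every value to one of five levels {-2, -1, 0, +1, +2} delimited
#' by the 10th, 30th, 70th and 90th percentiles. Levels are assigned by
#' half-open intervals closed on the left: (-Inf, q10) -> -2,
#' [q10, q30) -> -1, [q30, q70) -> 0, [q70, q90) -> +1, [q90, Inf) -> +2.
#' Percentiles use the linear-interpolation definition (R type 7) and are
#' computed per column by default, since every comparison has its own Z
#' scale; `scope = "global"` pools the whole matrix instead.
#'
#' @param z numeric matrix (transcripts x comparisons).
#' @param percentiles the four cutpoint percentiles, increasing, in (0,100).
#' @param scope "column" (default) or "global".
#' @return integer matrix of levels with attribute `cutpoints` (a 4 x n
#'   matrix of the cutpoints used per column).
#' @export
discretize <- function(z, percentiles = c(10, 30, 70, 90),
                       scope = c("column", "global")) {
  scope <- match.arg(scope)
  if (length(percentiles) != 4 || is.unsorted(percentiles) ||
      any(percentiles <= 0 | percentiles >= 100))
    stopf("percentiles must be four increasing values in (0, 100)")
  if (nrow(z) < 10) stopf("need at least 10 rows for percentile cutpoints")
  probs <- percentiles / 100
  lev_one <- function(x, q) {
    if (diff(range(x)) == 0 || diff(range(q)) == 0) {
      warnf("constant column: all levels set to 0")
      return(rep(0L, length(x)))
    }
    as.integer(findInterval(x, q)) - 2L
  }
  if (scope == "global") {
    q <- stats::quantile(z, probs, type = 7, names = FALSE)
    lev <- apply(z, 2, lev_one, q = q)
    cut_mat <- matrix(q, 4, ncol(z))
  } else {
    cut_mat <- apply(z, 2, stats::quantile, probs = probs, type = 7,
                     names = FALSE)
    lev <- vapply(seq_len(ncol(z)),
                  function(j) lev_one(z[, j], cut_mat[, j]),
                  integer(nrow(z)))
  }
  dimnames(lev) <- dimnames(z)
  rownames(cut_mat) <- paste0("q", percentiles)
  colnames(cut_mat) <- colnames(z)
  attr(lev, "cutpoints") <- cut_mat
  lev
}

#' Count real trajectories (optimal cluster number)
#'
#' A trajectory is the tuple of discretized levels a transcript takes over
#' all comparisons; it is real when it collects at least `min_el` of all
#' transcripts. The number of real trajectories is the estimated number of
#' clusters.
#'
#' @param d discretized level matrix from [discretize()].
#' @param min_el minimal fraction of elements per real trajectory (paper
#'   default 1%).
#' @return list with `k` (count of real trajectories) and `census`, a
#'   data.frame (trajectory, count, is_real) sorted by decreasing count.
#' @export
count_real_trajectories <- function(d, min_el = 0.01) {
  if (min_el <= 0 || min_el >= 1) stopf("min_el must be in (0, 1)")
  keys <- apply(d, 1, paste, collapse = ",")
  tab <- sort(table(keys), decreasing = TRUE)
  threshold <- ceiling(min_el * nrow(d))
  census <- data.frame(trajectory = names(tab),
                       count = as.integer(tab),
                       is_real = as.integer(tab) >= threshold,
                       row.names = NULL, stringsAsFactors = FALSE)
  k <- sum(census$is_real)
  if (k == 0)
    stopf("no trajectory reaches min_el = %g of %d elements; lower min_el",
          min_el, nrow(d))
  list(k = k, census = census, threshold = threshold)
}

## k-means++ seeding: D^2-weighted center choices.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[i + 1] <- sample.int(n, 1)
    } else {
      centers[i + 1] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means partition of the Z matrix
#'
#' Clusters the original (not discretized) signed Z values into `k` groups
#' by k-means with the squared-Euclidean objective, k-means++ seeding, and
#' the best of `n_restarts` runs by total within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param z numeric matrix (transcripts x comparisons).
#' @param k number of clusters, at most the number of distinct rows.
#' @param seed integer seed for the restarts.
#' @param n_restarts independent k-means++ starts (default 50).
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector 1..k), `centers` (k x n), `k`, `tot_withinss`.
#' @export
kmeans_partition <- function(z, k, seed = 1, n_restarts = 50) {
  distinct <- nrow(unique(z))
  if (k > distinct)
    stopf("k = %d exceeds the %d distinct rows", k, distinct)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(z, k)
      ## duplicate seeds would make kmeans fail; nudge exact duplicates
      dup <- duplicated(centers)
      if (any(dup))
        centers[dup, ] <- centers[dup, , drop = FALSE] +
          stats::rnorm(sum(dup) * ncol(centers), sd = 1e-6)
      km <- suppressWarnings(stats::kmeans(z, centers = centers,
                                           iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(cluster = stats::setNames(best$cluster, rownames(z)),
                 centers = best$centers, k = k,
                 tot_withinss = best$tot.withinss),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d transcripts in %d clusters\n",
              length(x$cluster), x$k))
  print(table(x$cluster))
  invisible(x)
}

#' Classify the temporal direction of a cluster
#'
#' Classifies a five-stage mean expression profile (normalized to E15) as
#' decreasing, increasing, or transient: decreasing when
#' `log2(P30/E15) <= -t`, increasing when `>= +t`, transient otherwise.
#'
#' @param profile positive numeric vector of length 5 (stage means).
#' @param t log2 threshold on the end-to-start ratio (default 1).
#' @return one of "decreasing", "increasing", "transient".
#' @export
classify_direction <- function(profile, t = 1) {
  if (length(profile) != length(STAGES))
    stopf("profile must have %d stage values", length(STAGES))
  if (any(profile <= 0)) stopf("profile values must be positive")
  lr <- log2(profile[length(profile)] / profile[1])
  if (lr <= -t) "decreasing" else if (lr >= t) "increasing" else "transient"
}

#' Per-cluster mean stage profiles
#'
#' Mean normalized expression per stage for every cluster, each gene first
#' scaled to its own E15 mean (a 0.5 pseudocount on normalized means guards
#' silent stages), then averaged within the cluster.
#'
#' @param bulk [bulk_data] object.
#' @param assignment [kmeans_partition()] result (or named cluster vector).
#' @param size_factors optional; estimated from all samples when NULL.
#' @return matrix clusters x stages of E15-normalized mean profiles.
#' @export
cluster_stage_profiles <- function(bulk, assignment, size_factors = NULL) {
  cl <- if (inherits(assignment, "cluster_assignment")) assignment$cluster
        else assignment
  if (is.null(size_factors)) size_factors <- estimate_size_factors(bulk)
  norm <- sweep(bulk$counts, 2, size_factors, "/")
  stage <- factor(bulk$samples$stage, STAGES)
  stage_means <- vapply(STAGES, function(s)
    rowMeans(norm[, stage == s, drop = FALSE]), numeric(nrow(norm)))
  stage_means <- stage_means + 0.5
  genes <- intersect(names(cl), rownames(stage_means))
  rel <- stage_means[genes, , drop = FALSE] / stage_means[genes, "E15"]
  out <- t(vapply(sort(unique(cl)), function(k)
    colMeans(rel[names(cl)[cl == k], , drop = FALSE]),
    numeric(length(STAGES))))
  rownames(out) <- paste0("C", sort(unique(cl)))
  out
}

#' Full trajectory clustering of a bulk time course
#'
#' Runs the composite clustering: pairwise DE over all stage pairs,
#' selection of developmentally regulated transcripts, Z-matrix assembly,
#' percentile discretization, trajectory counting for the cluster number,
#' k-means partition, and direction classification of every cluster.
#'
#' @param bulk [bulk_data] object.
#' @param z_threshold,min_comparisons selection rule (defaults 5 and 2).
#' @param percentiles discretization cutpoints.
#' @param min_el real-trajectory threshold (default 0.01).
#' @param seed seed for the k-means restarts.
#' @param n_restarts k-means restarts.
#' @param direction_t log2 threshold for direction classes.
#' @param de_results optionally, precomputed DE tables (named by
#'   comparison) with the [nb_wald_test()] schema; computed when NULL.
#' @return list of class `trajectory_clustering` with elements
#'   `de_results`, `selected`, `z`, `levels`, `census`, `k`, `assignment`,
#'   `profiles`, `directions`.
#' @export
trajectory_cluster <- function(bulk, z_threshold = 5, min_comparisons = 2,
                               percentiles = c(10, 30, 70, 90),
                               min_el = 0.01, seed = 1, n_restarts = 50,
                               direction_t = 1, de_results = NULL) {
  sf <- estimate_size_factors(bulk)
  if (is.null(de_results)) {
    de_results <- bulk_pairwise_de(bulk, size_factors = sf)
  }
  selected <- select_developmental(de_results, z_threshold, min_comparisons)
  if (!length(selected)) stopf("no developmentally regulated transcript")
  z <- build_z_matrix(de_results, selected)
  lev <- discretize(z, percentiles)
  traj <- count_real_trajectories(lev, min_el)
  assignment <- kmeans_partition(z, traj$k, seed = seed,
                                 n_restarts = n_restarts)
  profiles <- cluster_stage_profiles(bulk, assignment, sf)
  directions <- vapply(seq_len(traj$k), function(i)
    classify_direction(profiles[i, ], t = direction_t), character(1))
  names(directions) <- rownames(profiles)
  structure(list(de_results = de_results, selected = selected, z = z,
                 levels = lev, census = traj$census, k = traj$k,
                 assignment = assignment, profiles = profiles,
                 directions = directions),
            class = "trajectory_clustering")
}

#' Pairwise DE over all stage pairs of a bulk time course
#'
#' One [nb_wald_test()] per unordered stage pair (10 comparisons for 5
#' stages), the earlier stage as group A.
#'
#' @param bulk [bulk_data] object.
#' @param size_factors optional; estimated once from all samples when NULL.
#' @param ... passed to [nb_wald_test()].
#' @return named list of DE tables keyed by comparison label.
#' @export
bulk_pairwise_de <- function(bulk, size_factors = NULL, ...) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(bulk)
  stage <- bulk$samples$stage
  present <- STAGES[STAGES %in% stage]
  if (any(table(stage) < 2))
    stopf("stage(s) with fewer than 2 replicates: %s",
          paste(names(which(table(stage) < 2)), collapse = ", "))
  out <- list()
  for (i in seq_len(length(present) - 1)) {
    for (j in seq((i + 1), length(present))) {
      a <- which(stage == present[i]); b <- which(stage == present[j])
      lab <- paste0(present[i], "_vs_", present[j])
      out[[lab]] <- nb_wald_test(bulk$counts, a, b,
                                 size_factors = size_factors[c(a, b)],
                                 comparison = lab, ...)
    }
  }
  out
}
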