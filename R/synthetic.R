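#' Default temporal archetypes of the developmental time course
#'
#' Thirteen well-separated five-stage expression archetypes (4 decreasing,
#' 4 increasing, 5 transient), the simulator's stated world for the bulk
#' time course. Profiles are stored as expression multipliers per stage
#' with geometric mean 1; stage-to-stage contrasts lie on a half-log2 grid
#' chosen so that, in every stage-pair comparison, the archetype masses
#' group into 10/20/40/20/10% blocks whose boundaries coincide with the
#' 10/30/70/90 percentile cutpoints of the discretization, with effective
#' Z-score gaps of about 4 or more at every cut. This is what makes the
#' planted cluster number recoverable by trajectory counting.
#'
#' @return data.frame with columns `archetype`, `direction`, `proportion`,
#'   and `E15`,`P1`,`P7`,`P15`,`P30` (profile multipliers).
#' @export
default_archetypes <- function() {
  ## half-log2 stage offsets (see package vignette for the construction)
  h <- rbind(
    A01 = c(0,   8,   0,   0,  -8),   # peak at P1 then silenced
    A02 = c(0,  -4,  -4, -21,  -4),   # repressed, deep dip at P15
    A03 = c(0,   0, -12, -12, -12),   # silenced from P7
    A04 = c(0,   0,   0, -12, -12),   # silenced from P15
    A05 = c(0,  -8,   0,   0,   8),   # dip at P1 then activated
    A06 = c(0,   4,   4,  21,   4),   # activated, peak at P15
    A07 = c(0,   0,  12,  12,  12),   # activated from P7
    A08 = c(0,   0,   0,  12,  12),   # activated from P15
    A09 = c(0,  12,  21,  10,   0),   # hill peaking at P7
    A10 = c(0, -12, -21, -10,   0),   # valley at P7
    A11 = c(0,   0,  12,   0,   0),   # spike at P7
    A12 = c(0,   0, -12,   0,   0),   # dip at P7
    A13 = c(0,   0,   0,   5,   0))   # mild bump at P15
  colnames(h) <- STAGES
  ## profiles are centred on their geometric mean so that no stage of any
  ## archetype falls to unmeasurably low counts (the baseline law then sets
  ## the per-gene geometric-mean expression, not the peak)
  h <- h - rowMeans(h)
  prof <- 2^(h / 2)
  direction <- c("decreasing", "decreasing", "decreasing", "decreasing",
                 "increasing", "increasing", "increasing", "increasing",
                 "transient", "transient", "transient", "transient",
                 "transient")
  proportion <- c(.10, .10, .05, .05, .10, .10, .05, .05,
                  .10, .10, .05, .05, .10)
  data.frame(archetype = rownames(h), direction = direction,
             proportion = proportion, prof, row.names = NULL,
             stringsAsFactors = FALSE)
}

validate_archetypes <- function(archetypes) {
  need <- c("archetype", "proportion", STAGES)
  if (!all(need %in% names(archetypes)))
    stopf("archetype table needs columns: %s", paste(need, collapse = ", "))
  prof <- as.matrix(archetypes[, STAGES])
  if (any(prof <= 0)) stopf("archetype profiles must be positive")
  if (any(archetypes$proportion <= 0)) stopf("proportions must be positive")
  tot <- sum(archetypes$proportion)
  if (tot > 1 + 1e-8)
    stopf("archetype proportions sum to %.3f > 1", tot)
  invisible(archetypes)
}

#' Simulate a bulk developmental time course with planted archetypes
#'
#' Draws negative-binomial gene counts over the five stages (at least
#' `reps_per_stage` replicates each) with per-gene baseline means, planted
#' temporal archetypes, and log-normal library-size jitter. Genes not
#' assigned to an archetype (when proportions sum to less than 1) follow
#' the flat null profile. Gene-to-archetype assignment is deterministic
#' (largest-remainder apportionment), so realized proportions match the
#' requested ones exactly.
#'
#' @param archetypes archetype table as from [default_archetypes()].
#' @param n_genes number of simulated genes.
#' @param reps_per_stage replicates per stage (>= 2; paper design >= 3).
#' @param baseline list(meanlog, sdlog) of the log-normal law for each
#'   gene's geometric-mean expression across stages. The default keeps the
#'   planted genes in a regime where Wald significance is comparable
#'   across a discretization class (see the methods vignette).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param libsize_sigma sd of the log-normal per-sample size-factor jitter
#'   (0 disables it).
#' @param gene_length_range transcript lengths are drawn uniformly (in bp)
#'   from this range, for RPKM support.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `bulk` ([bulk_data]) and `truth` (data.frame: gene,
#'   archetype (NA for null genes), direction, baseline, dispersion), plus
#'   `size_factors_true`.
#' @export
simulate_bulk <- function(archetypes = default_archetypes(),
                          n_genes = 10000, reps_per_stage = 3,
                          baseline = list(meanlog = log(3000), sdlog = 0.25),
                          dispersion = 0.1, libsize_sigma = 0.2,
                          gene_length_range = c(500, 5000), seed = 1) {
  validate_archetypes(archetypes)
  if (reps_per_stage < 2)
    stopf("reps_per_stage must be >= 2 for testable DE")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  n_arch <- nrow(archetypes)
  props <- archetypes$proportion
  null_prop <- 1 - sum(props)
  counts_per <- apportion(n_genes, c(props, null_prop))
  arch_of <- rep(c(archetypes$archetype, NA_character_), counts_per)

  n_samples <- length(STAGES) * reps_per_stage
  samples <- data.frame(
    sample = paste0(rep(STAGES, each = reps_per_stage), "_r",
                    rep(seq_len(reps_per_stage), length(STAGES))),
    stage = rep(STAGES, each = reps_per_stage),
    replicate = rep(seq_len(reps_per_stage), length(STAGES)),
    stringsAsFactors = FALSE)

  prof <- rbind(as.matrix(archetypes[, STAGES]),
                matrix(1, 1, length(STAGES),
                       dimnames = list(NULL, STAGES)))
  rownames(prof) <- c(archetypes$archetype, ".null")
  arch_idx <- match(ifelse(is.na(arch_of), ".null", arch_of),
                    rownames(prof))

  out <- with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, baseline$meanlog, baseline$sdlog)
    sf_true <- if (libsize_sigma > 0)
      stats::rlnorm(n_samples, 0, libsize_sigma) else rep(1, n_samples)
    mu <- base_mu * prof[arch_idx, samples$stage, drop = FALSE]
    mu <- sweep(mu, 2, sf_true, "*")
    k <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    lengths <- round(stats::runif(n_genes, gene_length_range[1],
                                  gene_length_range[2]))
    list(k = k, base_mu = base_mu, sf_true = sf_true, lengths = lengths)
  })
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  dimnames(out$k) <- list(gene_ids, samples$sample)
  names(out$lengths) <- gene_ids

  dir_of <- archetypes$direction[match(arch_of, archetypes$archetype)]
  truth <- data.frame(gene = gene_ids, archetype = arch_of,
                      direction = dir_of, baseline = out$base_mu,
                      dispersion = dispersion, stringsAsFactors = FALSE)
  list(bulk = bulk_data(out$k, samples, gene_lengths = out$lengths),
       truth = truth, size_factors_true = out$sf_true)
}

#' Default nested cell-type / subtype structure
#'
#' Eleven cell types with 47 subtypes (subtype counts 7,6,5,5,4,4,4,3,3,3,3),
#' mirroring the granularity of the adult cortex/hippocampus single-cell
#' atlas used for marker discovery.
#'
#' @return named list mapping type to its subtype labels.
#' @export
default_celltypes <- function() {
  n_sub <- c(7, 6, 5, 5, 4, 4, 4, 3, 3, 3, 3)
  types <- sprintf("T%02d", seq_along(n_sub))
  stats::setNames(lapply(seq_along(n_sub), function(i)
    sprintf("%s_S%d", types[i], seq_len(n_sub[i]))), types)
}

#' Simulate a labeled single-cell UMI matrix with planted markers
#'
#' Draws sparse NB UMI counts for cells with nested type/subtype labels.
#' Planted type markers are up-regulated `fold_change`-fold in every cell
#' of the owning type; planted subtype markers only in the owning subtype.
#' Library sizes vary log-normally around `depth`.
#'
#' @param celltypes named list type -> subtype labels
#'   (default [default_celltypes()]).
#' @param cells_per_subtype cells simulated per subtype.
#' @param n_genes total genes.
#' @param markers_per_type,markers_per_subtype planted markers per class.
#' @param fold_change expression multiplier in the owning population; must
#'   be > 1 when markers are planted (1 gives a null simulation and is
#'   flagged in the truth table).
#' @param depth mean UMIs per cell.
#' @param dispersion NB dispersion of UMI counts (default 0.5).
#' @param libsize_sigma sd of log-normal per-cell depth jitter.
#' @param gene_ids optional gene identifiers (length `n_genes`), e.g. a
#'   subset of the bulk gene names so that the two modalities share a
#'   namespace; marker roles are assigned to a seeded random permutation
#'   of them. Default: fresh ids g00001...
#' @param seed integer seed.
#' @return list with `sc` ([sc_data]) and `truth` (data.frame: gene, role
#'   ("none", "type_marker", "subtype_marker"), owner, fold_change).
#' @export
simulate_sc <- function(celltypes = default_celltypes(),
                        cells_per_subtype = 50, n_genes = 2000,
                        markers_per_type = 10, markers_per_subtype = 5,
                        fold_change = 8, depth = 2000, dispersion = 0.5,
                        libsize_sigma = 0.3, gene_ids = NULL, seed = 1) {
  if (fold_change < 1) stopf("fold_change must be >= 1")
  n_marked <- markers_per_type > 0 || markers_per_subtype > 0
  if (fold_change == 1 && n_marked)
    warnf("fold_change = 1: planted markers carry no signal (null run)")
  subtypes <- unlist(celltypes, use.names = FALSE)
  types <- rep(names(celltypes), lengths(celltypes))
  if (any(cells_per_subtype < 2)) stopf("need >= 2 cells per subtype")
  n_sub <- length(subtypes)
  need <- markers_per_type * length(celltypes) + markers_per_subtype * n_sub
  if (need > n_genes)
    stopf("%d marker genes requested but only %d genes", need, n_genes)

  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
  } else {
    if (length(gene_ids) != n_genes)
      stopf("gene_ids must have length n_genes (%d)", n_genes)
    if (anyDuplicated(gene_ids)) stopf("gene_ids must be unique")
    ## seeded shuffle so marker roles are not tied to the input order
    gene_ids <- with_seed(seed + 1L, sample(gene_ids))
  }
  role <- rep("none", n_genes)
  owner <- rep(NA_character_, n_genes)
  idx <- 1
  for (tp in names(celltypes)) {
    if (markers_per_type > 0) {
      ii <- idx:(idx + markers_per_type - 1)
      role[ii] <- "type_marker"; owner[ii] <- tp
      idx <- idx + markers_per_type
    }
    for (sb in celltypes[[tp]]) {
      if (markers_per_subtype > 0) {
        ii <- idx:(idx + markers_per_subtype - 1)
        role[ii] <- "subtype_marker"; owner[ii] <- sb
        idx <- idx + markers_per_subtype
      }
    }
  }

  cell_sub <- rep(subtypes, each = cells_per_subtype)
  cell_type <- rep(types, each = cells_per_subtype)
  n_cells <- length(cell_sub)
  cells <- data.frame(cell = sprintf("c%05d", seq_len(n_cells)),
                      type = cell_type, subtype = cell_sub,
                      stringsAsFactors = FALSE)

  out <- with_seed(seed, {
    rel <- stats::rlnorm(n_genes, 0, 1.2)
    rel <- rel / sum(rel)
    depth_cell <- depth * stats::rlnorm(n_cells, 0, libsize_sigma)
    ## per-gene per-cell mean: baseline relative abundance, boosted in the
    ## owning population
    boost <- matrix(1, n_genes, n_cells)
    if (fold_change > 1) {
      for (g in which(role == "type_marker"))
        boost[g, cell_type == owner[g]] <- fold_change
      for (g in which(role == "subtype_marker"))
        boost[g, cell_sub == owner[g]] <- fold_change
    }
    mu <- (rel * boost) %*% diag(depth_cell)
    k <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    k
  })
  dimnames(out) <- list(gene_ids, cells$cell)
  truth <- data.frame(gene = gene_ids, role = role, owner = owner,
                      fold_change = ifelse(role == "none", NA, fold_change),
                      stringsAsFactors = FALSE)
  list(sc = sc_data(out, cells), truth = truth)
}

#' Simulate a gene-set collection with controlled overlap
#'
#' Builds a GMT-writable collection: `n_planted` terms drawn to overlap a
#' given truth group at fraction `planted_overlap` (rest of the term drawn
#' at random from the universe), plus `n_random` fully random terms.
#'
#' @param universe character vector of gene ids.
#' @param truth_groups named list of gene sets (e.g. planted marker sets or
#'   archetype members); may be empty when only random terms are wanted.
#' @param n_planted planted terms per truth group.
#' @param n_random additional random terms.
#' @param planted_overlap fraction of each planted term drawn from its
#'   truth group (0 gives uniform random terms).
#' @param size_law list(meanlog, sdlog) of the log-normal term-size law.
#' @param seed integer seed.
#' @return named list of gene sets with attributes `universe` and `truth`
#'   (data.frame term -> source group or NA).
#' @export
simulate_genesets <- function(universe, truth_groups = list(),
                              n_planted = 1, n_random = 20,
                              planted_overlap = 0.75,
                              size_law = list(meanlog = log(40), sdlog = 0.5),
                              seed = 1) {
  if (!length(universe)) stopf("empty universe")
  if (planted_overlap < 0 || planted_overlap > 1)
    stopf("planted_overlap must be in [0, 1]")
  with_seed(seed, {
    sets <- list(); src <- character(0)
    draw_size <- function() {
      s <- max(5, round(stats::rlnorm(1, size_law$meanlog, size_law$sdlog)))
      if (s > length(universe))
        stopf("term size %d exceeds universe size %d", s, length(universe))
      s
    }
    for (grp in names(truth_groups)) {
      pool <- intersect(truth_groups[[grp]], universe)
      for (i in seq_len(n_planted)) {
        sz <- draw_size()
        n_in <- min(round(planted_overlap * sz), length(pool))
        inside <- sample(pool, n_in)
        outside <- sample(setdiff(universe, inside), sz - n_in)
        nm <- sprintf("%s_term%d", grp, i)
        sets[[nm]] <- sort(c(inside, outside))
        src <- c(src, grp)
      }
    }
    for (i in seq_len(n_random)) {
      nm <- sprintf("random_term%d", i)
      sets[[nm]] <- sort(sample(universe, draw_size()))
      src <- c(src, NA_character_)
    }
    attr(sets, "universe") <- universe
    attr(sets, "truth") <- data.frame(term = names(sets), source = src,
                                      stringsAsFactors = FALSE)
    sets
  })
}
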