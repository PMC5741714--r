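#' Default run configuration
#'
#' All thresholds of the pipeline with their defaults: selection
#' (`z_threshold` 5, `min_comparisons` 2), trajectory counting (`min_el`
#' 0.01), marker discovery (`alpha` 0.05, `allowed_losses` 2), direction
#' classification (`direction_t` 1 log2 unit), and the simulation sizes
#' used when no input files are given.
#'
#' @param ... overrides for any field.
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    ## inputs: either file paths or NULL to simulate
    bulk_counts = NULL, sample_sheet = NULL, gene_lengths = NULL,
    sc_counts = NULL, cell_sheet = NULL, gmt = NULL,
    ## simulation sizes (used when the corresponding input is NULL)
    n_genes = 2000, reps_per_stage = 3,
    sc_n_genes = 1200, cells_per_subtype = 20,
    sc_types = 4, sc_subtypes_per_type = 2,
    markers_per_type = 8, markers_per_subtype = 4, fold_change = 8,
    ## thresholds
    z_threshold = 5, min_comparisons = 2, min_el = 0.01,
    alpha = 0.05, allowed_losses = 2, direction_t = 1,
    term_alpha = 0.01, n_restarts = 50,
    ## bookkeeping
    seed = 1, outdir = "trajmark_run",
    stages = c("simulate", "de", "cluster", "markers", "enrich", "drivers"))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  if (cfg$min_el <= 0 || cfg$min_el >= 1)
    stopf("min_el must be in (0, 1), got %s", cfg$min_el)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must be in (0, 1)")
  if (cfg$z_threshold <= 0) stopf("z_threshold must be positive")
  if (cfg$min_comparisons < 1) stopf("min_comparisons must be >= 1")
  if (cfg$allowed_losses < 0) stopf("allowed_losses must be >= 0")
  for (f in c("bulk_counts", "sample_sheet", "sc_counts", "cell_sheet",
              "gmt")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("config field %s: file not found: %s", f, cfg[[f]])
  }
  cfg
}

#' Read a flat key-value config file
#'
#' YAML-compatible flat syntax: one `key: value` per line, `#` comments,
#' blank lines ignored. Values are parsed as numbers when numeric.
#'
#' @param path config file.
#' @return `run_config` list (unknown keys are an error).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stopf("malformed config line: %s", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!is.na(num)) num else if (val == "null") NULL else val
  }
  do.call(default_config, kv)
}

sc_structure_from_config <- function(cfg) {
  types <- sprintf("T%02d", seq_len(cfg$sc_types))
  stats::setNames(lapply(types, function(tp)
    sprintf("%s_S%d", tp, seq_len(cfg$sc_subtypes_per_type))), types)
}

#' Run the full pipeline
#'
#' Executes simulate (when inputs are not given) -> pairwise DE ->
#' selection -> discretization -> trajectory counting -> k-means ->
#' direction classification -> marker discovery -> enrichments -> driver
#' prediction, writing every artifact as TSV/GMT under `cfg$outdir`
#' together with a JSON run manifest carrying the config echo and MD5
#' checksums of every output.
#'
#' @param cfg [default_config()] result (or overrides via `...`).
#' @param ... passed to [default_config()] when `cfg` is NULL.
#' @return the manifest, invisibly (list with `config`, `checksums`,
#'   `warnings`, `version`).
#' @export
run_all <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- default_config(...)
  cfg <- validate_config(cfg)
  if (!is.null(cfg$sc_counts) != !is.null(cfg$cell_sheet))
    stopf("sc_counts and cell_sheet must be given together")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  note <- function(...) warns <<- c(warns, sprintf(...))
  seeds <- derive_seeds(cfg$seed, 4)
  stage_fail <- function(stage, e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))

  ## ---- inputs / simulation -------------------------------------------
  truth_bulk <- truth_sc <- NULL
  if (is.null(cfg$bulk_counts)) {
    sim <- tryCatch(simulate_bulk(n_genes = cfg$n_genes,
                                  reps_per_stage = cfg$reps_per_stage,
                                  seed = seeds[1]),
                    error = function(e) stage_fail("simulate", e))
    bulk <- sim$bulk; truth_bulk <- sim$truth
    write_counts_tsv(bulk$counts, file.path(cfg$outdir, "bulk_counts.tsv"))
    write_tsv(bulk$samples, file.path(cfg$outdir, "samples.tsv"))
    write_tsv(data.frame(gene = names(bulk$gene_lengths),
                         length = unname(bulk$gene_lengths)),
              file.path(cfg$outdir, "gene_lengths.tsv"))
    write_tsv(truth_bulk, file.path(cfg$outdir, "truth_bulk.tsv"))
  } else {
    bulk <- read_bulk_tsv(cfg$bulk_counts, cfg$sample_sheet,
                          cfg$gene_lengths)
  }
  if (is.null(cfg$sc_counts)) {
    ## share the bulk gene namespace so markers can intersect clusters
    shared <- with_seed(seeds[4], sample(rownames(bulk$counts),
                                         min(cfg$sc_n_genes,
                                             nrow(bulk$counts))))
    scs <- tryCatch(simulate_sc(celltypes = sc_structure_from_config(cfg),
                                gene_ids = shared,
                                n_genes = length(shared),
                                cells_per_subtype = cfg$cells_per_subtype,
                                markers_per_type = cfg$markers_per_type,
                                markers_per_subtype = cfg$markers_per_subtype,
                                fold_change = cfg$fold_change,
                                seed = seeds[2]),
                    error = function(e) stage_fail("simulate", e))
    sc <- scs$sc; truth_sc <- scs$truth
    write_counts_tsv(sc$counts, file.path(cfg$outdir, "sc_counts.tsv"))
    write_tsv(sc$cells, file.path(cfg$outdir, "cells.tsv"))
    write_tsv(truth_sc, file.path(cfg$outdir, "truth_sc.tsv"))
  } else {
    sc <- read_sc_tsv(cfg$sc_counts, cfg$cell_sheet)
  }

  ## ---- bulk clustering ------------------------------------------------
  tc <- tryCatch(
    trajectory_cluster(bulk, z_threshold = cfg$z_threshold,
                       min_comparisons = cfg$min_comparisons,
                       min_el = cfg$min_el, seed = seeds[3],
                       n_restarts = cfg$n_restarts,
                       direction_t = cfg$direction_t),
    error = function(e) stage_fail("cluster", e))
  write_de_tables(tc$de_results, file.path(cfg$outdir, "de"))
  write_counts_tsv(tc$z, file.path(cfg$outdir, "zmatrix.tsv"))
  write_counts_tsv(tc$levels, file.path(cfg$outdir, "discretized.tsv"))
  write_tsv(tc$census, file.path(cfg$outdir, "trajectory_census.tsv"))
  cl_df <- data.frame(transcript = names(tc$assignment$cluster),
                      cluster_id = unname(tc$assignment$cluster),
                      direction = unname(
                        tc$directions[paste0("C",
                                             tc$assignment$cluster)]),
                      stringsAsFactors = FALSE)
  write_tsv(cl_df, file.path(cfg$outdir, "clusters.tsv"))
  write_counts_tsv(tc$assignment$centers,
                   file.path(cfg$outdir, "centroids.tsv"), "cluster")
  write_counts_tsv(tc$profiles, file.path(cfg$outdir, "profiles.tsv"),
                   "cluster")

  ## ---- markers --------------------------------------------------------
  catalog <- tryCatch({
    pw <- pairwise_subtype_de(sc)
    derive_marker_catalog(sc, pw, alpha = cfg$alpha,
                          allowed_losses = cfg$allowed_losses)
  }, error = function(e) stage_fail("markers", e))
  write_tsv(catalog, file.path(cfg$outdir, "markers.tsv"))
  lists <- combined_type_marker_lists(catalog, rownames(sc$counts))
  gmt_sets <- c(lists, list(non_marker = attr(lists, "non_markers")))
  write_gmt(gmt_sets, file.path(cfg$outdir, "marker_lists.gmt"))

  ## ---- enrichments ----------------------------------------------------
  universe <- rownames(bulk$counts)[rowSums(bulk$counts > 0) >= 2]
  enr <- tryCatch(
    cluster_marker_enrichment(tc$assignment, lists, universe,
                              alpha = cfg$alpha),
    error = function(e) stage_fail("enrich", e))
  write_tsv(enr$table, file.path(cfg$outdir, "marker_enrichment.tsv"))
  if (!is.null(enr$top3))
    write_tsv(enr$top3, file.path(cfg$outdir, "top3_clusters.tsv"))
  if (!is.null(cfg$gmt)) {
    terms <- read_gmt(cfg$gmt)
    biggest <- names(which.max(table(tc$assignment$cluster)))
    cluster_genes <- names(tc$assignment$cluster)[
      tc$assignment$cluster == as.integer(biggest)]
    gct <- go_celltype_interaction(cluster_genes, terms, lists, universe,
                                   term_alpha = cfg$term_alpha)
    if (nrow(gct$table))
      write_tsv(gct$table, file.path(cfg$outdir, "go_type_interaction.tsv"))
  }

  ## ---- drivers --------------------------------------------------------
  drivers <- tryCatch(predict_drivers(catalog, tc),
                      error = function(e) stage_fail("drivers", e))
  prof <- profile_table(drivers, bulk, sc)
  write_tsv(prof, file.path(cfg$outdir, "drivers.tsv"))
  driver_sets <- split(drivers$gene, drivers$type)
  if (length(driver_sets))
    write_gmt(driver_sets, file.path(cfg$outdir, "drivers.gmt"))

  ## ---- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$outdir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(cfg$outdir, files))
  manifest <- list(
    package = "trajmark",
    version = as.character(utils::packageVersion("trajmark")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    k = tc$k,
    checksums = as.list(stats::setNames(unname(sums), files)),
    warnings = warns)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  tmp <- file.path(cfg$outdir, ".manifest.tmp")
  writeLines(json, tmp)
  file.rename(tmp, file.path(cfg$outdir, "manifest.json"))
  invisible(manifest)
}
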