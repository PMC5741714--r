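## construct a pairwise DE list for given subtypes where `winners` maps
## gene -> subtype it is up-regulated in (significant in all its pairs)
## and `losses` optionally knocks out specific comparisons.
fake_pairwise <- function(subtypes, genes, winners = list(), losses = list()) {
  out <- list()
  for (i in seq_len(length(subtypes) - 1)) {
    for (j in seq((i + 1), length(subtypes))) {
      a <- subtypes[i]; b <- subtypes[j]
      lab <- paste0(a, "_vs_", b)
      padj <- rep(0.9, length(genes))
      l2fc <- rep(0, length(genes))
      for (g in names(winners)) {
        gi <- match(g, genes)
        if (winners[[g]] == a) { padj[gi] <- 1e-4; l2fc[gi] <- -2 }
        if (winners[[g]] == b) { padj[gi] <- 1e-4; l2fc[gi] <- 2 }
      }
      for (g in names(losses)) {
        gi <- match(g, genes)
        if (lab %in% losses[[g]]) { padj[gi] <- 0.9; l2fc[gi] <- 0 }
      }
      out[[lab]] <- data.frame(gene = genes, comparison = lab,
                               log2fc = l2fc, pvalue = padj, padj = padj,
                               z = 0, flag = "ok", stringsAsFactors = FALSE)
    }
  }
  out
}

test_that("pairwise_subtype_de produces s(s-1)/2 tables", {
  sim <- small_sc()
  pw <- pairwise_subtype_de(sim$sc)
  expect_length(pw, 4 * 3 / 2)
  expect_true(all(grepl("_vs_", names(pw))))
  ## group A is lexicographically first
  expect_true(all(vapply(strsplit(names(pw), "_vs_"), function(x)
    x[1] < x[2], logical(1))))
  ## error on subtypes with a single cell
  sc_bad <- sim$sc
  keep <- !(sc_bad$cells$subtype == "TA_S1" &
              duplicated(sc_bad$cells$subtype == "TA_S1") == FALSE)
  cells <- sc_bad$cells[-(1:29), ]   # leave one TA_S1 cell
  sc1 <- sc_data(sc_bad$counts[, cells$cell], cells)
  expect_error(pairwise_subtype_de(sc1), "TA_S1")
})

test_that("subtype voting honours the allowed-losses slack", {
  subs <- paste0("S", 1:5)          # s = 5: min_wins = 4 - 2 = 2
  genes <- c("gA", "gB", "gC")
  pw <- fake_pairwise(subs, genes,
                      winners = list(gA = "S1", gB = "S1", gC = "S1"),
                      losses = list(gB = c("S1_vs_S2", "S1_vs_S3"),
                                    gC = c("S1_vs_S2", "S1_vs_S3",
                                           "S1_vs_S4")))
  cand <- call_subtype_markers(pw, alpha = 0.05, allowed_losses = 2)
  expect_equal(attr(cand, "min_wins"), 2)
  expect_true(cand["gA", "S1"])     # 4/4 wins
  expect_true(cand["gB", "S1"])     # 2/4 wins: exactly at threshold
  expect_false(cand["gC", "S1"])    # 1/4 wins: below
  expect_false(any(cand[, setdiff(subs, "S1")]))
})

test_that("multiple markers resolve to the subtype of highest expression", {
  sim <- small_sc()
  subs <- sort(unique(sim$sc$cells$subtype))
  genes <- rownames(sim$sc$counts)[1:3]
  pw <- fake_pairwise(subs, genes, winners = list())
  cand <- call_subtype_markers(pw)
  ## force double candidacy by hand
  cand[1, c("TA_S1", "TB_S2")] <- TRUE
  cand[2, "TA_S2"] <- TRUE
  res <- resolve_multiple_markers(cand, sim$sc)
  expect_equal(nrow(res), 2)
  norm <- umi_normalize(sim$sc$counts)$normalized
  mu1 <- vapply(c("TA_S1", "TB_S2"), function(s)
    mean(norm[genes[1], sim$sc$cells$subtype == s]), numeric(1))
  expect_equal(res$owner_subtype[res$gene == genes[1]],
               names(mu1)[which.max(mu1)])
  expect_equal(res$owner_subtype[res$gene == genes[2]], "TA_S2")
})

test_that("type markers need homogeneity and cross-type up-regulation", {
  ## constructed 2x2 world: gene uniform within TA, silent in TB;
  ## a second gene uniform everywhere; a third heterogeneous within TA
  ## enough genes that library-size normalization is not distorted by
  ## the planted markers (compositional effect)
  ct <- tiny_celltypes()
  cells <- data.frame(cell = sprintf("c%03d", 1:80),
                      type = rep(c("TA", "TB"), each = 40),
                      subtype = rep(unlist(ct), each = 20),
                      stringsAsFactors = FALSE)
  set.seed(31)
  base <- matrix(rpois(80 * 300, 20), 300, 80)
  rownames(base) <- sprintf("g%03d", 1:300)
  colnames(base) <- cells$cell
  base["g001", cells$type == "TA"] <- rpois(40, 160)      # type marker
  base["g002", ] <- rpois(80, 40)                         # flat everywhere
  base["g003", cells$subtype == "TA_S1"] <- rpois(20, 160) # subtype only
  sc <- sc_data(base, cells)
  pw <- pairwise_subtype_de(sc)
  tm <- call_type_markers(sc, pw, alpha = 0.05)
  expect_true("g001" %in% tm$gene)
  expect_equal(tm$owner_type[tm$gene == "g001"], "TA")
  expect_false("g002" %in% tm$gene)
  expect_false("g003" %in% tm$gene)   # heterogeneous within TA
  ## but g003 is a subtype candidate of TA_S1
  cand <- call_subtype_markers(pw)
  expect_true(cand["g003", "TA_S1"])
})

test_that("combined lists union type and nested subtype markers", {
  catalog <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    level = c("type", "type", "subtype", "subtype", "subtype"),
    owner_type = c("TA", "TA", "TA", "TA", "TB"),
    owner_subtype = c(NA, NA, "TA_S1", "TA_S2", "TB_S1"),
    wins = c(NA, NA, 4L, 4L, 4L),
    mean_expr_owner = 1:5, stringsAsFactors = FALSE)
  lists <- combined_type_marker_lists(catalog, letters[1:10])
  expect_setequal(lists$TA, c("a", "b", "c", "d"))
  expect_setequal(lists$TB, "e")
  expect_setequal(attr(lists, "non_markers"), letters[6:10])
  ## owner uniqueness across lists
  expect_length(intersect(lists$TA, lists$TB), 0)
  ## empty catalog
  empty <- combined_type_marker_lists(catalog[0, ], letters[1:4])
  expect_length(empty, 0)
  expect_setequal(attr(empty, "non_markers"), letters[1:4])
})

test_that("planted markers are recovered from the small simulation", {
  sim <- small_sc()
  catalog <- derive_marker_catalog(sim$sc)
  truth <- sim$truth[sim$truth$role != "none", ]
  called <- catalog$gene
  recall <- mean(truth$gene %in% called)
  precision <- mean(called %in% truth$gene)
  expect_gt(recall, 0.9)
  expect_gt(precision, 0.9)
  ## owner correctness for recovered type markers
  tm <- catalog[catalog$level == "type", ]
  tm_truth <- truth[match(tm$gene, truth$gene), ]
  agree <- tm$owner_type == tm_truth$owner
  expect_gt(mean(agree, na.rm = TRUE), 0.9)
  ## owner uniqueness
  expect_equal(anyDuplicated(catalog$gene), 0L)
})

test_that("null simulation calls almost no markers", {
  sim0 <- simulate_sc(celltypes = tiny_celltypes(), cells_per_subtype = 30,
                      n_genes = 400, markers_per_type = 0,
                      markers_per_subtype = 0, fold_change = 8,
                      depth = 1500, seed = 13)
  catalog <- derive_marker_catalog(sim0$sc)
  expect_lt(nrow(catalog) / 400, 0.01)
})
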