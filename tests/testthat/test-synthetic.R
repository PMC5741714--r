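test_that("default archetypes satisfy the stated invariants", {
  arch <- default_archetypes()
  expect_equal(nrow(arch), 13)
  expect_equal(sum(arch$proportion), 1)
  expect_true(all(arch$proportion >= 0.05))
  prof <- as.matrix(arch[, STAGES])
  expect_true(all(prof > 0))
  ## geometric-mean centering
  expect_equal(unname(rowMeans(log2(prof))), rep(0, 13), tolerance = 1e-12)
  expect_equal(as.integer(table(arch$direction)[c("decreasing",
                                                  "increasing",
                                                  "transient")]),
               c(4L, 4L, 5L))
})

test_that("simulate_bulk is deterministic and truth-complete", {
  s1 <- simulate_bulk(n_genes = 300, seed = 99)
  s2 <- simulate_bulk(n_genes = 300, seed = 99)
  expect_identical(s1$bulk$counts, s2$bulk$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_bulk(n_genes = 300, seed = 100)
  expect_false(identical(s1$bulk$counts, s3$bulk$counts))
  ## exactly one truth record per gene
  expect_setequal(s1$truth$gene, rownames(s1$bulk$counts))
  expect_equal(anyDuplicated(s1$truth$gene), 0L)
  ## deterministic apportionment reproduces requested proportions
  frac <- table(s1$truth$archetype) / 300
  arch <- default_archetypes()
  expect_equal(as.numeric(frac[arch$archetype]), arch$proportion,
               tolerance = 1 / 300)
})

test_that("simulate_bulk null archetype with zero dispersion is Poisson-flat", {
  arch <- default_archetypes()
  arch$proportion <- arch$proportion * 0.5   # half the genes are null
  sim <- simulate_bulk(arch, n_genes = 2000, dispersion = 0,
                       libsize_sigma = 0, seed = 3)
  nulls <- sim$truth$gene[is.na(sim$truth$archetype)]
  cnt <- sim$bulk$counts[nulls, ]
  stage <- factor(sim$bulk$samples$stage, STAGES)
  sm <- vapply(STAGES, function(s)
    mean(cnt[, stage == s]), numeric(1))
  ## equal stage means within Poisson error
  expect_lt(diff(range(sm)) / mean(sm), 0.02)
  ## Poisson: variance ~ mean across genes
  vm <- apply(cnt, 1, var) / rowMeans(cnt)
  expect_lt(abs(median(vm) - 1), 0.1)
})

test_that("a decreasing archetype yields monotone stage means", {
  arch <- data.frame(archetype = "dec", direction = "decreasing",
                     proportion = 0.2,
                     E15 = 1, P1 = .8, P7 = .5, P15 = .3, P30 = .2)
  sim <- simulate_bulk(arch, n_genes = 5000, reps_per_stage = 3,
                       baseline = list(meanlog = log(500), sdlog = 0),
                       dispersion = 0.05, libsize_sigma = 0, seed = 12)
  genes <- sim$truth$gene[!is.na(sim$truth$archetype)]
  expect_length(genes, 1000)
  stage <- factor(sim$bulk$samples$stage, STAGES)
  sm <- vapply(STAGES, function(s)
    mean(sim$bulk$counts[genes, stage == s]), numeric(1))
  ## analytic NB means with 3 reps x 1000 genes; se per stage mean
  mu <- 500 * c(1, .8, .5, .3, .2)
  se <- sqrt((mu + 0.05 * mu^2) / (3 * 1000))
  expect_true(all(diff(sm) < 0))
  expect_true(all(abs(sm - mu) < 3 * se + 1e-9))
})

test_that("simulate_bulk input validation", {
  arch <- default_archetypes()
  arch$proportion[1] <- arch$proportion[1] + 0.5
  expect_error(simulate_bulk(arch, n_genes = 50), "sum")
  expect_error(simulate_bulk(n_genes = 50, reps_per_stage = 1), ">= 2")
})

test_that("simulate_sc plants recoverable marker structure", {
  sim <- small_sc()
  sc <- sim$sc; truth <- sim$truth
  norm <- umi_normalize(sc$counts)$normalized
  subs <- sort(unique(sc$cells$subtype))
  sub_means <- vapply(subs, function(s)
    rowMeans(norm[, sc$cells$subtype == s, drop = FALSE]),
    numeric(nrow(norm)))
  ## subtype markers: maximal mean normalized expression in the owner
  sub_m <- truth[truth$role == "subtype_marker", ]
  top <- subs[apply(sub_means[sub_m$gene, ], 1, which.max)]
  expect_gt(mean(top == sub_m$owner), 0.9)
  ## type markers: elevated in both subtypes of the owning type
  type_m <- truth[truth$role == "type_marker", ]
  nest <- sc$nesting
  for (g in type_m$gene[1:5]) {
    own <- type_m$owner[type_m$gene == g]
    own_mean <- mean(sub_means[g, names(nest)[nest == own]])
    other_mean <- mean(sub_means[g, names(nest)[nest != own]])
    expect_gt(own_mean, 3 * other_mean)
  }
  ## truth completeness and determinism
  expect_setequal(truth$gene, rownames(sc$counts))
  again <- simulate_sc(celltypes = tiny_celltypes(),
                       cells_per_subtype = 30, n_genes = 400,
                       markers_per_type = 5, markers_per_subtype = 3,
                       fold_change = 8, depth = 1500, seed = 11)
  expect_identical(again$sc$counts, sc$counts)
})

test_that("simulate_sc validates fold change and sizes", {
  expect_error(simulate_sc(celltypes = tiny_celltypes(), n_genes = 50,
                           fold_change = 0.5), "fold_change")
  expect_warning(simulate_sc(celltypes = tiny_celltypes(), n_genes = 100,
                             cells_per_subtype = 3, fold_change = 1,
                             seed = 1), "null run")
  expect_error(simulate_sc(celltypes = tiny_celltypes(), n_genes = 10,
                           markers_per_type = 10), "marker genes")
})

test_that("simulate_genesets controls overlap with the planted groups", {
  universe <- sprintf("g%04d", 1:2000)
  groups <- list(grp = universe[1:100])
  sets <- simulate_genesets(universe, groups, n_planted = 5, n_random = 10,
                            planted_overlap = 0.75, seed = 2)
  expect_length(sets, 15)
  truth <- attr(sets, "truth")
  planted <- truth$term[!is.na(truth$source)]
  for (tm in planted) {
    ov <- length(intersect(sets[[tm]], groups$grp)) / length(sets[[tm]])
    expect_gt(ov, 0.5)
  }
  ## planted_overlap = 0 gives uniform random draws: overlap near
  ## expectation |term| * 100/2000
  sets0 <- simulate_genesets(universe, groups, n_planted = 20, n_random = 0,
                             planted_overlap = 0, seed = 3)
  ovs <- vapply(names(sets0), function(tm)
    length(intersect(sets0[[tm]], groups$grp)), numeric(1))
  expected <- vapply(sets0, length, numeric(1)) * 100 / 2000
  expect_lt(abs(sum(ovs) - sum(expected)) / sum(expected), 0.5)
  ## full overlap: hypergeometric p is the minimum achievable
  full <- list(term = groups$grp)
  h <- hypergeom_test(full$term, groups$grp, universe)
  expect_equal(h$overlap, 100)
  expect_equal(h$p, hyper_tail_oracle(100, 2000, 100, 100), tolerance = 1e-12)
})
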