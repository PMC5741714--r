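test_that("size factors: median-of-ratios on hand-checkable inputs", {
  m <- matrix(c(2, 8, 4, 16), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)

  same <- cbind(s1 = c(3, 7, 1), s2 = c(3, 7, 1))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(same)), c(1, 1))

  one <- matrix(5:7, ncol = 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(estimate_size_factors(one)), 1)

  expect_error(estimate_size_factors(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y")))), "all-zero")
})

test_that("size factors are scale-equivariant and handle sparse matrices", {
  set.seed(1)
  m <- matrix(rpois(60, 20), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sf1 <- estimate_size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  sf2 <- estimate_size_factors(m2)
  ## factors are defined up to a constant: equivariance holds for ratios
  expect_equal(unname((sf2[3] / sf2[1]) / (sf1[3] / sf1[1])), 5,
               tolerance = 1e-12)
  ## no gene positive everywhere -> sparse fallback still works
  sp <- m; sp[cbind(1:10, rep(1:6, length.out = 10))] <- 0
  expect_true(all(estimate_size_factors(sp) > 0))
})

test_that("p_to_signed_z maps adjusted p-values to signed Z-scores", {
  expect_equal(p_to_signed_z(2.87e-7, 1), 5, tolerance = 1e-3)
  expect_equal(p_to_signed_z(0.5, 1), 0, tolerance = 1e-12)
  expect_equal(p_to_signed_z(0.05, -1), -qnorm(0.95), tolerance = 1e-10)
  expect_warning(z0 <- p_to_signed_z(0, 1), "underflow")
  expect_equal(z0, 38)
  expect_error(p_to_signed_z(1.2, 1), "0, 1")
  expect_error(p_to_signed_z(0.1, 2), "direction")
})

test_that("rpkm follows its unit definition", {
  expect_equal(unname(rpkm(matrix(1), 1000, 1e6)[1, 1]), 1)
  expect_equal(unname(rpkm(matrix(10), 2000, 5e6)[1, 1]), 1)
  expect_equal(unname(rpkm(matrix(0), 1500, 2e6)[1, 1]), 0)
  expect_error(rpkm(matrix(1), 1000, 0), "positive")
  expect_error(rpkm(matrix(1), -5, 1e6), "positive")
})

test_that("umi_normalize scales cells to a common total", {
  m <- matrix(c(10, 90, 30, 170, 100, 300), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  res <- umi_normalize(m)   # totals 100, 200, 400; median 200
  expect_equal(unname(res$factors), c(0.5, 1, 2))
  expect_equal(unname(colSums(res$normalized)), rep(200, 3))
  ## same composition at double depth -> identical normalized profile
  m2 <- cbind(a = c(10, 30), b = c(20, 60))
  rownames(m2) <- c("g1", "g2")
  r2 <- umi_normalize(m2)
  expect_equal(r2$normalized[, "a"], r2$normalized[, "b"])
  expect_warning(umi_normalize(cbind(x = c(1, 1), y = c(0, 0))), "zero")
})

test_that("nb_wald_test: type-I error is calibrated on a null simulation", {
  set.seed(42)
  m <- 2000; n <- 3
  mu <- exp(rnorm(m, log(500), 1))
  cnt <- matrix(rnbinom(m * 2 * n, mu = rep(mu, 2 * n), size = 10),
                nrow = m, dimnames = list(paste0("g", 1:m),
                                          paste0("s", 1:(2 * n))))
  r <- nb_wald_test(cnt, 1:n, n + 1:n, size_factors = rep(1, 2 * n))
  frac <- mean(r$pvalue < 0.05)
  halfwidth <- 2.576 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), halfwidth + 0.01)
})

test_that("nb_wald_test: trivial and degenerate genes", {
  cnt <- rbind(flat = rep(10, 6), zero = rep(0, 6),
               lone = c(3, 0, 0, 0, 0, 0))
  colnames(cnt) <- paste0("s", 1:6)
  r <- nb_wald_test(cnt, 1:3, 4:6, size_factors = rep(1, 6),
                    dispersion = 0)
  expect_equal(r$log2fc[r$gene == "flat"], 0)
  expect_equal(r$pvalue[r$gene == "zero"], 1)
  expect_equal(r$flag[r$gene == "zero"], "all_zero")
  expect_equal(r$flag[r$gene == "lone"], "low_count")
  expect_equal(r$pvalue[r$gene == "lone"], 1)
})

test_that("nb_wald_test: power on a planted fold-change, LR oracle agrees", {
  set.seed(7)
  m <- 400; n <- 10; alpha <- 0.05
  mu <- rep(100, m)
  fold <- rep(1, m); planted <- 1:20; fold[planted] <- 8
  cnt <- cbind(matrix(rnbinom(m * n, mu = mu, size = 1 / alpha), m),
               matrix(rnbinom(m * n, mu = mu * fold, size = 1 / alpha), m))
  dimnames(cnt) <- list(paste0("g", 1:m), paste0("s", 1:(2 * n)))
  r <- nb_wald_test(cnt, 1:n, n + 1:n, size_factors = rep(1, 2 * n))
  expect_true(all(r$padj[planted] < 0.05))
  ## independent likelihood-ratio oracle finds the same genes
  lr_p <- vapply(planted, function(g)
    nb_lr_pvalue(cnt[g, 1:n], cnt[g, n + 1:n], alpha), numeric(1))
  expect_true(all(lr_p < 1e-4))
})

test_that("nb_wald_test: swapping groups negates log2fc and z, keeps p", {
  sim <- small_bulk()
  cnt <- sim$bulk$counts[1:200, ]
  a <- 1:3; b <- 4:6
  r1 <- nb_wald_test(cnt, a, b, size_factors = rep(1, 6))
  r2 <- nb_wald_test(cnt, b, a, size_factors = rep(1, 6))
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-12)
  expect_equal(r1$z, -r2$z, tolerance = 1e-12)
  expect_true(all(r1$padj >= r1$pvalue - 1e-15))
  expect_true(all(sign(r1$z) == sign(r1$log2fc) | r1$z == 0))
})

test_that("nb_wald_test on Poisson data agrees with two-proportion oracle", {
  set.seed(3)
  m <- 300; n <- 6
  mu <- rep(500, m)
  cnt <- matrix(rpois(m * 2 * n, rep(mu, 2 * n)), m,
                dimnames = list(paste0("g", 1:m), paste0("s", 1:(2 * n))))
  r <- nb_wald_test(cnt, 1:n, n + 1:n, size_factors = rep(1, 2 * n),
                    dispersion = 0)
  ## two-sample Poisson normal-approximation oracle
  ta <- rowSums(cnt[, 1:n]); tb <- rowSums(cnt[, n + 1:n])
  w <- (tb - ta) / sqrt(ta + tb)
  p_oracle <- 2 * pnorm(-abs(w))
  ## agreement within simulation error: compare rejection behaviour
  expect_gt(cor(qnorm(pmax(r$pvalue, 1e-12) / 2),
                qnorm(pmax(p_oracle, 1e-12) / 2)), 0.98)
})

test_that("BH within comparison: adjusted p monotone in rank, capped at 1", {
  set.seed(9)
  p <- runif(50)
  q <- correct(p, "benjamini")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q <= 1))
})
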