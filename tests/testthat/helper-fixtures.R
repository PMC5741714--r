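## Shared fixtures, built once per test run. Sizes are kept small; the
## heavier simulations live only in test-acceptance.R.

# tiny nested cell-type structure: 2 types x 2 subtypes
tiny_celltypes <- function()
  list(TA = c("TA_S1", "TA_S2"), TB = c("TB_S1", "TB_S2"))

# small labeled single-cell simulation with planted markers
small_sc <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_sc(celltypes = tiny_celltypes(),
                          cells_per_subtype = 30, n_genes = 400,
                          markers_per_type = 5, markers_per_subtype = 3,
                          fold_change = 8, depth = 1500, seed = 11)
    val
  }
})

# small bulk simulation (defaults scaled down)
small_bulk <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_bulk(n_genes = 1200, seed = 5)
    val
  }
})

# build a fake DE-result list from a named z matrix (rows = genes,
# columns = canonical comparisons); only fields used by the consumers
fake_de_from_z <- function(z) {
  lapply(stats::setNames(colnames(z), colnames(z)), function(cmp) {
    data.frame(gene = rownames(z), comparison = cmp,
               log2fc = sign(z[, cmp]), pvalue = NA_real_,
               padj = NA_real_, z = z[, cmp], flag = "ok",
               stringsAsFactors = FALSE)
  })
}

# NB likelihood-ratio oracle for a two-group comparison with known
# dispersion (used to cross-check nb_wald_test power)
nb_lr_pvalue <- function(ka, kb, alpha) {
  size <- 1 / alpha
  ll <- function(k, mu) sum(stats::dnbinom(k, size = size, mu = mu,
                                           log = TRUE))
  l1 <- ll(ka, mean(ka)) + ll(kb, mean(kb))
  l0 <- ll(c(ka, kb), mean(c(ka, kb)))
  stats::pchisq(2 * (l1 - l0), df = 1, lower.tail = FALSE)
}

# direct hypergeometric tail by PMF summation (independent oracle)
hyper_tail_oracle <- function(k, N, K, n, tail = "over") {
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  support <- lo:hi
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  if (tail == "over") sum(pmf[support >= k]) else sum(pmf[support <= k])
}
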