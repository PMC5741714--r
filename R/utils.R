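#' @keywords internal
"_PACKAGE"

#' Developmental stages of the bulk time course
#'
#' The five perinatal stages, in chronological order. All bulk functions
#' assume exactly these stage labels.
#' @export
STAGES <- c("E15", "P1", "P7", "P15", "P30")

## Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a stream of sub-seeds from a root seed (kept < 2^31);
## arithmetic in doubles to avoid integer overflow.
derive_seeds <- function(seed, n) {
  as.integer((as.numeric(seed) + 1013 * seq_len(n)) %%
               (.Machine$integer.max - 1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Apportion n items to proportions p by largest remainder, deterministic.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_order <- order(raw - base, decreasing = TRUE)
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used to score recovery of planted archetypes by the clustering stages.
#'
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Multiple-testing correction
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment, implemented
#' directly (the BH step-up is the classic sort / cummin construction).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method "bonferroni" or "benjamini".
#' @return vector of corrected p-values, same order as the input.
#' @export
correct <- function(p, method = c("bonferroni", "benjamini")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  if (method == "bonferroni") return(pmin(1, p * n))
  ## BH step-up: q_(i) = min_{j >= i} p_(j) * n / j
  ord <- order(p, decreasing = TRUE)
  ranks <- n:1L
  q <- pmin(1, cummin(p[ord] * n / ranks))
  out <- numeric(n)
  out[ord] <- q
  out
}
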