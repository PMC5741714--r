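#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median ratio of each
#' sample's counts to the per-gene geometric mean across samples, using
#' genes with nonzero counts in every sample. When no such gene exists the
#' geometric mean is taken over nonzero entries only (sparse fallback,
#' suitable for UMI matrices).
#'
#' @param counts count matrix (genes x samples) or a [bulk_data]/[sc_data]
#'   object.
#' @return positive numeric vector, one factor per sample/cell.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "bulk_data") || inherits(counts, "sc_data"))
    counts <- counts$counts
  counts <- as.matrix(counts)
  if (all(counts == 0)) stopf("all-zero count matrix: size factors undefined")
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    logg <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - logg)))
  } else {
    ## sparse fallback: geometric mean over nonzero entries per gene
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    logg <- rowMeans(lc, na.rm = TRUE)
    keep <- is.finite(logg)
    sf <- apply(counts[keep, , drop = FALSE], 2, function(col) {
      r <- log(col) - logg[keep]
      r <- r[is.finite(r)]
      if (!length(r)) return(NA_real_)
      exp(stats::median(r))
    })
    if (anyNA(sf)) stopf("sample(s) share no expressed gene with the rest")
  }
  ## normalize to geometric mean 1: makes the factors exactly
  ## scale-equivariant (scaling one column by c scales its factor by c)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Signed Z-score from an adjusted p-value
#'
#' Converts a (one-sided) adjusted p-value to a standard-normal Z-score and
#' signs it by the direction of regulation; `p = 2.87e-7` maps to `Z = 5`.
#' |Z| is capped at 38, where the normal tail underflows double precision.
#'
#' @param p p-value(s) in (0, 1]; p = 0 is capped with a warning.
#' @param direction +1 or -1 per element (sign of the fold change).
#' @return signed Z score(s).
#' @export
p_to_signed_z <- function(p, direction = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  if (!all(abs(direction) == 1)) stopf("direction must be +1 or -1")
  if (any(p == 0, na.rm = TRUE))
    warnf("p-value underflow: Z capped at 38")
  z <- stats::qnorm(pmax(p, 1e-320), lower.tail = FALSE)
  direction * pmin(pmax(z, -38), 38)
}

## moment estimate of the NB dispersion alpha (variance = mu + alpha mu^2),
## pooled over the two groups; inv_a / inv_b are mean(1/size factor).
moment_dispersion <- function(ya, yb, mu_a, mu_b, inv_a, inv_b) {
  na <- ncol(ya); nb <- ncol(yb)
  va <- if (na > 1) rowSums((ya - mu_a)^2) / (na - 1) else rep(0, nrow(ya))
  vb <- if (nb > 1) rowSums((yb - mu_b)^2) / (nb - 1) else rep(0, nrow(yb))
  num <- (na - 1) * (va - mu_a * inv_a) + (nb - 1) * (vb - mu_b * inv_b)
  den <- (na - 1) * mu_a^2 + (nb - 1) * mu_b^2
  alpha <- ifelse(den > 0, num / den, 0)
  pmin(pmax(alpha, 0), 100)
}

## smooth the per-gene moment dispersions into a mean-dispersion trend.
## With few replicates the per-gene estimate is far too noisy for a normal
## Wald reference; pooling across genes with similar expression (bin means
## over log mean expression, linear interpolation) mirrors the information
## sharing of mainstream NB DE tools and restores type-I calibration.
dispersion_trend <- function(alpha_gene, mu, n_bins = 20, min_per_bin = 25) {
  ok <- mu > 0
  if (sum(ok) < 2 * min_per_bin)
    return(rep(mean(alpha_gene[ok]), length(mu)))
  lm_ <- log(mu[ok])
  n_bins <- max(2, min(n_bins, floor(sum(ok) / min_per_bin)))
  br <- unique(stats::quantile(lm_, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) return(rep(mean(alpha_gene[ok]), length(mu)))
  bin <- cut(lm_, br, include.lowest = TRUE)
  centers <- tapply(lm_, bin, mean)
  means <- tapply(alpha_gene[ok], bin, mean)
  keep <- !is.na(means)
  if (sum(keep) < 2) return(rep(mean(alpha_gene[ok]), length(mu)))
  fit <- stats::approx(centers[keep], means[keep],
                       xout = log(pmax(mu, min(mu[ok]))), rule = 2)$y
  pmax(fit, 0)
}

#' Negative-binomial Wald test between two sample groups
#'
#' Per-gene two-group differential expression on size-factor-normalized
#' counts: NB model with variance `mu + alpha mu^2`, per-gene moment
#' estimate of `alpha` pooled over both groups, delta-method Wald statistic
#' on the log ratio of group means, two-sided p-value, and
#' Benjamini-Hochberg adjustment within the comparison. The signed Z
#' reported per gene is `sign(log2fc) * max(0, qnorm(1 - padj))`, so that
#' its sign always matches the fold-change direction and |Z| decreases with
#' the adjusted p-value.
#'
#' Genes with zero counts in both groups are reported (not dropped) with
#' `log2fc = 0`, `p = 1` and flag `"all_zero"`; genes with nonzero counts in
#' fewer than `min_nonzero` samples are flagged `"low_count"` and assigned
#' `p = 1` rather than tested.
#'
#' @param counts count matrix (genes x samples).
#' @param group_a,group_b disjoint character/integer vectors of columns; by
#'   convention A is the earlier stage (bulk) or the lexicographically first
#'   subtype (single cell), and `log2fc > 0` means higher in B.
#' @param size_factors positive per-sample factors for the used columns;
#'   estimated from the two groups when NULL.
#' @param comparison label stored in the result (default "A_vs_B").
#' @param pseudocount added to a group mean of zero before taking logs.
#' @param min_nonzero minimum samples with nonzero counts for testing.
#' @param dispersion `"trend"` (default) fits a mean-dispersion trend across
#'   genes from the per-gene moment estimates and uses the fitted value
#'   (information sharing, needed for calibration at 3 replicates);
#'   `"gene"` uses the raw per-gene moment estimate; a numeric scalar or
#'   per-gene vector supplies known dispersions directly.
#' @return data.frame of class `de_result`: gene, comparison, base_mean_a,
#'   base_mean_b, log2fc, pvalue, padj, z, flag.
#' @export
nb_wald_test <- function(counts, group_a, group_b, size_factors = NULL,
                         comparison = NULL, pseudocount = 0.5,
                         min_nonzero = 2, dispersion = "trend") {
  counts <- as.matrix(counts)
  if (length(group_a) == 0 || length(group_b) == 0)
    stopf("both groups must be non-empty")
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (anyNA(group_a) || anyNA(group_b)) stopf("unknown sample in group")
  if (length(intersect(group_a, group_b))) stopf("groups must be disjoint")
  used <- c(group_a, group_b)
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(counts[, used, drop = FALSE])
  } else {
    if (length(size_factors) == ncol(counts))
      size_factors <- size_factors[used]
    if (length(size_factors) != length(used))
      stopf("size_factors must cover the used samples")
    if (any(size_factors <= 0)) stopf("size factors must be positive")
  }
  sa <- size_factors[seq_along(group_a)]
  sb <- size_factors[length(group_a) + seq_along(group_b)]
  ka <- counts[, group_a, drop = FALSE]
  kb <- counts[, group_b, drop = FALSE]
  ya <- sweep(ka, 2, sa, "/")
  yb <- sweep(kb, 2, sb, "/")
  mu_a <- rowMeans(ya); mu_b <- rowMeans(yb)
  inv_a <- mean(1 / sa); inv_b <- mean(1 / sb)
  na <- length(group_a); nb <- length(group_b)

  alpha_gene <- moment_dispersion(ya, yb, mu_a, mu_b, inv_a, inv_b)
  if (is.numeric(dispersion)) {
    alpha <- rep_len(dispersion, nrow(counts))
  } else if (identical(dispersion, "gene")) {
    alpha <- alpha_gene
  } else if (identical(dispersion, "trend")) {
    alpha <- dispersion_trend(alpha_gene, (mu_a + mu_b) / 2)
  } else stopf("unknown dispersion mode")
  ## pseudocount only where a group mean vanishes (keeps exact symmetry)
  zero_any <- (mu_a == 0) | (mu_b == 0)
  ma <- ifelse(zero_any, mu_a + pseudocount, mu_a)
  mb <- ifelse(zero_any, mu_b + pseudocount, mu_b)
  var_log_a <- (ma * inv_a + alpha * ma^2) / (na * ma^2)
  var_log_b <- (mb * inv_b + alpha * mb^2) / (nb * mb^2)
  lfc_ln <- log(mb) - log(ma)
  wald <- lfc_ln / sqrt(var_log_a + var_log_b)
  pval <- 2 * stats::pnorm(-abs(wald))

  nz <- rowSums(cbind(ka, kb) > 0)
  flag <- rep("ok", nrow(counts))
  flag[nz < min_nonzero & nz > 0] <- "low_count"
  flag[nz == 0] <- "all_zero"
  skip <- flag != "ok"
  pval[skip] <- 1
  lfc_ln[flag == "all_zero"] <- 0
  wald[skip] <- 0

  padj <- correct(pval, "benjamini")
  dir <- ifelse(lfc_ln >= 0, 1, -1)
  z <- dir * pmax(0, pmin(stats::qnorm(pmax(padj, 1e-320),
                                       lower.tail = FALSE), 38))
  z[lfc_ln == 0] <- 0
  if (is.null(comparison)) comparison <- "A_vs_B"
  res <- data.frame(gene = rownames(counts), comparison = comparison,
                    base_mean_a = mu_a, base_mean_b = mu_b,
                    log2fc = lfc_ln / log(2), pvalue = pval, padj = padj,
                    z = z, flag = flag, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `counts / (length_kb * library_size_millions)`.
#'
#' @param counts count matrix (genes x samples) or vector.
#' @param gene_lengths transcript lengths in base pairs, one per gene.
#' @param library_sizes total mapped reads per sample; column sums of
#'   `counts` when NULL.
#' @return matrix of RPKM values, same shape as `counts`.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts))
    stopf("need one gene length per row")
  if (any(gene_lengths <= 0)) stopf("gene lengths must be positive")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stopf("library sizes must be positive")
  sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' Library-size normalization of UMI counts
#'
#' Scales every cell to a common total (the median cell total by default),
#' the normalization used for single-cell expression summaries.
#'
#' @param counts UMI count matrix (genes x cells) or [sc_data].
#' @param scale_to target total per cell; median of cell totals if NULL.
#' @return list with `normalized` (matrix), `factors` (per-cell divisors,
#'   proportional to cell totals) and `scale_to`.
#' @export
umi_normalize <- function(counts, scale_to = NULL) {
  if (inherits(counts, "sc_data")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 0 || nrow(counts) == 0) stopf("empty matrix")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warnf("dropping %d cell(s) with zero total counts", sum(totals == 0))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
    if (!length(totals)) stopf("no cell with nonzero counts")
  }
  if (is.null(scale_to)) scale_to <- stats::median(totals)
  factors <- totals / scale_to
  list(normalized = sweep(counts, 2, factors, "/"),
       factors = factors, scale_to = scale_to)
}
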