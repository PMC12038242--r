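#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference features
#' (features with positive counts in every sample) of the ratio of the
#' sample's count to the feature's geometric mean across samples. If no
#' feature is positive everywhere, falls back to total-count ratios with a
#' warning (factors normalized to geometric mean 1).
#'
#' @param mat features x samples count matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(mat) {
  logmat <- log(mat)
  logmeans <- rowMeans(logmat)
  ref <- is.finite(logmeans)
  if (!any(ref)) {
    warning("no feature with all-positive counts; using total-count ratios")
    tot <- colSums(mat)
    return(tot / exp(mean(log(tot))))
  }
  apply(mat[ref, , drop = FALSE], 2, function(col) {
    median(col / exp(logmeans[ref]))
  })
}

#' Method-of-moments dispersion estimates
#'
#' Per-feature NB dispersion alpha from normalized counts:
#' alpha = max((var - mean) / mean^2, floor). A crude plug-in estimator (no
#' shrinkage across features), sufficient for the simplified Wald test.
#'
#' @param mat features x samples count matrix.
#' @param sf per-sample size factors.
#' @param alpha_floor lower bound (default 1e-8).
#' @return numeric vector of dispersions.
#' @export
estimate_dispersion <- function(mat, sf = size_factors(mat), alpha_floor = 1e-8) {
  norm <- sweep(mat, 2, sf, "/")
  m <- rowMeans(norm)
  v <- rowSums((norm - m)^2) / (ncol(norm) - 1)
  a <- (v - m) / m^2
  a[!is.finite(a)] <- alpha_floor
  pmax(a, alpha_floor)
}

#' Simplified negative-binomial Wald test for a two-group contrast
#'
#' Group means are fitted on size-factor-normalized counts;
#' log2FC = log2(muB/muA) (+0.5 pseudocount to both means when either group
#' mean is zero); the standard error comes from the NB variance
#' mu + alpha*mu^2 via the delta method, and the Wald statistic log2FC/SE is
#' referred to a two-sided standard normal. Features with all-zero counts
#' are returned NA. P-values are BH-adjusted across features.
#'
#' @param mat features x samples count matrix.
#' @param groups factor/character of length ncol(mat) with two levels; the
#'   contrast is level 2 vs level 1 (B vs A).
#' @param sf size factors (default median-of-ratios).
#' @param dispersion per-feature alpha (default method-of-moments).
#' @return A `DifferentialResult` data.table with DESeq2-compatible columns:
#'   feature_id, baseMean, log2FoldChange, lfcSE, stat, pvalue, padj,
#'   dispersion; size factors as attribute `size_factors`.
#' @export
nb_wald_test <- function(mat, groups, sf = size_factors(mat),
                         dispersion = estimate_dispersion(mat, sf)) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, ncol(mat) == length(groups))
  if (any(table(groups) == 0)) stop("both groups must be non-empty")
  a_lvl <- levels(groups)[1]; b_lvl <- levels(groups)[2]
  norm <- sweep(mat, 2, sf, "/")
  muA <- rowMeans(norm[, groups == a_lvl, drop = FALSE])
  muB <- rowMeans(norm[, groups == b_lvl, drop = FALSE])
  nA <- sum(groups == a_lvl); nB <- sum(groups == b_lvl)
  zero <- muA == 0 | muB == 0
  muA_fc <- ifelse(zero, muA + 0.5, muA)
  muB_fc <- ifelse(zero, muB + 0.5, muB)
  lfc <- log2(muB_fc / muA_fc)
  se_g <- function(mu, n) sqrt((mu + dispersion * mu^2) / n) / (mu * log(2))
  se <- sqrt(se_g(muA_fc, nA)^2 + se_g(muB_fc, nB)^2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  allzero <- muA == 0 & muB == 0
  lfc[allzero] <- NA_real_; se[allzero] <- NA_real_
  stat[allzero] <- NA_real_; p[allzero] <- NA_real_
  res <- data.table(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    baseMean = rowMeans(norm), log2FoldChange = lfc, lfcSE = se, stat = stat,
    pvalue = p, padj = bh_adjust(p), dispersion = dispersion)
  setattr(res, "size_factors", sf)
  setattr(res, "contrast", c(b_lvl, "vs", a_lvl))
  setattr(res, "class", c("DifferentialResult", class(res)))
  res[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: padj_(i) = min_{k >= i}(p_(k) * m / k), capped at 1.
#' NAs are excluded from m and returned as NA.
#'
#' @param pvalues numeric vector in [0, 1], NA allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Permutation test for differential circular-to-linear ratio
#'
#' The statistic is the difference of group means of log2(CLR + eps)
#' (eps = 0.01). P-values come from label permutations: exact enumeration of
#' all group assignments when there are at most `max_exact` arrangements,
#' otherwise `n_perm` random permutations (with the +1 correction). Fewer
#' than 20 possible arrangements yields NA. BH adjustment across features.
#'
#' @param clr_mat features x samples CLR matrix.
#' @param groups two-level factor; statistic is level 2 minus level 1.
#' @param n_perm number of random permutations when not enumerating.
#' @param seed RNG seed for random permutations.
#' @param eps offset inside the log (default 0.01).
#' @param max_exact enumeration threshold on choose(n, nB).
#' @return A `DifferentialResult`-style data.table (log2FoldChange holds the
#'   observed statistic).
#' @export
differential_clr <- function(clr_mat, groups, n_perm = 1000, seed = 1,
                             eps = 0.01, max_exact = 10000) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, ncol(clr_mat) == length(groups))
  n <- length(groups)
  idxB <- which(groups == levels(groups)[2])
  nB <- length(idxB); nA <- n - nB
  x <- log2(clr_mat + eps)
  contrast_vec <- function(bidx) {
    w <- rep(-1 / nA, n); w[bidx] <- 1 / nB; w
  }
  obs <- as.vector(x %*% contrast_vec(idxB))
  n_arr <- choose(n, nB)
  if (n_arr < 20) {
    p <- rep(NA_real_, nrow(clr_mat))
  } else if (n_arr <= max_exact) {
    combs <- combn(n, nB)
    W <- apply(combs, 2, contrast_vec)
    perm <- abs(x %*% W)           # features x arrangements
    p <- rowMeans(perm >= abs(obs) - 1e-12)
  } else {
    perm <- with_seed(seed, {
      W <- vapply(seq_len(n_perm), function(i) contrast_vec(sample(n, nB)),
                  numeric(n))
      abs(x %*% W)
    })
    p <- (1 + rowSums(perm >= abs(obs) - 1e-12)) / (n_perm + 1)
  }
  res <- data.table(
    feature_id = rownames(clr_mat) %||% as.character(seq_len(nrow(clr_mat))),
    baseMean = rowMeans(clr_mat), log2FoldChange = obs, lfcSE = NA_real_,
    stat = obs, pvalue = p, padj = bh_adjust(p))
  setattr(res, "class", c("DifferentialResult", class(res)))
  res[]
}

#' Default significance thresholds
#'
#' Expression contrasts use adjusted P < 0.05 and |log2FC| > 1; CLR
#' contrasts use adjusted P < 0.2 and |log2FC| > 0.1.
#'
#' @param lfc_cut,padj_cut cuts for expression contrasts.
#' @param clr_lfc_cut,clr_padj_cut cuts for CLR contrasts.
#' @return list of the four thresholds.
#' @export
de_thresholds <- function(lfc_cut = 1, padj_cut = 0.05,
                          clr_lfc_cut = 0.1, clr_padj_cut = 0.2) {
  stopifnot(lfc_cut > 0, padj_cut > 0, clr_lfc_cut > 0, clr_padj_cut > 0)
  list(lfc_cut = lfc_cut, padj_cut = padj_cut,
       clr_lfc_cut = clr_lfc_cut, clr_padj_cut = clr_padj_cut)
}

#' Partition features into up / down / unchanged
#'
#' @param results a `DifferentialResult`.
#' @param lfc_cut,padj_cut thresholds (defaults |log2FC| > 1, padj < 0.05).
#' @return list of feature-id vectors: up, down, unchanged (NAs unchanged).
#' @export
classify_significant <- function(results, lfc_cut = 1, padj_cut = 0.05) {
  sig <- !is.na(results$padj) & !is.na(results$log2FoldChange) &
    results$padj < padj_cut & abs(results$log2FoldChange) > lfc_cut
  list(up = results$feature_id[sig & results$log2FoldChange > 0],
       down = results$feature_id[sig & results$log2FoldChange < 0],
       unchanged = results$feature_id[!sig])
}

#' Write a differential result as a DESeq2-compatible TSV
#' @param results a `DifferentialResult`.
#' @param path output file.
#' @export
write_de_results <- function(results, path) {
  fwrite(results[, .(feature_id, baseMean, log2FoldChange, lfcSE, stat,
                     pvalue, padj)], path, sep = "\t")
  invisible(path)
}
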