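test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
              dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  # identical samples give equal factors
  mi <- cbind(A = c(5, 8, 2), B = c(5, 8, 2))
  expect_equal(unname(diff(size_factors(mi))), 0)
  # hand enumeration on a 3-feature toy
  toy <- matrix(c(2, 4, 8, 4, 4, 16, 8, 16, 8), nrow = 3,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  gm <- apply(toy, 1, function(x) exp(mean(log(x))))
  expect_equal(size_factors(toy),
               apply(toy, 2, function(col) median(col / gm)))
  # scale equivariance given all-positive reference features (size factors
  # are defined up to a common scale, so compare factor ratios)
  toy2 <- toy; toy2[, 2] <- toy2[, 2] * 3
  r1 <- size_factors(toy)[2] / size_factors(toy)[1]
  r2 <- size_factors(toy2)[2] / size_factors(toy2)[1]
  expect_equal(unname(r2 / r1), 3)
  # fallback when no feature is positive everywhere
  mz <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_warning(size_factors(mz), "total-count")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  sim <- simulate_cohort_matrix(300, 6, 0, dispersion = 0.2, seed = 501)
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  # DESeq2 takes the median on the log-ratio scale; with an even number of
  # reference features the two medians differ only in how the central pair
  # is averaged, so agreement is near-exact rather than bitwise
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("method-of-moments dispersion recovers simulated alpha", {
  with_poisson <- simulate_cohort_matrix(400, 25, 0, dispersion = 0, seed = 502)
  a_pois <- estimate_dispersion(with_poisson$counts)
  expect_lt(median(a_pois), 0.02)
  with_nb <- simulate_cohort_matrix(400, 25, 0, dispersion = 0.1, seed = 503)
  a_nb <- estimate_dispersion(with_nb$counts)
  expect_gt(median(a_nb), 0.05)
  expect_lt(median(a_nb), 0.2)
  const <- matrix(7, 3, 4)
  expect_equal(estimate_dispersion(const, rep(1, 4)), rep(1e-8, 3))
})

test_that("the NB Wald test is calibrated and recovers planted effects", {
  # identical group means: log2FC 0, p ~ 1
  m <- matrix(rep(c(10, 50, 100), 4), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  res0 <- nb_wald_test(m, c("A", "A", "B", "B"))
  expect_equal(res0$log2FoldChange, rep(0, 3))
  expect_equal(res0$pvalue, rep(1, 3))
  # label swap negates the fold change and preserves the p-value
  sim <- simulate_cohort_matrix(200, 8, 20, effect_log2fc = 1.5,
                                dispersion = 0.1, seed = 504)
  fwd <- nb_wald_test(sim$counts, sim$classes)
  rev_ <- nb_wald_test(sim$counts, factor(sim$classes, levels = c("B", "A")))
  expect_equal(fwd$log2FoldChange, -rev_$log2FoldChange)
  expect_equal(fwd$pvalue, rev_$pvalue)
  # null calibration at moderate scale
  null <- simulate_cohort_matrix(1000, 5, 0, dispersion = 0.1, seed = 505)
  resn <- nb_wald_test(null$counts, null$classes)
  expect_gt(mean(resn$pvalue < 0.05, na.rm = TRUE), 0.02)
  expect_lt(mean(resn$pvalue < 0.05, na.rm = TRUE), 0.08)
  # planted recovery
  pl <- simulate_cohort_matrix(500, 10, 25, effect_log2fc = 2,
                               dispersion = 0.1, seed = 506)
  resp <- nb_wald_test(pl$counts, pl$classes)
  planted <- resp$feature_id %in% pl$informative
  expect_lt(abs(median(resp$log2FoldChange[planted]) - 2), 0.3)
  expect_gte(mean(resp$padj[planted] < 0.05 &
                  abs(resp$log2FoldChange[planted]) > 1), 0.8)
  # all-zero features are flagged NA
  z <- rbind(pl$counts, zero = 0L)
  resz <- nb_wald_test(z, pl$classes)
  expect_true(is.na(resz[feature_id == "zero", pvalue]))
})

test_that("BH adjustment equals an independent step-up enumeration", {
  bh_oracle <- function(p) {
    # literal step-up: padj_(i) = min_{k>=i}(p_(k) * m/k), capped at 1
    m <- length(p)
    o <- order(p)
    padj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    out <- numeric(m)
    out[o] <- pmin(padj_sorted, 1)
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(507)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # NAs excluded from m
  p_na <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p_na), c(bh_oracle(c(0.01, 0.04))[1], NA,
                                  bh_oracle(c(0.01, 0.04))[2]))
})

test_that("permutation CLR test behaves under null and planted shifts", {
  # identical groups: statistic 0, p = 1 within permutation resolution
  clr_id <- matrix(rep(c(1, 2, 4), 8), nrow = 3)
  res_id <- differential_clr(clr_id, rep(c("A", "B"), each = 4), seed = 508)
  expect_equal(res_id$log2FoldChange, rep(0, 3))
  expect_equal(res_id$pvalue, rep(1, 3))
  # planted 4x ratio with tight counts: statistic ~ log2(4) = 2
  set.seed(509)
  base <- matrix(runif(50 * 6, 0.9, 1.1), nrow = 50)
  shifted <- cbind(base[, 1:3], base[, 4:6] * 4)
  res4 <- differential_clr(shifted, rep(c("A", "B"), each = 3), seed = 510)
  expect_lt(max(abs(res4$log2FoldChange - 2)), 0.3)
  # degenerate permutation space: p is NA
  res_deg <- differential_clr(clr_id[, 1:4], rep(c("A", "B"), each = 2),
                              seed = 511)
  expect_true(all(is.na(res_deg$pvalue)))
  # label-permuted planted data yields uniform p-values
  set.seed(512)
  nullmat <- matrix(exp(rnorm(200 * 10)), nrow = 200)
  resn <- differential_clr(nullmat, sample(rep(c("A", "B"), each = 5)),
                           seed = 513)
  ks <- suppressWarnings(ks.test(resn$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significance partition applies both cuts with NA as unchanged", {
  res <- data.table(feature_id = c("a", "b", "c", "d"),
                    log2FoldChange = c(1.2, 1.2, -3, NA),
                    padj = c(0.01, 0.2, 1e-5, NA))
  cls <- classify_significant(res)
  expect_equal(cls$up, "a")
  expect_equal(cls$down, "c")
  expect_setequal(cls$unchanged, c("b", "d"))
})

test_that("a planted excess of up-regulation is recovered proportionally", {
  # 130 up vs 10 down planted (13x), mirroring a strongly asymmetric
  # differentiation response
  circlr:::with_seed(514, {
    base <- exp(rnorm(2000, log(60), 0.6))
    mu <- matrix(base, 2000, 20)
    mu[1:130, 11:20] <- mu[1:130, 11:20] * 4
    mu[131:140, 11:20] <- mu[131:140, 11:20] / 4
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 2000, 20,
                     dimnames = list(sprintf("f%04d", 1:2000), NULL))
    res <- nb_wald_test(counts, rep(c("A", "B"), each = 10))
    sig <- classify_significant(res)
    ratio <- length(sig$up) / length(sig$down)
    expect_gt(ratio, 13 * 0.7)
    expect_lt(ratio, 13 * 1.3)
  })
})
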