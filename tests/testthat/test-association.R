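test_that("call masking and variant QC apply the printed thresholds", {
  n <- 100
  dosage <- matrix(rep(c(0L, 1L, 2L, 1L), each = n / 4), ncol = 1)
  dp <- matrix(30L, n, 1); gq <- matrix(60L, n, 1)
  dp[1:11, 1] <- 19L                       # 11 calls below DP 20
  gd <- genotype_dataset(
    data.frame(sample_id = sprintf("S%03d", 1:n),
               status = rep(c(1L, 0L), n / 2)),
    data.frame(variant_id = "v1", contig = "chr1", pos = 100L,
               ref = "A", alt = "G", biallelic = TRUE),
    dosage, dp = dp, gq = gq)
  masked <- apply_call_mask(gd)
  expect_equal(sum(is.na(masked$dosage)), 11)
  qc <- variant_qc(masked)
  expect_equal(qc$call_rate, 0.89)
  expect_false(qc$pass)                    # 0.11 > 0.1 missing
  expect_match(qc$reason, "high_missing")

  # boundary behaviors: DP = 20 kept, GQ = 30 masked
  gd$dp[, 1] <- 20L; gd$gq[, 1] <- 31L
  expect_equal(sum(is.na(apply_call_mask(gd)$dosage)), 0)
  gd$gq[1, 1] <- 30L
  expect_equal(sum(is.na(apply_call_mask(gd)$dosage)), 1)

  # MAF rule is strict: 0.04 fails, 0.3 with full calls passes
  d2 <- matrix(c(rep(1L, 8), rep(0L, 92),
                 rep(c(0L, 1L, 2L, 1L), 25)), ncol = 2)
  gd2 <- genotype_dataset(
    gd$samples,
    data.frame(variant_id = c("rare", "common"), contig = "chr1",
               pos = c(1L, 2L), ref = "A", alt = "G",
               biallelic = TRUE),
    d2)
  qc2 <- variant_qc(gd2)
  expect_equal(qc2$maf[1], 0.04)
  expect_false(qc2$pass[1])
  expect_true(qc2$pass[2])
  # requested but absent variant
  qc3 <- variant_qc(gd2, variant_ids = c("common", "ghost"))
  expect_identical(qc3$reason[2], "missing_from_data")
})

test_that("logistic fit equals the closed-form 2x2 OR and a grid oracle", {
  # carriers: cases 30/100, controls 15/100 -> OR = (30*85)/(70*15)
  dosage <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  status <- rep(c(1, 0), each = 100)
  fit <- fit_additive_logistic(dosage, status)
  or_expected <- (30 * 85) / (70 * 15)
  expect_equal(fit$or_, or_expected, tolerance = 1e-6)
  expect_equal(fit$beta, log(or_expected), tolerance = 1e-6)
  expect_true(fit$ci_lo < fit$or_ && fit$or_ < fit$ci_hi)
  # independent grid-search likelihood maximization
  beta_grid <- grid_logistic_beta(dosage, status)
  expect_equal(fit$beta, beta_grid, tolerance = 1e-4)
})

test_that("separation is flagged and degenerate inputs error", {
  dosage <- c(rep(1, 20), rep(0, 20))
  status <- c(rep(1, 20), rep(0, 20))     # perfect separation
  fit <- fit_additive_logistic(dosage, status)
  expect_true(fit$separation)
  firth <- fit_additive_logistic(dosage, status, firth = TRUE)
  expect_false(firth$separation)
  expect_true(is.finite(firth$beta))
  expect_error(fit_additive_logistic(rep(1, 40), status),
               "constant dosage")
  expect_error(fit_additive_logistic(dosage, rep(1, 40)),
               "case and one control")
})

test_that("null scan at n=10^3 gives OR near 1 and uniform p", {
  set.seed(31)
  n <- 1000
  status <- rep(c(1, 0), each = n / 2)
  ors <- replicate(50, {
    fit_additive_logistic(rbinom(n, 2, 0.3), status)$or_
  })
  expect_equal(mean(ors), 1, tolerance = 0.05)
})

test_that("genomic inflation: identity at p=0.5, scale equivariance, null ~1", {
  expect_equal(genomic_inflation(rep(0.5, 99))$lambda_gc, 1)
  set.seed(17)
  p <- runif(1e5)
  lam <- genomic_inflation(p)$lambda_gc
  expect_equal(lam, 1, tolerance = 0.02)
  # doubling every chi-square doubles lambda
  chisq <- qchisq(1 - p, df = 1)
  p2 <- 1 - pchisq(2 * chisq, df = 1)
  expect_equal(genomic_inflation(p2)$lambda_gc, 2 * lam,
               tolerance = 1e-6)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("BH FDR matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand computation: p*m/rank with cumulative minimum from the bottom
  p <- c(0.005, 0.1, 0.03, 0.9)
  expect_equal(bh_fdr(p), c(0.02, 0.1333333333, 0.06, 0.9),
               tolerance = 1e-9)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise r2: identical = 1, sign-free, independent ~ 0", {
  set.seed(23)
  a <- rbinom(10000, 2, 0.4)
  expect_equal(pairwise_r2(a, a), 1)
  expect_equal(pairwise_r2(a, 2 - a), 1)
  b <- rbinom(10000, 2, 0.4)
  expect_lt(pairwise_r2(a, b), 0.01)
  expect_error(pairwise_r2(a, rep(1, 10000)), "constant")
})

test_that("greedy clumping follows the traced rules and ignores row order", {
  set.seed(29)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  corrupt <- function(g, rate) {
    flip <- rbinom(n, 1, rate)
    ifelse(flip == 1, rbinom(n, 2, 0.5), g)
  }
  A <- base
  B <- corrupt(base, 0.15)      # r2(A,B) high
  C <- corrupt(B, 0.15)         # r2(B,C) high, r2(A,C) lower
  # ensure the fixture realizes the intended chain geometry
  stopifnot(pairwise_r2(A, B) >= 0.6, pairwise_r2(B, C) >= 0.6,
            pairwise_r2(A, C) < 0.6)
  dosage <- cbind(A, B, C)
  gd <- genotype_dataset(
    data.frame(sample_id = sprintf("S%04d", 1:n),
               status = rep(c(1L, 0L), n / 2)),
    data.frame(variant_id = c("A", "B", "C"), contig = "chr1",
               pos = c(1000L, 2000L, 3000L), ref = "A", alt = "G",
               biallelic = TRUE),
    dosage)
  res <- data.frame(variant_id = c("A", "B", "C"), contig = "chr1",
                    pos = c(1000L, 2000L, 3000L), alt = "G",
                    beta = 1, p = c(1e-6, 1e-5, 1e-4))
  cl <- ld_clump(res, gd)
  expect_identical(cl$clump_id, c(1L, 1L, 2L))   # {A,B}, {C}
  expect_identical(cl$is_index, c(TRUE, FALSE, TRUE))
  # index = lowest p in the block
  expect_identical(cl$variant_id[cl$is_index & cl$clump_id == 1], "A")
  # row order invariance
  cl2 <- ld_clump(res[c(3, 1, 2), ], gd)
  expect_identical(cl2$clump_id[order(cl2$variant_id)],
                   cl$clump_id[order(cl$variant_id)])
  # all-independent variants: every variant its own index
  gd2 <- gd; gd2$dosage <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.5),
                                 rbinom(n, 2, 0.5))
  cl3 <- ld_clump(res, gd2)
  expect_true(all(cl3$is_index))
})
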