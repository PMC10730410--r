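make_gd <- function(dosage, contig = "chr1",
                    pos = seq_len(ncol(dosage)) * 1000L) {
  n <- nrow(dosage); m <- ncol(dosage)
  genotype_dataset(
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               status = rep(c(1L, 0L), length.out = n)),
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               contig = contig, pos = pos,
               ref = "A", alt = "G", biallelic = TRUE),
    dosage)
}

test_that("ld_prune keeps one of a duplicate pair, all independents, and matches a brute-force check", {
  set.seed(42)
  a <- rbinom(100, 2, 0.4)
  dup <- make_gd(cbind(a, a))
  kept <- ld_prune(dup, r2_threshold = 0.2)
  expect_length(kept, 1)
  expect_identical(kept, "v001")       # later variant dropped

  indep <- make_gd(vapply(1:6, function(i) rbinom(200, 2, 0.3),
                          integer(200)))
  expect_length(ld_prune(indep, r2_threshold = 0.2), 6)

  # correlated 5-variant block: retained set must violate nothing
  base <- rbinom(300, 2, 0.5)
  block <- vapply(1:5, function(i) {
    flip <- rbinom(300, 1, 0.15 * i)
    ifelse(flip == 1, sample(0:2, 300, TRUE), base)
  }, integer(300))
  gd <- make_gd(block)
  kept <- ld_prune(gd, r2_threshold = 0.2)
  idx <- match(kept, gd$variants$variant_id)
  if (length(idx) > 1)
    for (i in seq_along(idx))
      for (j in seq_len(i - 1))
        expect_lte(pairwise_r2(block[, idx[i]], block[, idx[j]]), 0.2)
  expect_error(ld_prune(gd, window_size = 10, step = 20), "window_size")
})

test_that("PCA separates diverged populations and projection is exact", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_variants = 400,
                    n_genes = 5, seed = 3,
                    planted_risk = data.frame(or_ = numeric(0),
                                              gene = character(0),
                                              eqtl_beta = numeric(0),
                                              maf = numeric(0)),
                    populations = data.frame(
                      label = c("POP1", "POP2"), frac = c(0.5, 0.5),
                      fst = c(0.2, 0.2)))
  gd <- simulate_cohort(cfg)
  pca <- suppressWarnings(compute_pca(gd, k = 4))
  pop <- gd$samples$population
  pc1 <- pca$scores[, 1]
  # strong divergence: PC1 ranges of the two populations do not overlap
  expect_true(max(pc1[pop == "POP1"]) < min(pc1[pop == "POP2"]) ||
              max(pc1[pop == "POP2"]) < min(pc1[pop == "POP1"]))
  # projecting a training sample reproduces its own score
  proj <- project_pca(gd$dosage[c(1, 5), pca$variant_id], pca)
  expect_equal(unname(proj), unname(pca$scores[c(1, 5), ]),
               tolerance = 1e-8)
  expect_error(compute_pca(gd, k = nrow(gd$samples)), "k must be")
})

test_that("ancestry mixture recovers centroids, midpoints, and the 90% gate", {
  set.seed(7)
  k <- 10
  labs <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  centroids <- matrix(rnorm(5 * k, sd = 8), 5, k)
  ref_labels <- rep(labs, each = 40)
  ref <- centroids[rep(1:5, each = 40), ] + matrix(rnorm(200 * k), 200, k)
  # pure sample at the EUR centroid
  est <- estimate_ancestry(centroids[4, , drop = FALSE], ref, ref_labels)
  expect_gt(est$EUR, 0.99)
  expect_true(est$retained)
  # exact 50/50 midpoint of EUR and AFR centroids
  mid <- (centroids[4, ] + centroids[1, ]) / 2
  est2 <- estimate_ancestry(matrix(mid, 1), ref, ref_labels)
  expect_equal(est2$EUR, 0.5, tolerance = 0.05)
  expect_equal(est2$AFR, 0.5, tolerance = 0.05)
  # EUR weight just under 0.90 is excluded
  p89 <- 0.89 * centroids[4, ] + 0.11 * centroids[1, ]
  est3 <- estimate_ancestry(matrix(p89, 1), ref, ref_labels)
  expect_false(est3$retained)
  expect_equal(rowSums(as.matrix(est3[labs])), 1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("IBD moments: duplicates ~1, parent-offspring ~0.5, unrelated ~0", {
  set.seed(11)
  m <- 5000
  af <- runif(m, 0.1, 0.5)
  draw <- function() rbinom(m, 2, af)
  # parent-offspring by Mendelian transmission
  transmit <- function(g) ifelse(g == 1, rbinom(m, 1, 0.5), g / 2)
  p1 <- draw(); p2 <- draw()
  child <- transmit(p1) + transmit(p2)
  unrel <- draw()
  dosage <- rbind(p1, p1, child, unrel)   # row 2 duplicates row 1
  rownames(dosage) <- c("dup1", "dup2", "child", "unrel")
  ibd <- estimate_ibd(dosage, af = af)
  get <- function(a, b)
    ibd$pihat[(ibd$id1 == a & ibd$id2 == b) |
              (ibd$id1 == b & ibd$id2 == a)]
  expect_equal(get("dup1", "dup2"), 1, tolerance = 0.02)
  expect_equal(get("dup1", "child"), 0.5, tolerance = 0.05)
  expect_lt(get("dup1", "unrel"), 0.05)
})

test_that("remove_relateds drops one member per flagged pair, reproducibly", {
  set.seed(13)
  m <- 3000
  af <- runif(m, 0.2, 0.5)
  g <- rbinom(m, 2, af)
  dosage <- rbind(A = g, B = g,
                  C = rbinom(m, 2, af), D = rbinom(m, 2, af))
  ibd <- estimate_ibd(dosage, af = af)
  kept <- remove_relateds(ibd, seed = 5, sample_ids = rownames(dosage))
  expect_length(kept, 3)
  expect_length(intersect(kept, c("A", "B")), 1)
  expect_identical(kept,
                   remove_relateds(ibd, seed = 5,
                                   sample_ids = rownames(dosage)))
  # after pruning no retained pair exceeds the threshold
  sub <- ibd[ibd$id1 %in% kept & ibd$id2 %in% kept, ]
  expect_true(all(sub$pihat <= 0.12))
})
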