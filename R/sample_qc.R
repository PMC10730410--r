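# Sample-level QC gates: LD pruning, principal components, ancestry
# estimation as a constrained mixture over reference-population centroids
# in PC space, and relatedness pruning on PLINK-style method-of-moments
# IBD estimates (pi-hat > 0.12 flags third-degree-or-closer pairs).

#' Greedy windowed LD pruning
#'
#' Slides a window (in variants) across the genome; within each window,
#' any pair with dosage-correlation r-squared above the threshold loses
#' its later member (position order). After pruning, no retained
#' within-window pair exceeds the threshold.
#'
#' @param gd a `genotype_dataset`.
#' @param r2_threshold prune when pairwise r^2 exceeds this value.
#' @param window_size window width in variants.
#' @param step window advance in variants; must not exceed `window_size`.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(gd, r2_threshold = 0.2, window_size = 50L,
                     step = 25L) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (window_size < step) stop("window_size must be >= step")
  v <- gd$variants
  keep <- rep(TRUE, nrow(v))
  ord <- order(v$contig, v$pos)
  for (ct in unique(v$contig)) {
    idx <- ord[v$contig[ord] == ct]
    start <- 1L
    while (start <= length(idx)) {
      win <- idx[start:min(start + window_size - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) > 1) {
        d <- gd$dosage[, win, drop = FALSE]
        cc <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
        cc[is.na(cc)] <- 0
        r2 <- cc^2
        alive <- rep(TRUE, length(win))
        for (i in seq_along(win)) {
          if (!alive[i]) next
          for (j in seq_len(i - 1L)) {
            if (alive[j] && r2[i, j] > r2_threshold) {
              alive[i] <- FALSE  # drop the later variant
              break
            }
          }
        }
        keep[win[!alive]] <- FALSE
      }
      start <- start + step
    }
  }
  v$variant_id[keep]
}

#' Genotype principal components
#'
#' Standardizes each variant by mean `2p` and SD `sqrt(2p(1-p))`
#' (missing calls imputed to the mean), then takes the top-k left
#' singular vectors. Monomorphic variants are dropped with a warning.
#'
#' @param gd a `genotype_dataset` (or a samples x variants dosage
#'   matrix).
#' @param k number of components (default 10); must be < n samples.
#' @return list of class `genotype_pca`: `scores` (n x k), `loadings`
#'   (m x k), `af`, `variant_id`, `d` (singular values).
#' @export
compute_pca <- function(gd, k = 10L) {
  dosage <- if (inherits(gd, "genotype_dataset")) gd$dosage else gd
  n <- nrow(dosage)
  if (k > n - 1L) stop("k must be at most n_samples - 1")
  p <- colMeans(dosage, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) dropped before PCA")
    dosage <- dosage[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  X <- sweep(dosage, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  s <- svd(X, nu = k, nv = k)
  scores <- s$u %*% diag(s$d[seq_len(k)], k)
  colnames(scores) <- colnames(s$v) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = s$v, af = p,
                 variant_id = colnames(dosage), d = s$d[seq_len(k)]),
            class = "genotype_pca")
}

#' Project new samples onto fitted principal components
#'
#' Standardizes with the training allele frequencies and multiplies by
#' the variant loadings; projecting a training sample reproduces its own
#' score.
#'
#' @param dosage samples x variants matrix over the PCA's variants (same
#'   order).
#' @param pca a `genotype_pca`.
#' @return scores matrix (n x k).
#' @export
project_pca <- function(dosage, pca) {
  stopifnot(inherits(pca, "genotype_pca"))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  X <- sweep(dosage, 2, 2 * pca$af)
  X <- sweep(X, 2, sqrt(2 * pca$af * (1 - pca$af)), "/")
  X[is.na(X)] <- 0
  X %*% pca$loadings
}

#' Ancestry proportions by constrained GLS on population centroids
#'
#' Models each sample's top-k PC score vector as a mixture of the five
#' reference-population centroids, solved by generalized least squares
#' under the Mahalanobis metric defined by the pooled within-population
#' PC covariance, with the weights constrained to sum to one and then
#' clamped to the simplex. Samples are retained when the European-type
#' weight is at least `min_weight` (default 0.90).
#'
#' @param scores sample scores (n x k), same PC space as the reference.
#' @param ref_scores reference-panel scores (r x k).
#' @param ref_labels population label per reference sample (e.g. EUR,
#'   AFR, EAS, AMR, SAS).
#' @param eur_label label whose weight gates retention.
#' @param min_weight retention threshold on `eur_label`'s weight.
#' @param ridge optional ridge added to the covariance diagonal (for
#'   near-singular panels).
#' @return data.frame: one row per sample, one weight column per
#'   population, plus `retained`.
#' @export
estimate_ancestry <- function(scores, ref_scores, ref_labels,
                              eur_label = "EUR", min_weight = 0.90,
                              ridge = 0) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  labs <- sort(unique(ref_labels))
  centroids <- t(vapply(labs, function(l)
    colMeans(ref_scores[ref_labels == l, , drop = FALSE]),
    numeric(ncol(ref_scores))))          # pops x k
  centered <- ref_scores - centroids[match(ref_labels, labs), ,
                                     drop = FALSE]
  S <- crossprod(centered) / max(nrow(ref_scores) - length(labs), 1)
  if (ridge > 0) S <- S + diag(ridge, ncol(S))
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular within-population covariance; supply a ridge term"))
  A <- t(centroids)                      # k x pops
  M <- t(A) %*% Sinv %*% A
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular centroid system; supply a ridge term"))
  one <- rep(1, length(labs))
  W <- t(apply(scores, 1, function(x) {
    b <- t(A) %*% Sinv %*% x
    w <- Minv %*% b
    # enforce sum-to-one by the Lagrange correction, then clamp
    w <- w + Minv %*% one *
      as.numeric((1 - sum(w)) / (t(one) %*% Minv %*% one))
    w <- pmax(as.numeric(w), 0)
    w / sum(w)
  }))
  colnames(W) <- labs
  out <- as.data.frame(W)
  out$retained <- if (eur_label %in% labs)
    out[[eur_label]] >= min_weight else NA
  out
}

#' Method-of-moments IBD estimates for all sample pairs
#'
#' PLINK-style IBS decomposition: per-pair counts of IBS 0/1/2 are
#' compared with their allele-frequency expectations under IBD 0/1/2 to
#' give moment estimates of P(IBD = k), clamped to [0,1] and normalized;
#' pi-hat = P(IBD=2) + P(IBD=1)/2.
#'
#' @param gd a `genotype_dataset` (or dosage matrix); complete genotypes
#'   assumed (missing calls excluded per pair would require per-pair
#'   expectations).
#' @param af optional allele frequencies; defaults to sample frequencies.
#' @return data.frame: `id1`, `id2`, `ibd0`, `ibd1`, `ibd2`, `pihat`.
#' @export
estimate_ibd <- function(gd, af = NULL) {
  dosage <- if (inherits(gd, "genotype_dataset")) gd$dosage else gd
  ids <- rownames(dosage) %||% as.character(seq_len(nrow(dosage)))
  if (nrow(dosage) < 2)
    return(data.frame(id1 = character(0), id2 = character(0),
                      ibd0 = numeric(0), ibd1 = numeric(0),
                      ibd2 = numeric(0), pihat = numeric(0)))
  if (is.null(af)) af <- colMeans(dosage, na.rm = TRUE) / 2
  informative <- af > 0 & af < 1
  dosage <- dosage[, informative, drop = FALSE]
  p <- af[informative]; q <- 1 - p
  m <- length(p)
  # one-hot genotype indicators give all IBS counts as matrix products
  I0 <- (dosage == 0L) * 1; I1 <- (dosage == 1L) * 1
  I2 <- (dosage == 2L) * 1
  N2 <- I0 %*% t(I0) + I1 %*% t(I1) + I2 %*% t(I2)   # IBS = 2
  N0 <- I0 %*% t(I2) + I2 %*% t(I0)                  # IBS = 0
  N1 <- m - N2 - N0
  # per-locus IBS probabilities given IBD state, summed over loci
  e0_0 <- sum(2 * p^2 * q^2)
  e1_0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  pairs <- which(upper.tri(N2), arr.ind = TRUE)
  P0 <- N0[pairs] / e0_0
  P1 <- (N1[pairs] - P0 * e1_0) / e1_1
  P2 <- (N2[pairs] - P0 * e2_0 - P1 * e2_1) / m
  est <- cbind(P0, P1, P2)
  est[est < 0] <- 0; est[est > 1] <- 1
  est <- est / rowSums(est)
  data.frame(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
             ibd0 = est[, 1], ibd1 = est[, 2], ibd2 = est[, 3],
             pihat = est[, 3] + est[, 2] / 2,
             stringsAsFactors = FALSE)
}

#' Prune related samples by pi-hat
#'
#' Flags pairs with pi-hat above the threshold (default 0.12, third
#' degree or closer) and removes one random member of each flagged pair.
#' Pairs are processed sorted by descending pi-hat then pair id, and the
#' removal draws are seeded, so the retained set is reproducible.
#'
#' @param ibd output of [estimate_ibd()] (or a `genotype_dataset`, in
#'   which case IBD is estimated first).
#' @param pihat_threshold flag pairs strictly above this value.
#' @param seed seed for the random member choice.
#' @param sample_ids full id set (needed when passing an `ibd` table so
#'   unflagged singletons are retained); inferred for a dataset.
#' @return Character vector of retained sample ids.
#' @export
remove_relateds <- function(ibd, pihat_threshold = 0.12, seed = 1L,
                            sample_ids = NULL) {
  if (inherits(ibd, "genotype_dataset")) {
    sample_ids <- ibd$samples$sample_id
    ibd <- estimate_ibd(ibd)
  }
  if (is.null(sample_ids))
    sample_ids <- unique(c(ibd$id1, ibd$id2))
  if (length(sample_ids) < 2) return(sample_ids)
  flagged <- ibd[ibd$pihat > pihat_threshold, , drop = FALSE]
  flagged <- flagged[order(-flagged$pihat, flagged$id1, flagged$id2), ,
                     drop = FALSE]
  removed <- character(0)
  with_seed(substream_seed(seed, "relateds"), {
    for (i in seq_len(nrow(flagged))) {
      a <- flagged$id1[i]; b <- flagged$id2[i]
      if (a %in% removed || b %in% removed) next
      removed <- c(removed, sample(c(a, b), 1))
    }
  })
  setdiff(sample_ids, removed)
}
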