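# Per-variant QC, additive case/control logistic association, genomic
# inflation, BH FDR, composite-LD r-squared, and greedy LD clumping with
# FDR selection of index eQTLs. Threshold conventions follow the printed
# rules exactly: per-call masking at DP < 20 or GQ <= 30, then fail a
# variant when it is non-biallelic, MAF <= 0.05, or missing in more than
# 10% of individuals; clumping at r^2 >= 0.6; index significance at
# FDR < 0.1 computed over index variants only, after clumping.

#' Mask low-quality genotype calls
#'
#' Sets dosage to missing wherever read depth is below `dp_min` (calls
#' with DP >= 20 are kept) or genotype quality is at or below `gq_gt`
#' (only GQ > 30 is kept). When no call-quality matrices are present the
#' dataset passes through with a warning (configurable to an error).
#'
#' @param gd a `genotype_dataset`.
#' @param dp_min minimum read depth retained (default 20, kept when
#'   DP >= 20).
#' @param gq_gt strict genotype-quality floor (default 30, kept when
#'   GQ > 30).
#' @param require_quality error (instead of warn) when DP/GQ are absent.
#' @return The dataset with masked calls set to `NA`.
#' @export
apply_call_mask <- function(gd, dp_min = 20L, gq_gt = 30L,
                            require_quality = FALSE) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (is.null(gd$dp) || is.null(gd$gq)) {
    msg <- "no per-call DP/GQ present; quality mask skipped"
    if (require_quality) stop(msg)
    warning(msg)
    return(gd)
  }
  mask <- gd$dp < dp_min | gd$gq <= gq_gt
  gd$dosage[mask] <- NA_integer_
  gd
}

#' Per-variant quality control
#'
#' Computes call rate and minor-allele frequency on the (already masked)
#' dosages over all analyzed samples, and fails a variant when it is
#' non-biallelic, its MAF is not strictly above `maf_min`, or its
#' missing fraction exceeds `max_missing`. Variants requested but absent
#' from the data are recorded as `missing_from_data` and excluded.
#'
#' @param gd a `genotype_dataset` (apply [apply_call_mask()] first when
#'   DP/GQ are available).
#' @param variant_ids variants to assess (default: all in `gd`).
#' @param maf_min strict MAF floor (default 0.05).
#' @param max_missing maximum tolerated missing fraction (default 0.1;
#'   strictly above fails).
#' @return data.frame: `variant_id`, `maf`, `call_rate`, `biallelic`,
#'   `pass`, `reason`.
#' @export
variant_qc <- function(gd, variant_ids = NULL, maf_min = 0.05,
                       max_missing = 0.1) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (is.null(variant_ids)) variant_ids <- gd$variants$variant_id
  idx <- match(variant_ids, gd$variants$variant_id)
  out <- data.frame(variant_id = variant_ids, maf = NA_real_,
                    call_rate = NA_real_, biallelic = NA,
                    pass = FALSE, reason = "", stringsAsFactors = FALSE)
  absent <- is.na(idx)
  out$reason[absent] <- "missing_from_data"
  if (all(absent)) return(out)
  j <- idx[!absent]
  d <- gd$dosage[, j, drop = FALSE]
  cr <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  bi <- gd$variants$biallelic[j]
  reasons <- mapply(function(b, m, c) {
    r <- character(0)
    if (!b) r <- c(r, "non_biallelic")
    if (!(m > maf_min)) r <- c(r, "low_maf")
    if ((1 - c) > max_missing) r <- c(r, "high_missing")
    paste(r, collapse = ";")
  }, bi, maf, cr)
  out$maf[!absent] <- maf
  out$call_rate[!absent] <- cr
  out$biallelic[!absent] <- bi
  out$reason[!absent] <- reasons
  out$pass[!absent] <- reasons == ""
  out
}

# logistic ML fit with Wald statistics via IRLS (glm.fit); X includes
# the intercept column. Returns coefficients, SEs and diagnostics.
logistic_wald <- function(X, y) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  w <- fit$weights
  ok <- !is.na(beta)         # aliased (collinear) columns get NA SEs
  XtWX <- crossprod(X[, ok, drop = FALSE] * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se <- rep(NA_real_, length(beta))
  if (!is.null(cov)) se[ok] <- sqrt(diag(cov))
  mu <- fit$fitted.values
  separation <- !fit$converged ||
    any(abs(beta) > 15, na.rm = TRUE) ||
    (any(mu < 1e-10) || any(mu > 1 - 1e-10))
  list(beta = beta, se = se, converged = fit$converged,
       separation = separation)
}

# Firth bias-reduced logistic fit (Jeffreys-prior penalty); used as the
# optional fallback under separation.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(w))
    XtWXinv <- solve(XtWX)
    H <- (X * sqrt(w)) %*% XtWXinv %*% t(X * sqrt(w))
    h <- diag(H)
    U <- as.numeric(t(X) %*% (y - mu + h * (0.5 - mu)))
    step <- as.numeric(XtWXinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- plogis(as.numeric(X %*% beta))
  se <- sqrt(diag(solve(crossprod(X * sqrt(mu * (1 - mu))))))
  list(beta = beta, se = se, converged = it < max_iter,
       separation = FALSE)
}

#' Additive logistic association for one variant
#'
#' Maximum-likelihood logistic regression of case status on allele
#' dosage plus covariates; Wald z and two-sided p; OR and 95% CI as exp
#' transforms of the dosage coefficient. Samples with missing dosage are
#' dropped for this variant. Perfect separation is flagged (the result
#' is marked unstable); a Firth bias-reduced refit is available behind
#' `firth`.
#'
#' @param dosage numeric vector of alt-allele counts (NA = missing).
#' @param status 0/1 case status.
#' @param covariates optional numeric matrix / data.frame of covariates.
#' @param firth refit with the Firth penalty when separation is
#'   detected.
#' @return one-row data.frame: `beta`, `se`, `z`, `or_`, `ci_lo`,
#'   `ci_hi`, `p`, `n`, `converged`, `separation`.
#' @export
fit_additive_logistic <- function(dosage, status, covariates = NULL,
                                  firth = FALSE) {
  keep <- !is.na(dosage) & !is.na(status)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & complete.cases(covariates)
  }
  d <- dosage[keep]; y <- status[keep]
  if (length(unique(y)) < 2) stop("need at least one case and one control")
  if (length(unique(d)) < 2) stop("constant dosage")
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (!is.null(covariates))
    X <- cbind(X, covariates[keep, , drop = FALSE])
  res <- logistic_wald(X, y)
  if (res$separation && firth) res <- firth_logistic(X, y)
  b <- res$beta[2]; se <- res$se[2]
  z <- b / se
  data.frame(beta = b, se = se, z = z, or_ = exp(b),
             ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
             p = 2 * pnorm(-abs(z)), n = length(y),
             converged = res$converged, separation = res$separation,
             row.names = NULL)
}

#' Association scan over a variant test set
#'
#' Runs [fit_additive_logistic()] per variant (samples with masked
#' calls dropped variant-wise), adjusting for sex and the ancestry
#' covariate columns. Monomorphic or separated variants are flagged;
#' BH-adjusted q-values across the scanned variants are appended.
#'
#' @param gd a (masked) `genotype_dataset` whose sample table carries
#'   `status`, `sex` and the covariate columns.
#' @param variant_ids variants to test (default: all).
#' @param covariate_cols columns of the sample table used as covariates
#'   (`sex` is recoded 0/1).
#' @param firth pass-through to the per-variant fit.
#' @return data.frame: variant key columns plus `beta`, `se`, `z`,
#'   `or_`, `ci_lo`, `ci_hi`, `p`, `q`, `n`, flags.
#' @export
assoc_scan <- function(gd, variant_ids = NULL,
                       covariate_cols = c("sex", paste0("PC", 1:10)),
                       firth = FALSE) {
  stopifnot(inherits(gd, "genotype_dataset"))
  if (is.null(variant_ids)) variant_ids <- gd$variants$variant_id
  covariate_cols <- intersect(covariate_cols, names(gd$samples))
  covs <- gd$samples[, covariate_cols, drop = FALSE]
  if ("sex" %in% names(covs))
    covs$sex <- as.numeric(covs$sex == "F")
  covs <- as.matrix(covs)
  status <- gd$samples$status
  idx <- match(variant_ids, gd$variants$variant_id)
  rows <- lapply(seq_along(variant_ids), function(i) {
    j <- idx[i]
    if (is.na(j)) return(NULL)
    d <- gd$dosage[, j]
    res <- tryCatch(
      fit_additive_logistic(d, status, covs, firth = firth),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(gd$variants[j, c("variant_id", "contig", "pos", "ref", "alt")],
          res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no testable variants in the scan")
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out$neglog10p <- -log10(out$p)
  out
}

#' Genomic inflation factor
#'
#' Lambda = median of the association chi-square statistics
#' (qchisq(1 - p, df = 1)) divided by the null median chi-square
#' (qchisq(0.5, 1) = 0.4549...). Approximately 1 in the absence of
#' stratification or systematic inflation.
#'
#' @param pvalues p-values in (0, 1].
#' @return list of class `inflation_stat` with `lambda_gc` and `n`.
#' @export
genomic_inflation <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0) stop("no p-values supplied")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  chisq <- qchisq(1 - pvalues, df = 1)
  structure(list(lambda_gc = median(chisq) / qchisq(0.5, df = 1),
                 n = length(pvalues)),
            class = "inflation_stat")
}

#' @export
print.inflation_stat <- function(x, ...) {
  cat(sprintf("genomic inflation lambda = %.4f (%d tests)\n",
              x$lambda_gc, x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement; input order preserved.
#' @param pvalues p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Composite LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of genotype dosages over shared
#' non-missing samples (genotype-based composite LD, not
#' haplotype-based).
#'
#' @param dosage_a,dosage_b numeric dosage vectors.
#' @return r^2 in [0, 1].
#' @export
pairwise_r2 <- function(dosage_a, dosage_b) {
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[keep]; b <- dosage_b[keep]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("r^2 undefined for a constant dosage vector")
  cor(a, b)^2
}

#' Greedy LD clumping and FDR index-eQTL selection
#'
#' Sorts tested variants by p ascending (ties by position then alt
#' allele); repeatedly takes the best unassigned variant as an index and
#' assigns to its clump every unassigned variant on the same contig
#' within the window whose dosage r^2 with the index is at or above the
#' threshold. BH FDR is then computed over the index variants' p-values
#' only; indices with q strictly below `fdr_threshold` are significant.
#'
#' @param results an [assoc_scan()] data.frame.
#' @param gd the `genotype_dataset` supplying dosages for r^2.
#' @param r2_threshold clump membership at r^2 >= this value (default
#'   0.6).
#' @param fdr_threshold strict index significance threshold (default
#'   0.1).
#' @param window maximum index-member distance in bp (default 1 Mb).
#' @return `results` with `clump_id`, `is_index`, `q_index` (index rows
#'   only), `significant` appended; row order = input order.
#' @export
ld_clump <- function(results, gd, r2_threshold = 0.6,
                     fdr_threshold = 0.1, window = 1e6) {
  stopifnot(is.data.frame(results), inherits(gd, "genotype_dataset"))
  ord <- order(results$p, results$pos, results$alt)
  jmap <- match(results$variant_id, gd$variants$variant_id)
  n <- nrow(results)
  clump <- rep(NA_integer_, n)
  is_index <- rep(FALSE, n)
  cid <- 0L
  for (i in ord) {
    if (!is.na(clump[i])) next
    cid <- cid + 1L
    clump[i] <- cid
    is_index[i] <- TRUE
    near <- which(is.na(clump) &
                  results$contig == results$contig[i] &
                  abs(results$pos - results$pos[i]) <= window)
    if (length(near)) {
      di <- gd$dosage[, jmap[i]]
      for (k in near) {
        r2 <- tryCatch(pairwise_r2(di, gd$dosage[, jmap[k]]),
                       error = function(e) 0)
        if (r2 >= r2_threshold) clump[k] <- cid
      }
    }
  }
  results$clump_id <- clump
  results$is_index <- is_index
  results$q_index <- NA_real_
  results$q_index[is_index] <- bh_fdr(results$p[is_index])
  results$significant <- !is.na(results$q_index) &
    results$q_index < fdr_threshold
  results
}
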