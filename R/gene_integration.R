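# Gene-level Bayesian integration of eQTL and association evidence.
# Each gene is scored by a log10 Bayes factor built from Wakefield
# approximate Bayes factors of its eQTLs' association z-scores, mixed
# with a prior probability pi1 that an eQTL is also trait-associated.
# eQTLs unsupported by association (bf < 1) pull the score down, so a
# positive LBF means the gene's eQTL set collectively supports a trait
# link. Significance is empirical, by size-matched random eQTL sets
# drawn from the tested-variant pool.

#' Wakefield approximate Bayes factor for one association signal
#'
#' bf = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W))), the Bayes factor
#' for "associated with prior effect variance W" versus null, given a
#' Wald z-score with sampling variance V = SE^2. Its expectation under
#' the null (z ~ N(0,1)) is 1.
#'
#' @param z association z-score(s); must be finite.
#' @param V sampling variance (SE^2) of the log-odds estimate, > 0.
#' @param W prior variance of the trait log-odds effect at a true joint
#'   signal, > 0.
#' @return Bayes factor(s), vectorized over `z`/`V`.
#' @export
snp_bayes_factor <- function(z, V, W) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(V <= 0) || any(W <= 0)) stop("V and W must be positive")
  sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
}

# per-eQTL LBF contribution under the pi1 mixture; the null offset
# log10(pi1 * E0[bf] + (1 - pi1)) is 0 because E0[bf] = 1.
lbf_terms <- function(z, V, W, pi1) {
  log10(pi1 * snp_bayes_factor(z, V, W) + (1 - pi1))
}

#' Gene-level log Bayes factor with permutation p-value
#'
#' LBF = sum over the gene's eQTLs of
#' log10(pi1 * bf_i + (1 - pi1)); the null offset vanishes because the
#' null expectation of each Bayes factor is 1, so null eQTLs contribute
#' about zero and sub-null eQTLs (bf < 1) contribute negatively. The
#' empirical p draws B size-matched random eQTL sets from the
#' tested-variant pool: p_emp = (b + 1) / (B + 1) with b = number of
#' permuted LBFs at or above the observed one.
#'
#' @param z,V the gene's eQTLs' association z-scores and sampling
#'   variances.
#' @param pool_z,pool_V the full tested-variant pool (for the
#'   permutation null); defaults to the gene's own values (no
#'   permutation contrast — supply the pool in practice).
#' @param W prior effect variance (default 0.1 on the log-odds scale).
#' @param pi1 prior probability an eQTL is trait-associated (default
#'   0.1).
#' @param B number of permutations (default 999).
#' @param seed permutation seed.
#' @return one-row data.frame: `lbf`, `p_emp`, `n_eqtls`.
#' @export
gene_lbf <- function(z, V, pool_z = z, pool_V = V, W = 0.1, pi1 = 0.1,
                     B = 999L, seed = 1L) {
  if (length(z) == 0) stop("gene has no eQTLs in the association set")
  obs <- sum(lbf_terms(z, V, W, pi1))
  pool_terms <- lbf_terms(pool_z, pool_V, W, pi1)
  n <- length(z)
  b <- with_seed(substream_seed(seed, "gene_lbf"), {
    perm <- vapply(seq_len(B), function(i)
      sum(pool_terms[sample.int(length(pool_terms), n)]), numeric(1))
    sum(perm >= obs)
  })
  data.frame(lbf = obs, p_emp = (b + 1) / (B + 1), n_eqtls = n,
             row.names = NULL)
}

#' Score every gene's eQTL set against the association scan
#'
#' Deduplicates each gene's significant eQTLs by variant, joins them to
#' the association scan, and computes [gene_lbf()] per gene against the
#' scanned-variant pool. The minimum-FDR region's beta sign per variant
#' is carried as a direction annotation. Genes with no eQTL present in
#' the scan are skipped with a warning.
#'
#' @param eqtl_catalog significant catalog rows (`variant_id`, `gene`,
#'   `fdr`, `beta`).
#' @param assoc an [assoc_scan()] result (`variant_id`, `z`, `se`).
#' @param W,pi1,B,seed see [gene_lbf()].
#' @return data.frame of class `gene_lbf_result`: `gene`, `lbf`,
#'   `p_emp`, `n_eqtls`.
#' @export
gene_lbf_scan <- function(eqtl_catalog, assoc, W = 0.1, pi1 = 0.1,
                          B = 999L, seed = 1L) {
  stopifnot(all(c("variant_id", "gene") %in% names(eqtl_catalog)),
            all(c("variant_id", "z", "se") %in% names(assoc)))
  pool_z <- assoc$z
  pool_V <- assoc$se^2
  pool_terms <- lbf_terms(pool_z, pool_V, W, pi1)
  genes <- unique(eqtl_catalog$gene)
  skipped <- character(0)
  rows <- lapply(genes, function(g) {
    sub <- eqtl_catalog[eqtl_catalog$gene == g, , drop = FALSE]
    # deduplicate by variant, keeping the minimum-FDR region's row
    sub <- sub[order(sub$fdr %||% seq_len(nrow(sub))), , drop = FALSE]
    sub <- sub[!duplicated(sub$variant_id), , drop = FALSE]
    j <- match(sub$variant_id, assoc$variant_id)
    j <- j[!is.na(j)]
    if (!length(j)) { skipped <<- c(skipped, g); return(NULL) }
    n <- length(j)
    obs <- sum(pool_terms[j])
    b <- with_seed(substream_seed(seed, paste0("lbf_", g)), {
      perm <- vapply(seq_len(B), function(i)
        sum(pool_terms[sample.int(length(pool_terms), n)]), numeric(1))
      sum(perm >= obs)
    })
    data.frame(gene = g, lbf = obs, p_emp = (b + 1) / (B + 1),
               n_eqtls = n, stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning(length(skipped),
            " gene(s) had no eQTL in the association scan; skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_lbf_result", "data.frame")
  out
}

#' Final gene selection across two cohorts
#'
#' A gene is retained iff LBF > 0 and empirical p < `p_threshold` in
#' BOTH cohorts and it is annotated protein-coding. Genes missing from
#' the annotation are treated as non-coding (excluded, logged via
#' message).
#'
#' @param results_wgs,results_array [gene_lbf_scan()] outputs for the
#'   two cohorts.
#' @param gene_annotation data.frame `gene`, `protein_coding`.
#' @param lbf_threshold strict LBF floor (default 0).
#' @param p_threshold strict empirical-p ceiling (default 5e-3).
#' @return data.frame, one row per gene scored in both cohorts:
#'   per-cohort values, `sig_wgs`, `sig_array`, `replicated`,
#'   `protein_coding`, `selected`.
#' @export
select_genes <- function(results_wgs, results_array, gene_annotation,
                         lbf_threshold = 0, p_threshold = 5e-3) {
  m <- merge(results_wgs, results_array, by = "gene",
             suffixes = c("_wgs", "_array"))
  ann <- match(m$gene, gene_annotation$gene)
  unknown <- is.na(ann)
  if (any(unknown))
    message(sum(unknown), " gene(s) missing from annotation; ",
            "treated as non-coding")
  m$protein_coding <- ifelse(unknown, FALSE,
                             gene_annotation$protein_coding[ann])
  m$sig_wgs <- m$lbf_wgs > lbf_threshold & m$p_emp_wgs < p_threshold
  m$sig_array <- m$lbf_array > lbf_threshold &
    m$p_emp_array < p_threshold
  m$replicated <- m$sig_wgs & m$sig_array
  m$selected <- m$replicated & m$protein_coding
  m
}
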