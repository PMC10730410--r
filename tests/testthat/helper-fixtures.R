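# shared fixture builders; everything generated in code, seeded

small_config <- function(seed = 1L, ...) {
  sim_config(n_cases = 120, n_controls = 80, n_variants = 300,
             n_genes = 25, seed = seed, ...)
}

null_config <- function(seed = 1L, n_cases = 120, n_controls = 80,
                        n_variants = 300, n_genes = 25, ...) {
  sim_config(n_cases = n_cases, n_controls = n_controls,
             n_variants = n_variants, n_genes = n_genes, seed = seed,
             planted_risk = data.frame(or_ = numeric(0),
                                       gene = character(0),
                                       eqtl_beta = numeric(0),
                                       maf = numeric(0)),
             ...)
}

# brute-force per-base membership oracle for interval sets on a toy contig
per_base_membership <- function(gr, contig, length_bp) {
  covered <- logical(length_bp)
  sub <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  for (i in seq_along(sub)) {
    s <- max(GenomicRanges::start(sub)[i], 1)
    e <- min(GenomicRanges::end(sub)[i], length_bp)
    if (s <= e) covered[s:e] <- TRUE
  }
  covered
}

# grid-search logistic MLE oracle for a 1-predictor model (intercept +
# slope), independent of glm.fit
grid_logistic_beta <- function(dosage, status, lo = -3, hi = 3,
                               steps = 4) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * dosage
    sum(status * eta - log1p(exp(eta)))
  }
  b0r <- c(-3, 3); b1r <- c(lo, hi)
  for (s in seq_len(steps)) {
    b0g <- seq(b0r[1], b0r[2], length.out = 41)
    b1g <- seq(b1r[1], b1r[2], length.out = 41)
    ll <- outer(b0g, b1g, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    st0 <- diff(b0r) / 40; st1 <- diff(b1r) / 40
    b0r <- b0g[best[1]] + c(-st0, st0)
    b1r <- b1g[best[2]] + c(-st1, st1)
  }
  mean(b1r)
}
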