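# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with planted, parameterized structure so each downstream stage
# has a recoverable ground truth: risk eQTLs with a chosen odds ratio and
# minor-allele frequency, an eQTL catalog over 13 brain regions, peak/loop
# geometry with controllable overlap fractions, case/control expression
# shifts, and diagnostic-category prevalences. A single run seed drives
# everything; each generator draws from a deterministic sub-stream so
# modules can be regenerated independently.

#' The 13 brain-region labels used by the eQTL catalog
#' @export
BRAIN_REGIONS <- c(
  "Amygdala", "Anterior_cingulate_cortex", "Caudate",
  "Cerebellar_hemisphere", "Cerebellum", "Cortex", "Frontal_cortex",
  "Hippocampus", "Hypothalamus", "Nucleus_accumbens", "Putamen",
  "Spinal_cord", "Substantia_nigra")

#' The curated EHR diagnostic categories and their default prevalences
#'
#' Default carrier-independent prevalences for the simulated diagnosis
#' table (fractions of suicide-death samples with each diagnosis; e.g.
#' pain 0.695, anxiety 0.526, bipolar disorder 0.423).
#' @export
DX_PREVALENCE_DEFAULT <- c(
  alcohol_related = 0.287, asthma = 0.164, anxiety = 0.526,
  bipolar_disorder = 0.423, broad_depression = 0.633,
  neurodegenerative = 0.136, drug_related = 0.394,
  eating_related = 0.022, mdd = 0.391, obesity = 0.205,
  opioid_misuse = 0.182, pain = 0.695, schizophrenia = 0.063,
  sleep_related = 0.294, suicidal_ideation = 0.298)

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort: sample sizes, variant and
#' gene counts, population allele-frequency profiles, planted risk eQTLs
#' (variant, odds ratio, target gene, eQTL beta, MAF), regulatory-overlap
#' fractions, differential-expression shifts, and diagnostic prevalences.
#' Defaults mirror the study conditions: 986 cases vs 415 controls, a
#' planted risk allele with OR 1.67 at MAF 0.3, and Table-1-style
#' diagnostic prevalences.
#'
#' @param n_cases,n_controls sample counts (> 0).
#' @param n_variants,n_genes variant and gene counts (> 0).
#' @param populations data.frame with `label`, `frac` (sample fraction)
#'   and `fst` (Balding-Nichols divergence from the shared ancestral
#'   frequency; 0 = none).
#' @param planted_risk data.frame of planted effects: `or_` (> 0, odds
#'   ratio per alt allele), `gene`, `eqtl_beta`, `maf`. Variants are
#'   assigned deterministically at evenly spaced positions. `NULL` plants
#'   one OR 1.67 / MAF 0.3 eQTL on gene G0001; use a 0-row data.frame for
#'   a global-null cohort.
#' @param maf_range ancestral allele-frequency range for non-planted
#'   variants, inside [0, 0.5].
#' @param peak_overlap_frac,loop_overlap_frac probability that a
#'   significant eQTL position is covered by an accessibility peak /
#'   a loop anchor.
#' @param de_effects data.frame of expression shifts: `gene`, `shift`
#'   (in SD units, added to cases), optional `sex` ("M"/"F", NA = both).
#' @param dx_prevalence named probabilities per diagnostic category.
#' @param seed integer run seed; fixed seed gives byte-identical outputs.
#' @param n_regions number of brain regions in the eQTL catalog.
#' @param eqtls_per_gene catalog variant-gene pairs per gene.
#' @param frac_true_eqtl fraction of non-planted catalog pairs that are
#'   genuine eQTLs (large expression effect, trait-null).
#' @param eqtl_se catalog standard error per (variant, gene, region) row.
#' @param dp_mean mean sequencing depth; `dp_low_frac` of calls fall
#'   below DP 20 and `gq_low_frac` at or below GQ 30.
#' @param dp_low_frac,gq_low_frac per-call low-quality fractions.
#' @param genome named vector of contig lengths (bp).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 986, n_controls = 415,
                       n_variants = 2000, n_genes = 100,
                       populations = data.frame(label = "EUR", frac = 1,
                                                fst = 0),
                       planted_risk = NULL,
                       maf_range = c(0.05, 0.5),
                       peak_overlap_frac = 0.7, loop_overlap_frac = 0.8,
                       de_effects = data.frame(gene = character(0),
                                               shift = numeric(0),
                                               sex = character(0)),
                       dx_prevalence = DX_PREVALENCE_DEFAULT,
                       seed = 1L,
                       n_regions = 13L, eqtls_per_gene = 4L,
                       frac_true_eqtl = 0.3, eqtl_se = 0.08,
                       dp_mean = 35, dp_low_frac = 0.02,
                       gq_low_frac = 0.02,
                       genome = c(chr1 = 6e7, chr2 = 6e7)) {
  if (is.null(planted_risk))
    planted_risk <- data.frame(or_ = 1.67, gene = "G0001",
                               eqtl_beta = -0.5, maf = 0.3,
                               stringsAsFactors = FALSE)
  stopifnot(n_cases > 0, n_controls > 0, n_variants > 0, n_genes > 0,
            n_regions >= 1, eqtls_per_gene >= 1)
  if (any(planted_risk$or_ <= 0)) stop("planted odds ratios must be > 0")
  for (p in c(peak_overlap_frac, loop_overlap_frac, frac_true_eqtl,
              dp_low_frac, gq_low_frac, dx_prevalence))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (maf_range[1] < 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2])
    stop("maf_range must be an interval inside [0, 0.5]")
  if (abs(sum(populations$frac) - 1) > 1e-8)
    stop("population fractions must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d cases / %d controls, %d variants, %d genes, seed %d\n",
              x$n_cases, x$n_controls, x$n_variants, x$n_genes, x$seed))
  cat(sprintf("  planted risk eQTLs: %d; peak/loop overlap %.2f/%.2f\n",
              nrow(x$planted_risk), x$peak_overlap_frac,
              x$loop_overlap_frac))
  invisible(x)
}

# Deterministic variant table shared by all generators: positions uniform
# over the configured contigs, ancestral AF uniform over maf_range, and
# the planted variants pinned at evenly spaced indices with their
# configured MAF.
sim_variant_table <- function(config) {
  with_seed(substream_seed(config$seed, "variants"), {
    m <- config$n_variants
    lens <- config$genome
    n_per <- pmax(1L, round(m * lens / sum(lens)))
    n_per[length(n_per)] <- m - sum(n_per[-length(n_per)])
    contig <- rep(names(lens), n_per)
    pos <- unlist(lapply(seq_along(lens), function(i)
      sort(sample.int(lens[i], n_per[i]))), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    af <- runif(m, config$maf_range[1], config$maf_range[2])
    v <- data.frame(variant_id = sprintf("v%06d", seq_len(m)),
                    contig = contig, pos = as.integer(pos),
                    ref = ref, alt = unname(alt),
                    biallelic = TRUE, af = af,
                    stringsAsFactors = FALSE)
    k <- nrow(config$planted_risk)
    if (k > 0) {
      idx <- unique(round(seq(1, m, length.out = k + 2)))[2:(k + 1)]
      v$af[idx] <- config$planted_risk$maf
      pl <- config$planted_risk
      pl$variant_id <- v$variant_id[idx]
      attr(v, "planted") <- pl
    } else attr(v, "planted") <- cbind(config$planted_risk,
                                       variant_id = character(0))
    v
  })
}

# Genotype distribution in cases under the retrospective logistic model:
# P(g | case) over g in {0,1,2} with HWE priors at allele frequency af.
case_genotype_dist <- function(af, log_or, b0) {
  g <- 0:2
  pg <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  pc <- plogis(b0 + log_or * (g - 2 * af))
  w <- pg * pc
  w / sum(w)
}

#' Simulate a case/control genotype cohort
#'
#' Genotypes are drawn as two binomial allele draws at each variant's
#' population allele frequency. Case status follows a logistic model
#' whose intercept is calibrated to the case fraction and whose slopes
#' are the planted log odds ratios (centered dosage); exact case/control
#' quotas are filled by retrospective sampling from a population pool,
#' which leaves the planted odds ratios recoverable without bias by the
#' downstream logistic fit. Per-call DP and GQ are drawn with the
#' configured low-quality fractions; sex and 10 ancestry-covariate
#' columns are emitted.
#'
#' @param config a [sim_config()].
#' @return A [genotype_dataset()] with a `planted` truth table.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  variants <- sim_variant_table(config)
  planted <- attr(variants, "planted")
  with_seed(substream_seed(config$seed, "cohort"), {
    n <- config$n_cases + config$n_controls
    case_frac <- config$n_cases / n
    b0 <- qlogis(case_frac)
    k <- nrow(planted)
    pidx <- match(planted$variant_id, variants$variant_id)
    log_or <- log(planted$or_)

    # retrospective sampling: draw pool members at the planted variants
    # only, assign status, keep quotas; null variants are filled in later
    # (they are independent of status).
    g_case <- matrix(0L, 0, k); g_ctrl <- matrix(0L, 0, k)
    rounds <- 0L
    while ((nrow(g_case) < config$n_cases ||
            nrow(g_ctrl) < config$n_controls) && rounds < 200L) {
      rounds <- rounds + 1L
      chunk <- max(2L * n, 1000L)
      g <- if (k > 0)
        vapply(seq_len(k), function(j)
          rbinom(chunk, 2L, planted$maf[j]), integer(chunk))
      else matrix(0L, chunk, 0)
      eta <- b0 + if (k > 0)
        as.numeric(g %*% log_or) - sum(2 * planted$maf * log_or)
      else 0
      y <- rbinom(chunk, 1L, plogis(eta))
      g_case <- rbind(g_case, g[y == 1L, , drop = FALSE])
      g_ctrl <- rbind(g_ctrl, g[y == 0L, , drop = FALSE])
    }
    if (nrow(g_case) < config$n_cases || nrow(g_ctrl) < config$n_controls)
      stop("could not fill case/control quotas; check planted effects")
    g_planted <- rbind(g_case[seq_len(config$n_cases), , drop = FALSE],
                       g_ctrl[seq_len(config$n_controls), , drop = FALSE])
    status <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))

    # population assignment and per-population allele frequencies
    # (Balding-Nichols divergence when fst > 0)
    pops <- config$populations
    pop <- sample(pops$label, n, replace = TRUE, prob = pops$frac)
    dosage <- matrix(0L, n, config$n_variants)
    for (pi in seq_len(nrow(pops))) {
      rows <- which(pop == pops$label[pi])
      if (!length(rows)) next
      f <- pops$fst[pi]
      af_pop <- if (f > 0)
        rbeta(config$n_variants, variants$af * (1 - f) / f,
              (1 - variants$af) * (1 - f) / f)
      else variants$af
      dosage[rows, ] <- matrix(
        rbinom(length(rows) * config$n_variants, 2L,
               rep(af_pop, each = length(rows))),
        nrow = length(rows))
    }
    if (k > 0) dosage[, pidx] <- g_planted

    sex <- sample(c("M", "F"), n, replace = TRUE)
    age <- round(ifelse(status == 1L, rnorm(n, 32.1, 13.4),
                        rnorm(n, 45, 16)))
    age <- pmax(age, 18)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                          status = status, sex = sex, age = age,
                          population = pop, stringsAsFactors = FALSE)
    samples <- cbind(samples, pcs)

    nm <- n * config$n_variants
    low_dp <- runif(nm) < config$dp_low_frac
    dp <- integer(nm)
    dp[low_dp] <- sample(5:19, sum(low_dp), replace = TRUE)
    dp[!low_dp] <- 20L + rpois(sum(!low_dp), max(config$dp_mean - 20, 1))
    low_gq <- runif(nm) < config$gq_low_frac
    gq <- integer(nm)
    gq[low_gq] <- sample(0:30, sum(low_gq), replace = TRUE)
    gq[!low_gq] <- sample(31:99, sum(!low_gq), replace = TRUE)
    dim(dp) <- dim(gq) <- c(n, config$n_variants)

    v_out <- variants[, c("variant_id", "contig", "pos", "ref", "alt",
                          "biallelic", "af")]
    genotype_dataset(samples, v_out, dosage, dp = dp, gq = gq,
                     planted = planted)
  })
}

#' Simulate a brain-region eQTL catalog
#'
#' Emits one row per (variant, gene, region): effect estimate, standard
#' error, and within-region BH-adjusted FDR. Planted risk eQTLs and a
#' configurable fraction of genuine trait-null eQTLs carry large true
#' effects (active in at least one region each), so their FDR falls below
#' 0.05 by construction; the remaining rows are draws from the null, so
#' their adjusted FDRs behave like a null BH ensemble.
#'
#' @param config a [sim_config()].
#' @param variants optional variant table (regenerated from `config` when
#'   `NULL`; regeneration is deterministic).
#' @return A data.frame of class `eqtl_catalog` with columns
#'   `variant_id`, `gene`, `region`, `beta`, `se`, `p`, `fdr`, `true_eqtl`.
#' @export
simulate_eqtl_catalog <- function(config, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_regions < 1) stop("need at least one brain region")
  if (is.null(variants)) variants <- sim_variant_table(config)
  planted <- attr(variants, "planted") %||% config$planted_risk
  with_seed(substream_seed(config$seed, "eqtl"), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    regions <- BRAIN_REGIONS[seq_len(min(config$n_regions,
                                         length(BRAIN_REGIONS)))]
    if (config$n_regions > length(BRAIN_REGIONS))
      regions <- c(regions, sprintf("Region_%02d",
                                    seq_len(config$n_regions -
                                            length(BRAIN_REGIONS))))
    # variant-gene pairs: eqtls_per_gene random variants per gene, with
    # planted (variant, gene) pairs pinned into their target genes
    pair_gene <- rep(genes, each = config$eqtls_per_gene)
    pair_var <- unlist(lapply(genes, function(g)
      sample(variants$variant_id, config$eqtls_per_gene)),
      use.names = FALSE)
    if (nrow(planted) > 0)
      for (i in seq_len(nrow(planted))) {
        slot <- which(pair_gene == planted$gene[i])[1]
        if (is.na(slot)) stop("planted gene ", planted$gene[i],
                              " not among simulated genes")
        pair_var[slot] <- planted$variant_id[i]
      }
    n_pairs <- length(pair_gene)
    beta_true <- numeric(n_pairs)
    is_true <- runif(n_pairs) < config$frac_true_eqtl
    beta_true[is_true] <- sample(c(-1, 1), sum(is_true), TRUE) *
      runif(sum(is_true), 0.5, 1.0)
    if (nrow(planted) > 0) {
      pp <- match(paste(planted$variant_id, planted$gene),
                  paste(pair_var, pair_gene))
      beta_true[pp] <- planted$eqtl_beta
      is_true[pp] <- TRUE
    }
    # region activity: each true pair is active in a random non-empty
    # subset of regions; estimates are truth + noise where active, pure
    # noise elsewhere
    R <- length(regions)
    active <- matrix(runif(n_pairs * R) < 0.5, n_pairs, R)
    none <- which(is_true & rowSums(active) == 0)
    if (length(none))
      active[cbind(none, sample.int(R, length(none), TRUE))] <- TRUE
    active[!is_true, ] <- FALSE
    se <- config$eqtl_se
    cat_df <- do.call(rbind, lapply(seq_len(R), function(r) {
      b <- ifelse(active[, r], beta_true, 0) + rnorm(n_pairs, 0, se)
      p <- 2 * pnorm(-abs(b / se))
      data.frame(variant_id = pair_var, gene = pair_gene,
                 region = regions[r], beta = b, se = se, p = p,
                 fdr = p.adjust(p, "BH"), true_eqtl = is_true,
                 stringsAsFactors = FALSE)
    }))
    rownames(cat_df) <- NULL
    class(cat_df) <- c("eqtl_catalog", "data.frame")
    cat_df
  })
}

#' Simulate regulatory tracks (accessibility peaks and Hi-C loops)
#'
#' Each significant eQTL position is covered by an accessibility peak
#' with probability `peak_overlap_frac` and by a loop anchor with
#' probability `loop_overlap_frac` (independent draws), so the expected
#' fraction surviving the peak-AND-loop regulatory selection is their
#' product. Background peaks and loops are placed away from the
#' candidate positions so the overlap fractions are exact.
#'
#' @param config a [sim_config()].
#' @param variants optional variant table (regenerated when `NULL`).
#' @param candidate_ids variant ids of the significant eQTLs to cover;
#'   when `NULL`, derived by regenerating the catalog and keeping
#'   FDR < 0.05 rows.
#' @param n_background background peaks per assay (and loops).
#' @return list with `peaks` (named list of `GRanges`, one per assay)
#'   and `loops` (a [loop_set()]).
#' @export
simulate_regulatory_tracks <- function(config, variants = NULL,
                                       candidate_ids = NULL,
                                       n_background = 200L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$peak_overlap_frac < 0 || config$peak_overlap_frac > 1 ||
      config$loop_overlap_frac < 0 || config$loop_overlap_frac > 1)
    stop("overlap fractions must lie in [0, 1]")
  if (is.null(variants)) variants <- sim_variant_table(config)
  if (is.null(candidate_ids)) {
    cat_df <- simulate_eqtl_catalog(config, variants)
    candidate_ids <- unique(cat_df$variant_id[cat_df$fdr < 0.05])
  }
  with_seed(substream_seed(config$seed, "tracks"), {
    assays <- c("H3K27ac", "H3K4me3", "H3K4me1", "ATAC", "DNase")
    cand <- variants[match(candidate_ids, variants$variant_id), ]
    covered_peak <- runif(nrow(cand)) < config$peak_overlap_frac
    covered_loop <- runif(nrow(cand)) < config$loop_overlap_frac

    mk_gr <- function(contig, start, end)
      GenomicRanges::GRanges(contig, IRanges::IRanges(pmax(start, 1), end))

    # peaks over covered candidates, assigned to a random assay each
    peak_list <- setNames(vector("list", length(assays)), assays)
    if (any(covered_peak)) {
      cc <- cand[covered_peak, ]
      half <- sample(100:500, nrow(cc), replace = TRUE)
      assay_of <- sample(assays, nrow(cc), replace = TRUE)
      for (a in assays) {
        sel <- assay_of == a
        peak_list[[a]] <- if (any(sel))
          mk_gr(cc$contig[sel], cc$pos[sel] - half[sel],
                cc$pos[sel] + half[sel])
        else GenomicRanges::GRanges()
      }
    } else peak_list[] <- list(GenomicRanges::GRanges())

    # background peaks, kept clear of every candidate position
    cand_gr <- mk_gr(cand$contig, cand$pos, cand$pos)
    bg_intervals <- function(n, max_half) {
      contig <- sample(names(config$genome), n, replace = TRUE,
                       prob = config$genome / sum(config$genome))
      center <- floor(runif(n, 1, config$genome[contig]))
      half <- sample(100:max_half, n, replace = TRUE)
      gr <- mk_gr(contig, center - half, pmin(center + half,
                                              config$genome[contig]))
      gr[!IRanges::overlapsAny(gr, cand_gr)]
    }
    for (a in assays)
      peak_list[[a]] <- sort(c(peak_list[[a]], bg_intervals(n_background, 500)))

    # loops: anchor1 over covered candidates, anchor2 distal; background
    # loops away from candidates
    if (any(covered_loop)) {
      cl <- cand[covered_loop, ]
      half1 <- sample(500:2500, nrow(cl), replace = TRUE)
      shift <- sample(50000:200000, nrow(cl), replace = TRUE)
      w2 <- sample(2000:10000, nrow(cl), replace = TRUE)
      a1 <- mk_gr(cl$contig, cl$pos - half1, cl$pos + half1)
      a2 <- mk_gr(cl$contig, cl$pos + shift, cl$pos + shift + w2)
    } else {
      a1 <- a2 <- GenomicRanges::GRanges()
    }
    bg1 <- bg_intervals(n_background, 2500)
    bg2 <- GenomicRanges::shift(bg1, 100000)
    keep <- !IRanges::overlapsAny(bg2, cand_gr)
    a1 <- c(a1, bg1[keep]); a2 <- c(a2, bg2[keep])
    list(peaks = peak_list,
         loops = loop_set(a1, a2, rep("brain", length(a1))))
  })
}

#' Simulate an expression matrix tied to the cohort
#'
#' Expression per gene = baseline + eQTL beta x dosage (for planted
#' eQTL-driven genes) + case-group shift (optionally sex-restricted)
#' + small sex/age/study covariate effects + unit Gaussian noise.
#' Sample metadata carries group, sex, age and study labels.
#'
#' @param config a [sim_config()].
#' @param genotypes the [simulate_cohort()] output supplying dosages and
#'   sample metadata.
#' @return An object of class `expression_matrix`: list with `expr`
#'   (genes x samples matrix) and `metadata` (sample table).
#' @export
simulate_expression <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_dataset"))
  planted <- genotypes$planted %||% data.frame()
  if (nrow(planted) > 0 &&
      !all(planted$variant_id %in% genotypes$variants$variant_id))
    stop("planted eQTL variant missing from genotypes")
  with_seed(substream_seed(config$seed, "expression"), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    n <- nrow(genotypes$samples)
    meta <- data.frame(sample_id = genotypes$samples$sample_id,
                       group = ifelse(genotypes$samples$status == 1L,
                                      "case", "control"),
                       sex = genotypes$samples$sex,
                       age = genotypes$samples$age,
                       study = sample(c("study1", "study2"), n, TRUE),
                       stringsAsFactors = FALSE)
    baseline <- rnorm(config$n_genes, 0, 1)
    expr <- matrix(rnorm(config$n_genes * n, 0, 1), config$n_genes, n,
                   dimnames = list(genes, meta$sample_id))
    expr <- expr + baseline +
      outer(rep(1, config$n_genes), 0.005 * (meta$age - mean(meta$age))) +
      outer(rnorm(config$n_genes, 0, 0.1), as.numeric(meta$sex == "F")) +
      outer(rnorm(config$n_genes, 0, 0.3),
            as.numeric(meta$study == "study2"))
    if (nrow(planted) > 0)
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]
        if (!g %in% genes) next
        expr[g, ] <- expr[g, ] + planted$eqtl_beta[i] *
          genotypes$dosage[, planted$variant_id[i]]
      }
    de <- config$de_effects
    if (nrow(de) > 0)
      for (i in seq_len(nrow(de))) {
        sel <- meta$group == "case"
        if (!is.null(de$sex) && !is.na(de$sex[i]))
          sel <- sel & meta$sex == de$sex[i]
        expr[de$gene[i], sel] <- expr[de$gene[i], sel] + de$shift[i]
      }
    structure(list(expr = expr, metadata = meta),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$expr), ncol(x$expr),
              paste(names(table(x$metadata$group)), collapse = "/")))
  invisible(x)
}

#' Simulate an EHR diagnosis table
#'
#' One row per sample with 0/1 flags for each configured diagnostic
#' category, drawn Bernoulli at the configured prevalence; carriers of a
#' chosen allele can receive shifted odds per category.
#'
#' @param config a [sim_config()].
#' @param samples sample table with `sample_id`, `sex`, `age`.
#' @param carrier optional logical vector (per sample): carries the risk
#'   allele.
#' @param carrier_effects optional data.frame `category`, `or_`: odds
#'   shift applied to carriers.
#' @return data.frame: `sample_id`, `sex`, `age`, one 0/1 column per
#'   category.
#' @export
simulate_ehr <- function(config, samples, carrier = NULL,
                         carrier_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  prev <- config$dx_prevalence
  if (any(prev < 0 | prev > 1)) stop("prevalence outside [0, 1]")
  n <- nrow(samples)
  if (!is.null(carrier)) stopifnot(length(carrier) == n)
  with_seed(substream_seed(config$seed, "ehr"), {
    out <- samples[, intersect(c("sample_id", "sex", "age"),
                               names(samples)), drop = FALSE]
    for (k in names(prev)) {
      if (prev[[k]] %in% c(0, 1)) {
        out[[k]] <- rep(as.integer(prev[[k]]), n)
        next
      }
      eta <- rep(qlogis(prev[[k]]), n)
      if (!is.null(carrier) && !is.null(carrier_effects)) {
        row <- carrier_effects[carrier_effects$category == k, ]
        if (nrow(row) == 1) eta <- eta + log(row$or_) * carrier
      }
      out[[k]] <- rbinom(n, 1L, plogis(eta))
    }
    out
  })
}

#' Simulate replication-cohort allele frequencies
#'
#' Builds aggregate allele-count tables for an independent case cohort
#' (array-style) and a large aggregate control panel. Planted risk
#' variants get their case frequency from the retrospective logistic
#' model (exact enumeration over genotypes), so the planted direction is
#' recoverable; all other variants share the population frequency.
#'
#' @param config a [sim_config()].
#' @param variants variant table with `variant_id` and `af` (population
#'   allele frequency); typically `genotypes$variants`.
#' @param planted planted-truth table (`variant_id`, `or_`); typically
#'   `genotypes$planted`.
#' @param n_array_cases diploid sample count of the replication case
#'   cohort.
#' @param aggregate_an total allele number of the aggregate control
#'   panel.
#' @return list of two data.frames (`array_cases`, `aggregate_controls`)
#'   with `variant_id`, `ac`, `an`, `af`.
#' @export
simulate_af_cohorts <- function(config, variants, planted = NULL,
                                n_array_cases = 4657,
                                aggregate_an = 152312) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "af_repl"), {
    b0 <- qlogis(config$n_cases / (config$n_cases + config$n_controls))
    af_case <- variants$af
    if (!is.null(planted) && nrow(planted) > 0) {
      idx <- match(planted$variant_id, variants$variant_id)
      for (i in seq_along(idx)) {
        d <- case_genotype_dist(planted$maf[i], log(planted$or_[i]), b0)
        af_case[idx[i]] <- sum((0:2) * d) / 2
      }
    }
    an_arr <- 2L * n_array_cases
    ac_arr <- rbinom(nrow(variants), an_arr, af_case)
    ac_agg <- rbinom(nrow(variants), aggregate_an, variants$af)
    list(array_cases = data.frame(variant_id = variants$variant_id,
                                  ac = ac_arr, an = an_arr,
                                  af = ac_arr / an_arr,
                                  stringsAsFactors = FALSE),
         aggregate_controls = data.frame(
           variant_id = variants$variant_id, ac = ac_agg,
           an = aggregate_an, af = ac_agg / aggregate_an,
           stringsAsFactors = FALSE))
  })
}

#' Simulate a gene annotation table
#'
#' HUGO-style annotation: gene id, symbol, protein-coding flag.
#' @param config a [sim_config()].
#' @param coding_frac fraction of genes flagged protein-coding.
#' @return data.frame `gene`, `symbol`, `protein_coding`.
#' @export
simulate_gene_annotation <- function(config, coding_frac = 0.85) {
  with_seed(substream_seed(config$seed, "annotation"), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    data.frame(gene = genes, symbol = paste0("SYM", seq_along(genes)),
               protein_coding = runif(length(genes)) < coding_frac,
               stringsAsFactors = FALSE)
  })
}
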