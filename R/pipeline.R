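# End-to-end driver over synthetic inputs: catalog -> regulatory test
# set -> QC'd association -> clumping/FDR -> allele-frequency
# replication -> gene-level LBF integration, with a survival funnel
# reported at every stage. Deterministic given the configuration seed.

#' Allele-frequency association summaries for a variant set
#'
#' Per variant, the log allelic OR between two frequency cohorts with
#' its Woolf standard error (Haldane-corrected on zero cells), as a
#' z/SE summary-statistic table usable by [gene_lbf_scan()].
#'
#' @param cases,controls frequency tables: `variant_id`, `ac`, `an`.
#' @param variant_ids variants to summarize (default: intersection).
#' @return data.frame: `variant_id`, `beta` (log OR), `se`, `z`.
#' @export
af_contrast_scan <- function(cases, controls, variant_ids = NULL) {
  if (is.null(variant_ids))
    variant_ids <- intersect(cases$variant_id, controls$variant_id)
  i <- match(variant_ids, cases$variant_id)
  j <- match(variant_ids, controls$variant_id)
  a <- cases$ac[i]; b <- cases$an[i] - cases$ac[i]
  c_ <- controls$ac[j]; d <- controls$an[j] - controls$ac[j]
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  c_[zero] <- c_[zero] + 0.5; d[zero] <- d[zero] + 0.5
  beta <- log((a * d) / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  data.frame(variant_id = variant_ids, beta = beta, se = se,
             z = beta / se, stringsAsFactors = FALSE)
}

#' Run the full regulatory-eQTL association pipeline on synthetic data
#'
#' Simulates the cohort and every companion resource from `config`,
#' then executes the analysis stages in order: significant-eQTL
#' filtering, regulatory-region restriction, call-quality masking and
#' variant QC, covariate-adjusted logistic association, genomic
#' inflation, LD clumping with FDR index selection, allele-frequency
#' replication of significant indices, gene-level LBF integration in
#' both cohorts, and final gene selection. The funnel vector reports
#' survival counts at each stage.
#'
#' @param config a [sim_config()].
#' @param B_lbf permutations per gene for the LBF empirical p.
#' @param lbf_p_threshold gene-selection empirical-p ceiling (default
#'   5e-3; at small `B_lbf` no permutation p can clear it, so scale
#'   `B_lbf` with the intended threshold).
#' @param covariate_cols sample-table covariates for the association
#'   model.
#' @return list of class `regeqtl_run`: per-stage results and `funnel`.
#' @export
run_pipeline <- function(config, B_lbf = 999L, lbf_p_threshold = 5e-3,
                         covariate_cols = c("sex", paste0("PC", 1:10))) {
  stopifnot(inherits(config, "sim_config"))
  gd <- simulate_cohort(config)
  catalog <- simulate_eqtl_catalog(config)
  sig <- filter_significant_eqtls(catalog)
  tracks <- simulate_regulatory_tracks(config,
                                       candidate_ids = sig$candidates)
  accessibility <- GenomicRanges::reduce(
    do.call(c, unname(tracks$peaks)))
  regions <- build_regulatory_regions(tracks$peaks, tracks$loops)
  cand_df <- gd$variants[match(sig$candidates,
                               gd$variants$variant_id), ]
  sel <- select_regulatory_eqtls(cand_df, regions,
                                 accessibility = accessibility,
                                 n_significant_rows = nrow(sig$catalog))
  masked <- apply_call_mask(gd)
  qc <- variant_qc(masked, sel$test_set$variant_id)
  pass_ids <- qc$variant_id[qc$pass]
  assoc <- assoc_scan(masked, pass_ids,
                      covariate_cols = covariate_cols)
  inflation <- genomic_inflation(assoc$p)
  clumped <- ld_clump(assoc, masked)
  sig_idx <- clumped[clumped$significant, , drop = FALSE]

  af <- simulate_af_cohorts(config, gd$variants, gd$planted)
  confirm <- if (nrow(sig_idx) > 0)
    cross_cohort_confirm(
      data.frame(variant_id = sig_idx$variant_id,
                 direction = sign(sig_idx$beta)),
      af$array_cases, af$aggregate_controls)
  else data.frame()

  tested_catalog <- sig$catalog[sig$catalog$variant_id %in%
                                assoc$variant_id, , drop = FALSE]
  array_assoc <- af_contrast_scan(af$array_cases,
                                  af$aggregate_controls,
                                  assoc$variant_id)
  lbf_wgs <- gene_lbf_scan(tested_catalog, assoc, B = B_lbf,
                           seed = config$seed)
  lbf_array <- gene_lbf_scan(tested_catalog, array_assoc, B = B_lbf,
                             seed = config$seed + 1L)
  annotation <- simulate_gene_annotation(config)
  genes <- select_genes(lbf_wgs, lbf_array, annotation,
                        p_threshold = lbf_p_threshold)

  funnel <- c(sel$funnel,
              post_qc = length(pass_ids),
              index_eqtls = sum(clumped$is_index),
              significant_indices = nrow(sig_idx),
              replicated_loci = if (nrow(confirm)) sum(confirm$retained)
                                else 0L,
              selected_genes = sum(genes$selected))
  structure(list(config = config, genotypes = gd, catalog = catalog,
                 significant = sig, tracks = tracks, regions = regions,
                 qc = qc, assoc = assoc, inflation = inflation,
                 clumped = clumped, replication = confirm,
                 lbf_wgs = lbf_wgs, lbf_array = lbf_array,
                 genes = genes, funnel = funnel),
            class = "regeqtl_run")
}

#' @export
print.regeqtl_run <- function(x, ...) {
  cat("regulatory-eQTL pipeline run\n")
  f <- x$funnel
  for (nm in names(f)) cat(sprintf("  %-28s %s\n", nm, f[[nm]]))
  cat(sprintf("  lambda_gc                    %.4f\n",
              x$inflation$lambda_gc))
  invisible(x)
}

#' Write a funnel report as JSON
#' @param funnel named integer vector (from `run_pipeline()$funnel`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel_json <- function(funnel, path) {
  jsonlite::write_json(as.list(funnel), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
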