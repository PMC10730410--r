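# Replication of WGS-significant index eQTLs in an independent case
# cohort and against aggregate control allele frequencies (allele-count
# tables only, gnomAD-style). The replication statistic is a two-sided
# Fisher exact test on the reconstructed 2x2 allele table with a
# direction-consistency requirement.

#' Allele-frequency contrast between two cohorts
#'
#' Reconstructs the 2x2 allele-count table (alt / ref alleles per
#' cohort), computes the allelic odds ratio with a Woolf (log-scale
#' normal) 95% CI, and a two-sided Fisher exact p. Zero cells get the
#' Haldane-Anscombe 0.5 correction for the OR/CI; the exact p is
#' computed on the uncorrected table.
#'
#' @param ac1,an1 alt-allele count and total allele number, cohort 1
#'   (e.g. cases).
#' @param ac2,an2 same for cohort 2 (e.g. controls).
#' @return one-row data.frame: `or_`, `ci_lo`, `ci_hi`, `p`,
#'   `direction` (sign of log OR).
#' @export
af_contrast <- function(ac1, an1, ac2, an2) {
  if (an1 <= 0 || an2 <= 0) stop("allele number must be positive")
  if (ac1 < 0 || ac1 > an1 || ac2 < 0 || ac2 > an2)
    stop("allele counts must lie in [0, AN]")
  tab <- matrix(c(ac1, an1 - ac1, ac2, an2 - ac2), 2, byrow = TRUE)
  ctab <- tab
  if (any(tab == 0)) ctab <- tab + 0.5
  or_ <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  se_log <- sqrt(sum(1 / ctab))
  p <- fisher.test(round(tab))$p.value
  data.frame(or_ = or_, ci_lo = exp(log(or_) - 1.96 * se_log),
             ci_hi = exp(log(or_) + 1.96 * se_log), p = p,
             direction = sign(log(or_)), row.names = NULL)
}

#' Cross-cohort confirmation of WGS index eQTLs
#'
#' Retains a WGS-significant locus iff (a) the independent case cohort
#' versus its control source (array controls when supplied, otherwise
#' the aggregate panel) is nominally significant, (b) that contrast's
#' direction matches the WGS direction, and (c) the aggregate-control
#' contrast also matches direction. Loci missing from a replication
#' source are recorded untestable and not retained.
#'
#' @param wgs_indices data.frame with `variant_id` and `direction`
#'   (sign of the WGS log OR; an [assoc_scan()] + [ld_clump()] result
#'   restricted to significant indices works directly when a
#'   `direction` column is added as `sign(beta)`).
#' @param array_cases frequency table for the independent case cohort:
#'   `variant_id`, `ac`, `an`.
#' @param aggregate_controls aggregate control frequency table, same
#'   columns.
#' @param array_controls optional frequency table of matched array
#'   controls; when absent the aggregate panel is the control side of
#'   contrast (a).
#' @param p_threshold nominal replication threshold (default 0.05); no
#'   multiplicity correction at this confirmatory stage.
#' @return data.frame, one row per locus: contrast statistics, rule
#'   flags, `retained`, `reason`.
#' @export
cross_cohort_confirm <- function(wgs_indices, array_cases,
                                 aggregate_controls,
                                 array_controls = NULL,
                                 p_threshold = 0.05) {
  stopifnot(all(c("variant_id", "direction") %in% names(wgs_indices)))
  ctrl1 <- array_controls %||% aggregate_controls
  rows <- lapply(seq_len(nrow(wgs_indices)), function(i) {
    vid <- wgs_indices$variant_id[i]
    dir_wgs <- wgs_indices$direction[i]
    a <- array_cases[array_cases$variant_id == vid, ]
    c1 <- ctrl1[ctrl1$variant_id == vid, ]
    agg <- aggregate_controls[aggregate_controls$variant_id == vid, ]
    base <- data.frame(variant_id = vid, direction_wgs = dir_wgs,
                       p_array = NA_real_, or_array = NA_real_,
                       direction_array = NA_real_,
                       direction_aggregate = NA_real_,
                       retained = FALSE, reason = "untestable",
                       stringsAsFactors = FALSE)
    if (nrow(a) != 1 || nrow(c1) != 1 || nrow(agg) != 1) return(base)
    con1 <- af_contrast(a$ac, a$an, c1$ac, c1$an)
    con2 <- af_contrast(a$ac, a$an, agg$ac, agg$an)
    base$p_array <- con1$p
    base$or_array <- con1$or_
    base$direction_array <- con1$direction
    base$direction_aggregate <- con2$direction
    ok_p <- con1$p < p_threshold
    ok_dir1 <- con1$direction == dir_wgs
    ok_dir2 <- con2$direction == dir_wgs
    base$retained <- ok_p && ok_dir1 && ok_dir2
    base$reason <- if (base$retained) "replicated"
      else if (!ok_p) "not_significant"
      else if (!ok_dir1) "direction_mismatch_array"
      else "direction_mismatch_aggregate"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
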