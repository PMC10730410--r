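# Construction of the brain-regulatory eQTL test set: significant
# catalog rows, restriction to regions supported by both accessibility
# peaks and Hi-C loop anchors, and the survival funnel. All thresholds
# are strict inequalities (FDR < 0.05 etc.), matching the printed rules.

#' Filter an eQTL catalog to significant rows
#'
#' Retains (variant, gene, region) rows with FDR strictly below the
#' threshold and emits the deduplicated variant set (union across genes
#' and regions) used as association candidates.
#'
#' @param catalog an `eqtl_catalog` data.frame (columns `variant_id`,
#'   `gene`, `region`, `fdr`, ...).
#' @param fdr_threshold strict significance threshold (default 0.05).
#' @param regions valid region labels; rows with labels outside this
#'   vocabulary raise an error. `NULL` skips the check.
#' @return list: `catalog` (significant rows), `candidates` (unique
#'   variant ids).
#' @export
filter_significant_eqtls <- function(catalog, fdr_threshold = 0.05,
                                     regions = NULL) {
  stopifnot(is.data.frame(catalog),
            all(c("variant_id", "gene", "region", "fdr") %in%
                names(catalog)))
  if (!is.null(regions) && !all(catalog$region %in% regions))
    stop("unknown region label(s): ",
         paste(setdiff(unique(catalog$region), regions), collapse = ", "))
  sig <- catalog[catalog$fdr < fdr_threshold, , drop = FALSE]
  list(catalog = sig, candidates = unique(sig$variant_id))
}

#' Intersect accessibility peaks with loop-anchor territory
#'
#' The accessibility union A is the merged union of all assays' peaks;
#' the loop territory L is the merged union of all loop anchors (both
#' anchors, not the full loop span). The regulatory region set is the
#' interval intersection A and L, normalized (sorted, merged).
#'
#' @param peaks list of `GRanges` (one per assay) or a single `GRanges`.
#' @param loops a `loop_set`, or a `GRanges` of anchor intervals.
#' @return `GRanges` of regulatory intervals (possibly empty, with a
#'   warning when either input is empty).
#' @export
build_regulatory_regions <- function(peaks, loops) {
  if (inherits(peaks, "GRanges")) peaks <- list(peaks)
  acc <- GenomicRanges::reduce(do.call(c, unname(peaks)))
  anchors <- if (inherits(loops, "loop_set"))
    c(loops$anchor1, loops$anchor2) else loops
  loop_u <- GenomicRanges::reduce(anchors)
  if (length(acc) == 0 || length(loop_u) == 0) {
    warning("empty peak or loop input; regulatory region set is empty")
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(GenomicRanges::intersect(acc, loop_u))
}

#' Select candidate eQTLs inside regulatory regions, with funnel counts
#'
#' A variant at 1-based position p lies inside a 0-based half-open
#' interval [s, e) iff s <= p-1 < e; with intervals held 1-based closed
#' this is s+1 <= p <= e, which is plain GRanges overlap. The funnel
#' reports survival at each stage: significant catalog rows, candidate
#' variants, candidates inside the accessibility union, candidates
#' inside accessibility-intersect-loops (the test set); the post-QC
#' count is appended by the association stage.
#'
#' @param candidates data.frame with `variant_id`, `contig`, `pos`
#'   (1-based).
#' @param regions regulatory `GRanges` from [build_regulatory_regions()].
#' @param accessibility optional accessibility-union `GRanges` for the
#'   intermediate funnel stage.
#' @param n_significant_rows optional count of significant catalog rows
#'   for the funnel head.
#' @return list: `test_set` (candidate rows inside `regions`), `funnel`
#'   (named integer vector).
#' @export
select_regulatory_eqtls <- function(candidates, regions,
                                    accessibility = NULL,
                                    n_significant_rows = NA_integer_) {
  stopifnot(is.data.frame(candidates),
            all(c("variant_id", "contig", "pos") %in% names(candidates)))
  pos_gr <- GenomicRanges::GRanges(
    candidates$contig, IRanges::IRanges(candidates$pos, candidates$pos))
  in_reg <- if (length(regions) > 0)
    IRanges::overlapsAny(pos_gr, regions) else rep(FALSE, nrow(candidates))
  in_acc <- if (!is.null(accessibility) && length(accessibility) > 0)
    IRanges::overlapsAny(pos_gr, accessibility)
  else rep(NA, nrow(candidates))
  funnel <- c(significant_eqtl_rows = as.integer(n_significant_rows),
              candidate_variants = nrow(candidates),
              in_accessibility = if (all(is.na(in_acc))) NA_integer_
                                 else sum(in_acc),
              in_accessibility_and_loops = sum(in_reg))
  list(test_set = candidates[in_reg, , drop = FALSE], funnel = funnel)
}
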