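# Containers and readers/writers for the standard formats the pipeline
# touches: VCF 4.2 genotypes with per-call DP/GQ, BED peaks, BEDPE loops,
# and TSV tables. All interval containers are GRanges (1-based closed);
# BED/BEDPE 0-based half-open coordinates are converted exactly once at
# ingest, so a BED interval [s,e) becomes GRanges [s+1, e].

#' Construct a genotype dataset
#'
#' Bundles a sample table (phenotype + covariates), a variant table, and
#' per-call dosage/quality matrices into the container every downstream
#' stage consumes.
#'
#' @param samples data.frame with at least `sample_id` and `status`
#'   (1 = case, 0 = control); typically also `sex` ("M"/"F"), `age`, and
#'   ancestry covariate columns `PC1`..`PC10`.
#' @param variants data.frame with `variant_id`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, and logical `biallelic`.
#' @param dosage integer matrix, samples x variants, alt-allele counts in
#'   {0,1,2}; `NA` marks a missing call.
#' @param dp,gq optional integer matrices of per-call read depth and
#'   genotype quality, same shape as `dosage`.
#' @param planted optional data.frame recording simulated truth
#'   (variant_id, or_, gene, eqtl_beta, maf); `NULL` for real data.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, variants, dosage, dp = NULL, gq = NULL,
                             planted = NULL) {
  stopifnot(is.data.frame(samples), is.data.frame(variants),
            is.matrix(dosage))
  if (nrow(samples) != nrow(dosage) || nrow(variants) != ncol(dosage))
    stop("dosage dimensions do not match sample/variant tables")
  for (m in list(dp, gq))
    if (!is.null(m) && !identical(dim(m), dim(dosage)))
      stop("dp/gq dimensions must match dosage")
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosage entries must be 0, 1, 2 or NA")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$variant_id
  structure(list(samples = samples, variants = variants, dosage = dosage,
                 dp = dp, gq = gq, planted = planted),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples (%d cases / %d controls), %d variants\n",
              nrow(x$samples), sum(x$samples$status == 1),
              sum(x$samples$status == 0), nrow(x$variants)))
  cat(sprintf("  call quality: %s\n",
              if (is.null(x$dp)) "absent" else "DP/GQ per call"))
  invisible(x)
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Write a genotype dataset as VCF 4.2
#'
#' Emits one biallelic record per variant with FORMAT `GT:DP:GQ`
#' (or `GT` alone when call-quality matrices are absent). Positions are
#' written 1-based as VCF requires. Output is deterministic: the same
#' dataset always produces byte-identical files.
#'
#' @param gd a `genotype_dataset`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gd, path) {
  stopifnot(inherits(gd, "genotype_dataset"))
  v <- gd$variants
  has_q <- !is.null(gd$dp) && !is.null(gd$gq)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=regeqtl",
           sprintf("##contig=<ID=%s>", unique(v$contig)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_q)
    hdr <- c(hdr,
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        gd$samples$sample_id),
                      collapse = "\t"))
  fmt <- if (has_q) "GT:DP:GQ" else "GT"
  body <- vapply(seq_len(nrow(v)), function(j) {
    gt <- dosage_to_gt(gd$dosage[, j])
    cell <- if (has_q) paste(gt, gd$dp[, j], gd$gq[, j], sep = ":") else gt
    paste(c(v$contig[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", fmt, cell), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

gt_to_dosage <- function(gt) {
  # count of allele "1"; any allele index >= 2 (multiallelic call) -> NA
  d <- rep(NA_integer_, length(gt))
  clean <- !is.na(gt) & grepl("^[01.]([/|][01.])?$", gt)
  alleles <- strsplit(gsub("\\|", "/", gt[clean]), "/")
  d[clean] <- vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  d
}

#' Read a VCF into a genotype dataset
#'
#' Parses GT (and DP/GQ when present) from a VCF 4.2 file. Multiallelic
#' records are preserved but flagged `biallelic = FALSE` so `variant_qc()`
#' can exclude them; missing genotypes (`./.`) become missing dosage.
#' Sample order follows the VCF header.
#'
#' @param path VCF file (plain or gzipped).
#' @return A `genotype_dataset`; the sample table carries ids only
#'   (phenotype/covariates are attached from a separate table).
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("VCF parse error in '", path,
                                           "': ", conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dosage <- apply(gt_raw, 2, gt_to_dosage)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(gt_raw))
  dosage <- t(dosage)  # samples x variants
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    biallelic = !grepl(",", fix$ALT),
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt_raw),
                        status = NA_integer_, stringsAsFactors = FALSE)
  dp <- gq <- NULL
  if (ncol(vcf@gt) > 1 && grepl("DP", vcf@gt[1, 1])) {
    dp <- t(apply(vcfR::extract.gt(vcf, element = "DP"), 2, as.integer))
    gq <- t(apply(vcfR::extract.gt(vcf, element = "GQ"), 2, as.integer))
    dimnames(dp) <- dimnames(gq) <- NULL
  }
  genotype_dataset(samples, variants, dosage, dp = dp, gq = gq)
}

#' Read genomic intervals (BED) or loops (BEDPE)
#'
#' BED coordinates (0-based half-open) are converted to 1-based closed
#' GRanges at ingest; this is the only coordinate conversion in the
#' package. Negative coordinates and empty intervals (`start >= end`)
#' are rejected.
#'
#' @param path tab-separated file, >= 3 columns (BED) or >= 6 (BEDPE).
#' @param format `"bed"` or `"bedpe"`.
#' @return For BED, a `GRanges`; for BEDPE, a `loop_set` (paired anchors).
#' @export
read_intervals <- function(path, format = c("bed", "bedpe")) {
  format <- match.arg(format)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  need <- if (format == "bed") 3L else 6L
  if (ncol(df) < need)
    stop(format, " requires >= ", need, " columns")
  check_iv <- function(s, e, what) {
    if (any(s < 0)) stop(what, ": negative coordinates")
    if (any(s >= e)) stop(what, ": start >= end")
  }
  if (format == "bed") {
    check_iv(df[[2]], df[[3]], "BED")
    return(GenomicRanges::GRanges(df[[1]],
                                  IRanges::IRanges(df[[2]] + 1L, df[[3]])))
  }
  check_iv(df[[2]], df[[3]], "BEDPE anchor1")
  check_iv(df[[5]], df[[6]], "BEDPE anchor2")
  loop_set(
    anchor1 = GenomicRanges::GRanges(df[[1]],
                                     IRanges::IRanges(df[[2]] + 1L, df[[3]])),
    anchor2 = GenomicRanges::GRanges(df[[4]],
                                     IRanges::IRanges(df[[5]] + 1L, df[[6]])),
    cell_type = if (ncol(df) >= 7) as.character(df[[7]])
                else rep(NA_character_, nrow(df)))
}

#' Paired chromatin-interaction loop anchors
#'
#' @param anchor1,anchor2 `GRanges` of equal length.
#' @param cell_type optional character vector of cell-type labels.
#' @return An object of class `loop_set`.
#' @export
loop_set <- function(anchor1, anchor2, cell_type = NULL) {
  stopifnot(length(anchor1) == length(anchor2))
  structure(list(anchor1 = anchor1, anchor2 = anchor2,
                 cell_type = cell_type %||%
                   rep(NA_character_, length(anchor1))),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("loop_set: %d loops\n", length(x$anchor1)))
  invisible(x)
}

#' Write intervals as BED (0-based half-open)
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write loops as BEDPE (two 0-based half-open anchors)
#' @param loops a `loop_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  a1 <- loops$anchor1; a2 <- loops$anchor2
  df <- data.frame(as.character(GenomicRanges::seqnames(a1)),
                   GenomicRanges::start(a1) - 1L, GenomicRanges::end(a1),
                   as.character(GenomicRanges::seqnames(a2)),
                   GenomicRanges::start(a2) - 1L, GenomicRanges::end(a2),
                   loops$cell_type)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
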