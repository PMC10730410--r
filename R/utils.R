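#' @keywords internal
"_PACKAGE"

#' @importFrom GenomicRanges GRanges seqnames reduce intersect shift
#' @importFrom IRanges IRanges overlapsAny start end
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats glm.fit binomial pnorm qnorm qchisq median cor rbinom
#'   rnorm runif rpois rbeta plogis qlogis p.adjust fisher.test wilcox.test
#'   ks.test complete.cases sd setNames
#' @importFrom utils read.table write.table head
NULL

# Deterministic sub-seed for a named generator, derived from the run seed.
# Keeps every derived seed in [0, 2^31): R's set.seed() takes 32-bit ints.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 131) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Evaluate expr under a local RNG state; global stream untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
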