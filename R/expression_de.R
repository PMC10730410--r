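# Case/control differential expression. Following the analysis contract,
# the regression direction is group-as-outcome: per gene, logistic
# regression of case status on z-scored expression with sex and age
# covariates (plus study when more than one study is present), Wald p,
# BH FDR across genes. Small-sample datasets use permutation empirical
# p-values ((b+1)/(B+1), labels permuted within study strata);
# sex-stratified runs assign male-/female-specificity by the
# FDR < 0.05 in one sex but > 0.05 in the other rule.

de_design <- function(meta, case_label, control_label) {
  keep <- meta$group %in% c(case_label, control_label)
  y <- as.numeric(meta$group[keep] == case_label)
  covs <- cbind(sex = as.numeric(meta$sex[keep] == "F"),
                age = meta$age[keep])
  if (length(unique(meta$study[keep])) > 1) {
    studies <- sort(unique(meta$study[keep]))[-1]
    for (s in studies)
      covs <- cbind(covs,
                    setNames(data.frame(as.numeric(meta$study[keep] == s)),
                             paste0("study_", s)))
  }
  covs <- as.matrix(covs)
  # constant covariates (e.g. sex within a single-sex stratum) are
  # dropped rather than left to break the fit
  varying <- apply(covs, 2, function(x) length(unique(x)) > 1)
  list(keep = keep, y = y, covs = covs[, varying, drop = FALSE])
}

# one-gene fit: z of the expression coefficient (NA for degenerate fits)
de_fit_one <- function(e, y, covs) {
  if (sd(e) == 0) return(NULL)
  ez <- (e - mean(e)) / sd(e)
  X <- cbind(1, expr = ez, covs)
  res <- logistic_wald(X, y)
  data.frame(coefficient = res$beta[2], se = res$se[2],
             z = res$beta[2] / res$se[2],
             separation = res$separation, row.names = NULL)
}

#' Differential expression by covariate-adjusted logistic regression
#'
#' Per gene: case status regressed on z-scored expression plus sex, age
#' and (when >1 study) study indicators; Wald two-sided p; BH q across
#' the genes in the contrast. Constant-expression genes are skipped;
#' separated fits are flagged.
#'
#' @param expr an `expression_matrix` (genes x samples + metadata).
#' @param case_label,control_label group labels to contrast (default
#'   "case" vs "control").
#' @return data.frame: `gene`, `coefficient`, `se`, `z`, `p`, `q`,
#'   `separation`.
#' @export
de_test <- function(expr, case_label = "case",
                    control_label = "control") {
  stopifnot(inherits(expr, "expression_matrix"))
  dd <- de_design(expr$metadata, case_label, control_label)
  if (length(unique(dd$y)) < 2)
    stop("both contrast groups must be present")
  rows <- lapply(rownames(expr$expr), function(g) {
    fit <- de_fit_one(expr$expr[g, dd$keep], dd$y, dd$covs)
    if (is.null(fit)) return(NULL)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), fit)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable genes")
  out$p <- 2 * pnorm(-abs(out$z))
  out$q <- NA_real_
  ok <- !is.na(out$p)        # degenerate (collinear/separated) fits
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Permutation empirical p-values for the DE statistic
#'
#' Permutes group labels within study strata (preserving each stratum's
#' group margins exactly) and recomputes the per-gene Wald z of the
#' expression coefficient; p_emp = (b + 1) / (B + 1) with b = permuted
#' |z| at or above the observed |z|. Deterministic under a fixed seed.
#'
#' @param expr an `expression_matrix`.
#' @param B number of randomizations (default 1000).
#' @param seed permutation seed.
#' @param case_label,control_label group labels to contrast.
#' @return data.frame: `gene`, `z_obs`, `p_emp`.
#' @export
de_empirical_p <- function(expr, B = 1000L, seed = 1L,
                           case_label = "case",
                           control_label = "control") {
  stopifnot(inherits(expr, "expression_matrix"), B >= 1)
  dd <- de_design(expr$metadata, case_label, control_label)
  y <- dd$y
  strata <- expr$metadata$study[dd$keep]
  for (s in unique(strata))
    if (length(unique(y[strata == s])) < 2)
      stop("stratum '", s, "' lacks one of the contrast groups")
  genes <- rownames(expr$expr)
  E <- expr$expr[, dd$keep, drop = FALSE]
  zs <- vapply(genes, function(g) {
    fit <- de_fit_one(E[g, ], y, dd$covs)
    if (is.null(fit)) NA_real_ else fit$z
  }, numeric(1))
  counts <- integer(length(genes))
  with_seed(substream_seed(seed, "de_perm"), {
    for (b in seq_len(B)) {
      yp <- y
      for (s in unique(strata)) {
        i <- which(strata == s)
        yp[i] <- y[i][sample.int(length(i))]
      }
      zp <- vapply(genes, function(g) {
        fit <- de_fit_one(E[g, ], yp, dd$covs)
        if (is.null(fit)) NA_real_ else fit$z
      }, numeric(1))
      counts <- counts + as.integer(!is.na(zp) & !is.na(zs) &
                                    abs(zp) >= abs(zs))
    }
  })
  data.frame(gene = genes, z_obs = zs,
             p_emp = (counts + 1) / (B + 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Sex-stratified differential expression and specificity calls
#'
#' Runs [de_test()] separately per sex and assigns specificity:
#' male-specific iff q < 0.05 in males but q > 0.05 in females,
#' female-specific by the mirrored rule, `none` otherwise (including
#' genes significant in both sexes). When a sex is absent from either
#' group, that stratum is skipped and no specificity calls are made.
#'
#' @param expr an `expression_matrix`.
#' @param case_label,control_label group labels to contrast.
#' @param fdr_threshold the per-sex significance threshold (default
#'   0.05).
#' @return data.frame: `gene`, `q_male`, `q_female`, `sex_specific`.
#' @export
sex_stratified <- function(expr, case_label = "case",
                           control_label = "control",
                           fdr_threshold = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  run_sex <- function(sx) {
    keep <- expr$metadata$sex == sx
    sub <- structure(list(expr = expr$expr[, keep, drop = FALSE],
                          metadata = expr$metadata[keep, , drop = FALSE]),
                     class = "expression_matrix")
    groups <- unique(sub$metadata$group)
    if (!all(c(case_label, control_label) %in% groups)) return(NULL)
    de_test(sub, case_label, control_label)
  }
  de_m <- run_sex("M"); de_f <- run_sex("F")
  if (is.null(de_m) || is.null(de_f)) {
    warning("a sex stratum lacks a contrast group; no specificity calls")
    return(data.frame(gene = character(0), q_male = numeric(0),
                      q_female = numeric(0),
                      sex_specific = character(0)))
  }
  m <- merge(de_m[, c("gene", "q")], de_f[, c("gene", "q")],
             by = "gene", suffixes = c("_male", "_female"))
  m$sex_specific <- "none"
  m$sex_specific[which(m$q_male < fdr_threshold &
                       m$q_female > fdr_threshold)] <- "male"
  m$sex_specific[which(m$q_female < fdr_threshold &
                       m$q_male > fdr_threshold)] <- "female"
  m
}
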