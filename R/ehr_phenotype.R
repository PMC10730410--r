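# Demographic and diagnostic-prevalence contrasts between carriers and
# non-carriers of identified risk alleles: per-category 2x2 Fisher exact
# tests with Haldane-corrected odds ratios, BH FDR across categories,
# rank-sum age comparison, Fisher sex comparison, and an optional
# sex- and age-adjusted logistic sensitivity model per category.

#' Carrier versus non-carrier phenotype contrast
#'
#' For each diagnostic category: 2x2 table (diagnosis x carrier), odds
#' ratio with the Haldane-Anscombe 0.5 correction on zero cells, Fisher
#' exact two-sided p, then BH FDR across the categories. Age is
#' compared by Wilcoxon rank-sum and sex by Fisher exact. With
#' `adjusted = TRUE`, each category also gets a logistic model of the
#' diagnosis on carrier status with sex and age covariates, as a
#' sensitivity check that neither demographic drives the contrast.
#'
#' @param dx diagnosis table: `sample_id`, `sex`, `age`, one 0/1 column
#'   per category.
#' @param carrier logical (or 0/1) vector aligned with `dx` rows.
#' @param categories category columns to test (default: all 0/1 columns
#'   besides the id/demographic ones).
#' @param adjusted also fit the sex/age-adjusted logistic model.
#' @return list: `categories` (per-category data.frame with `or_`, `p`,
#'   `q`, prevalences, optional adjusted stats), `age` (rank-sum
#'   comparison), `sex` (Fisher comparison).
#' @export
carrier_contrast <- function(dx, carrier, categories = NULL,
                             adjusted = FALSE) {
  carrier <- as.logical(carrier)
  stopifnot(length(carrier) == nrow(dx))
  if (all(carrier) || !any(carrier))
    stop("need at least one carrier and one non-carrier")
  if (is.null(categories))
    categories <- setdiff(names(dx), c("sample_id", "sex", "age"))
  rows <- lapply(categories, function(k) {
    f <- dx[[k]]
    a <- sum(f == 1 & carrier);  b <- sum(f == 0 & carrier)
    c_ <- sum(f == 1 & !carrier); d <- sum(f == 0 & !carrier)
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    ctab <- if (any(tab == 0)) tab + 0.5 else tab
    or_ <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
    out <- data.frame(category = k,
                      prev_carrier = a / (a + b),
                      prev_noncarrier = c_ / (c_ + d),
                      or_ = or_, p = fisher.test(tab)$p.value,
                      stringsAsFactors = FALSE)
    if (adjusted) {
      X <- cbind(1, carrier = as.numeric(carrier),
                 sex = as.numeric(dx$sex == "F"), age = dx$age)
      fit <- tryCatch(logistic_wald(X, f), error = function(e) NULL)
      out$or_adjusted <- if (is.null(fit)) NA_real_ else exp(fit$beta[2])
      out$p_adjusted <- if (is.null(fit)) NA_real_ else
        2 * pnorm(-abs(fit$beta[2] / fit$se[2]))
    }
    out
  })
  cat_df <- do.call(rbind, rows)
  cat_df$q <- bh_fdr(cat_df$p)
  rownames(cat_df) <- NULL
  age_test <- suppressWarnings(
    wilcox.test(dx$age[carrier], dx$age[!carrier]))
  sex_tab <- table(factor(dx$sex, levels = c("F", "M")), carrier)
  sex_p <- if (all(dim(sex_tab) == c(2, 2)))
    fisher.test(sex_tab)$p.value else NA_real_
  list(categories = cat_df,
       age = data.frame(mean_carrier = mean(dx$age[carrier]),
                        mean_noncarrier = mean(dx$age[!carrier]),
                        p = age_test$p.value),
       sex = data.frame(frac_female_carrier =
                          mean(dx$sex[carrier] == "F"),
                        frac_female_noncarrier =
                          mean(dx$sex[!carrier] == "F"),
                        p = sex_p))
}
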