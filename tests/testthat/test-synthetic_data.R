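test_that("fixed seed gives byte-identical VCF output", {
  cfg <- small_config(seed = 11)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_cohort(cfg), p1)
  write_vcf(simulate_cohort(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(planted_risk = data.frame(
    or_ = -1, gene = "G0001", eqtl_beta = 0.5, maf = 0.3)),
    "odds ratios")
  expect_error(sim_config(peak_overlap_frac = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(maf_range = c(0.1, 0.7)), "maf_range")
})

test_that("cohort has calibrated case mix, planted effect, DP/GQ tails", {
  cfg <- sim_config(n_cases = 400, n_controls = 200, n_variants = 400,
                    n_genes = 20, seed = 5, dp_low_frac = 0.05,
                    gq_low_frac = 0.05)
  gd <- simulate_cohort(cfg)
  expect_equal(sum(gd$samples$status == 1), 400)
  expect_equal(sum(gd$samples$status == 0), 200)
  # planted risk allele enriched in cases
  d <- gd$dosage[, gd$planted$variant_id]
  expect_gt(mean(d[gd$samples$status == 1]),
            mean(d[gd$samples$status == 0]))
  expect_equal(mean(gd$dp < 20), 0.05, tolerance = 0.25)
  expect_equal(mean(gd$gq <= 30), 0.05, tolerance = 0.25)
  expect_true(all(c("sex", paste0("PC", 1:10)) %in% names(gd$samples)))
})

test_that("eQTL catalog has pairs x regions rows and planted significance", {
  cfg <- small_config(seed = 2)
  cat_df <- simulate_eqtl_catalog(cfg)
  expect_equal(nrow(cat_df), 25 * 4 * 13)
  expect_equal(sort(unique(cat_df$region)), sort(BRAIN_REGIONS))
  gd <- simulate_cohort(cfg)
  pl <- gd$planted
  rows <- cat_df[cat_df$variant_id == pl$variant_id &
                 cat_df$gene == pl$gene, ]
  expect_equal(nrow(rows), 13)
  expect_lt(min(rows$fdr), 0.05)                 # significant somewhere
  sig_rows <- rows[rows$fdr < 0.05, ]
  expect_true(all(sign(sig_rows$beta) == sign(pl$eqtl_beta)))
})

test_that("all-null catalog keeps the FDR<0.05 row fraction near zero", {
  fracs <- vapply(1:5, function(s) {
    cfg <- null_config(seed = s, frac_true_eqtl = 0)
    cat_df <- simulate_eqtl_catalog(cfg)
    mean(cat_df$fdr < 0.05)
  }, numeric(1))
  expect_lt(mean(fracs), 0.05)                   # BH null bound
})

test_that("regulatory overlap fractions drive test-set survival", {
  run_frac <- function(pf, lf, seed = 1) {
    cfg <- small_config(seed = seed, peak_overlap_frac = pf,
                        loop_overlap_frac = lf)
    gd <- simulate_cohort(cfg)
    cat_df <- simulate_eqtl_catalog(cfg)
    sig <- filter_significant_eqtls(cat_df)
    tr <- simulate_regulatory_tracks(cfg, candidate_ids = sig$candidates)
    regions <- build_regulatory_regions(tr$peaks, tr$loops)
    cand <- gd$variants[match(sig$candidates, gd$variants$variant_id), ]
    sel <- select_regulatory_eqtls(cand, regions)
    nrow(sel$test_set) / nrow(cand)
  }
  expect_equal(run_frac(1, 1), 1)
  expect_equal(run_frac(0, 1), 0)
  surv <- vapply(1:6, function(s) run_frac(0.5, 1, seed = s), numeric(1))
  expect_equal(mean(surv), 0.5, tolerance = 0.12)  # Monte Carlo
  expect_error(simulate_regulatory_tracks(
    small_config(peak_overlap_frac = 0.5),
    candidate_ids = character(0))$x, NA)
})

test_that("expression generator plants recoverable group shifts", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_variants = 50,
                    n_genes = 15, seed = 9,
                    de_effects = data.frame(gene = "G0005", shift = 1,
                                            sex = NA))
  gd <- simulate_cohort(cfg)
  ex <- simulate_expression(cfg, gd)
  expect_identical(dim(ex$expr), c(15L, 200L))
  cases <- ex$metadata$group == "case"
  expect_gt(mean(ex$expr["G0005", cases]) -
            mean(ex$expr["G0005", !cases]), 0.5)
  # determinism
  ex2 <- simulate_expression(cfg, gd)
  expect_identical(ex$expr, ex2$expr)
})

test_that("EHR prevalences are recovered and carrier shifts planted", {
  cfg <- sim_config(n_cases = 5000, n_controls = 5000, n_variants = 10,
                    n_genes = 2, seed = 4,
                    dx_prevalence = c(pain = 0.695, anxiety = 0.526))
  samples <- data.frame(sample_id = sprintf("S%05d", 1:10000),
                        sex = rep(c("M", "F"), 5000),
                        age = rep(30:49, 500))
  dx <- simulate_ehr(cfg, samples)
  expect_equal(mean(dx$pain), 0.695, tolerance = 0.015)  # 0.695 +/- 0.01
  expect_equal(mean(dx$anxiety), 0.526, tolerance = 0.015)
  # prevalence 0 -> all flags 0
  cfg0 <- sim_config(dx_prevalence = c(pain = 0), seed = 4)
  dx0 <- simulate_ehr(cfg0, samples[1:50, ])
  expect_true(all(dx0$pain == 0))
  # planted carrier shift
  carrier <- rep(c(TRUE, FALSE), 5000)
  dxs <- simulate_ehr(cfg, samples, carrier = carrier,
                      carrier_effects = data.frame(category = "pain",
                                                   or_ = 1.5))
  cc <- carrier_contrast(dxs, carrier)
  pain_row <- cc$categories[cc$categories$category == "pain", ]
  expect_gt(pain_row$or_, 1)
  expect_lt(pain_row$p, 0.05)
})

test_that("replication frequency cohorts carry the planted direction", {
  cfg <- sim_config(n_cases = 986, n_controls = 415, n_variants = 20,
                    n_genes = 5, seed = 6)
  gd <- simulate_cohort(cfg)
  af <- simulate_af_cohorts(cfg, gd$variants, gd$planted)
  pl <- gd$planted$variant_id
  af_case <- af$array_cases$af[af$array_cases$variant_id == pl]
  af_ctrl <- af$aggregate_controls$af[
    af$aggregate_controls$variant_id == pl]
  expect_gt(af_case, af_ctrl)   # risk allele enriched in cases
  expect_equal(af_ctrl, 0.3, tolerance = 0.02)
})
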