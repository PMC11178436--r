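test_that("alternative allele ratios follow the read-count arithmetic", {
  gt <- matrix(1L, 2, 1, dimnames = list(NULL, "s1"))
  ad_ref <- matrix(c(30L, 30L), 2, 1, dimnames = list(NULL, "s1"))
  ad_alt <- matrix(c(15L, 30L), 2, 1, dimnames = list(NULL, "s1"))
  dp <- ad_ref + ad_alt
  tab <- as_variant_table(gt, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp)
  sp <- suppressWarnings(allele_ratio_spectrum(tab, "s1", min_depth = 20))
  # 15 alt among 45 reads: the 1:2 ratio, i.e. alt fraction exactly 1/3
  expect_equal(sort(sp$ratios), c(1 / 3, 1 / 2))
})

test_that("spectrum mass is conserved and restricted to deep het calls", {
  co <- simulate_cohort(small_spec(n_sites = 600))
  j <- 1
  sp <- suppressWarnings(allele_ratio_spectrum(co$table, j, min_depth = 20))
  tot <- co$table$ad_ref[, j] + co$table$ad_alt[, j]
  expected_n <- sum(!is.na(co$table$gt[, j]) & co$table$gt[, j] == 1L &
                      co$table$dp[, j] >= 20 & tot > 0)
  expect_equal(sp$n_sites, expected_n)
  expect_equal(sum(sp$counts), sp$n_sites, tolerance = 1e-9)
  # raising min_depth can only shrink the spectrum
  sp40 <- suppressWarnings(allele_ratio_spectrum(co$table, j, min_depth = 40))
  expect_lte(sp40$n_sites, sp$n_sites)
})

test_that("spectrum modes sit on the theoretical dosage values", {
  modes <- vapply(c(MM = "MM", MMT = "MMT", MTT = "MTT"), function(comp) {
    tab <- simulate_allele_balance_sample(10000, comp, mean_depth = 60,
                                          error_rate = 0.001, seed = 11)
    allele_ratio_spectrum(tab, 1)$mode
  }, 0)
  expect_lt(abs(modes[["MM"]] - 0.50), 0.0101)
  expect_lt(abs(modes[["MMT"]] - 1 / 3), 0.0101)
  expect_lt(abs(modes[["MTT"]] - 2 / 3), 0.0101)
})

test_that("depth tightens the spectrum around the true dosage", {
  sd_at <- function(depth) {
    tab <- simulate_allele_balance_sample(5000, "MM", mean_depth = depth,
                                          error_rate = 0.001, seed = 13)
    sd(allele_ratio_spectrum(tab, 1, min_depth = 10)$ratios)
  }
  s30 <- sd_at(30)
  s120 <- sd_at(120)
  expect_lt(s120, s30)
  expect_equal(s120 / s30, sqrt(30 / 120), tolerance = 0.15)
})

test_that("dosage classification is exact on 50 samples per class", {
  # depth 40, 2000 informative sites per sample
  for (comp in c("MM", "MMT", "MTT")) {
    want <- switch(comp, MM = "DIPLOID_HET", MMT = "TRIPLOID_MMT",
                   MTT = "TRIPLOID_MTT")
    cls <- vapply(1:50, function(seed) {
      tab <- simulate_allele_balance_sample(2000, comp, mean_depth = 40,
                                            error_rate = 0.001, seed = seed)
      classify_hybrid_dosage(allele_ratio_spectrum(tab, 1))$class
    }, "")
    expect_true(all(cls == want), info = comp)
  }
})

test_that("bimodal and thin spectra fall into the guard classes", {
  # equal masses at 1/3 and 1/2: ambiguous by the tie rule
  n <- 400
  gt <- matrix(1L, n, 1, dimnames = list(NULL, "s1"))
  ad_alt <- matrix(c(rep(20L, n / 2), rep(30L, n / 2)), n, 1)
  ad_ref <- matrix(60L, n, 1) - ad_alt
  tab <- as_variant_table(gt, ad_ref = ad_ref, ad_alt = ad_alt,
                          dp = ad_ref + ad_alt)
  sp <- allele_ratio_spectrum(tab, 1)
  expect_equal(classify_hybrid_dosage(sp)$class, "AMBIGUOUS")
  # too few sites: uninformative
  small <- subset_variant_table(tab, sites = 1:50)
  expect_warning(sp_small <- allele_ratio_spectrum(small, 1), "uninformative")
  expect_equal(classify_hybrid_dosage(sp_small)$class, "UNINFORMATIVE")
  # a mode outside every window
  gt9 <- matrix(1L, 300, 1, dimnames = list(NULL, "s1"))
  ad_alt9 <- matrix(54L, 300, 1)
  tab9 <- as_variant_table(gt9, ad_ref = matrix(6L, 300, 1), ad_alt = ad_alt9,
                           dp = matrix(60L, 300, 1))
  expect_equal(classify_hybrid_dosage(allele_ratio_spectrum(tab9, 1))$class,
               "AMBIGUOUS")
})

test_that("sub-genome coverage separates compositions on the combined view", {
  spec <- cohort_spec(n_pops_sp1 = 1, n_pops_sp2 = 1, samples_per_pop = 2,
                      n_sites = 4000, n_sites_t = 4000, reference = "Lj",
                      seed = 27)
  co <- simulate_cohort(spec)
  lm_id <- co$truth$samples$sample[co$truth$samples$species == "Lm"][1]
  lj_id <- co$truth$samples$sample[co$truth$samples$species == "Lj"][1]
  cov_lm <- subgenome_coverage(co$table, lm_id)
  expect_lt(cov_lm$frac_t_covered, 0.05)
  expect_equal(cov_lm$call, "pure_M")
  cov_lj <- subgenome_coverage(co$table, lj_id)
  expect_equal(cov_lj$ratio, 2, tolerance = 0.1)
  expect_equal(cov_lj$call, "MMT")
  # balanced M/T hybrid: ratio near 1
  spec_mt <- cohort_spec(n_pops_sp1 = 0, n_pops_sp2 = 1, samples_per_pop = 1,
                         n_sites = 4000, n_sites_t = 4000, reference = "Lj",
                         ploidy_sp2 = "MT", seed = 28)
  co_mt <- simulate_cohort(spec_mt)
  cov_mt <- subgenome_coverage(co_mt$table, 1)
  expect_equal(cov_mt$ratio, 1, tolerance = 0.1)
  expect_equal(cov_mt$call, "MT")
  # M/T/T: ratio near 1/2
  spec_mtt <- cohort_spec(n_pops_sp1 = 0, n_pops_sp2 = 1, samples_per_pop = 1,
                          n_sites = 4000, n_sites_t = 4000, reference = "Lj",
                          ploidy_sp2 = "MTT", seed = 29)
  cov_mtt <- subgenome_coverage(simulate_cohort(spec_mtt)$table, 1)
  expect_equal(cov_mtt$ratio, 0.5, tolerance = 0.05)
  expect_equal(cov_mtt$call, "MTT")
  # single-sub-genome table errors
  expect_error(subgenome_coverage(
    subset_variant_table(co$table, sites = co$table$sites$subgenome == "M"),
    lj_id), "sub-genome T")
})

test_that("per-sub-genome distances are concordant for a hybrid cohort", {
  # identical partitions of the same SNPs correlate perfectly
  co_small <- simulate_cohort(small_spec(n_sites = 200))
  tab <- co_small$table
  dup <- subset_variant_table(tab, sites = rep(seq_len(200), 2))
  dup$sites$subgenome <- rep(c("A", "B"), each = 200)
  dup$sites$contig <- rep(c("cA", "cB"), each = 200)
  dup$sites$pos <- rep(tab$sites$pos[1:200], 2)
  sc <- subgenome_distance_correlation(dup, nperm = 99, seed = 1)
  expect_equal(sc$correlations$r, 1)
  # hybrid-only cohort: divergence accrued after hybridisation shows up
  # in both sub-genomes, so M and T distances correlate strongly
  spec <- cohort_spec(n_pops_sp1 = 0, n_pops_sp2 = 5, samples_per_pop = 3,
                      n_sites = 1500, n_sites_t = 1500, reference = "Lj",
                      fixed_diff_fraction = 0, seed = 31)
  co <- simulate_cohort(spec)
  sc2 <- subgenome_distance_correlation(co$table, nperm = 199, seed = 2)
  expect_gt(sc2$correlations$r[1], 0.7)
  expect_lt(sc2$correlations$p[1], 0.05)
  # unstructured genotypes in independent partitions: no correlation
  set.seed(9)
  gt_rand <- matrix(sample(0:2, 400 * 10, replace = TRUE), 400, 10,
                    dimnames = list(NULL, paste0("s", 1:10)))
  tab_rand <- as_variant_table(gt_rand)
  tab_rand$sites$subgenome <- rep(c("M", "T"), each = 200)
  sc3 <- subgenome_distance_correlation(tab_rand, nperm = 199, seed = 3)
  expect_lt(abs(sc3$correlations$r[1]), 0.25)
  # a tiny partition is skipped with a warning
  tab_skew <- tab_rand
  tab_skew$sites$subgenome <- c(rep("M", 380), rep("T", 20))
  expect_warning(expect_error(
    subgenome_distance_correlation(tab_skew, min_snps = 50), "fewer than 2"),
    "skipped")
})
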