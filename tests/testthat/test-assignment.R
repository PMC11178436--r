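test_that("closed-form quasibinomial fit matches the glm oracle", {
  # 8-sample worked table: groups 4/4, genotypes 0,0,0,1 | 1,2,2,2
  grp <- rep(c("g1", "g2"), each = 4)
  gt <- c(0, 0, 0, 1, 1, 2, 2, 2)
  for (coding in c("THREE_LEVEL", "FACTOR_A", "FACTOR_B")) {
    coded <- lemnapop:::code_genotype(gt, coding)
    fit <- fit_snp_glm(grp, coded)
    g <- suppressWarnings(
      glm(I(grp == "g2") ~ factor(coded), family = quasibinomial("logit")))
    av <- suppressWarnings(anova(g, test = "F"))
    expect_equal(fit$d_null, g$null.deviance, tolerance = 1e-8)
    expect_equal(fit$d_res, g$deviance, tolerance = 1e-6)
    expect_equal(fit$pct_dev,
                 100 * (g$null.deviance - g$deviance) / g$null.deviance,
                 tolerance = 1e-6)
    if (!fit$separated) {
      expect_equal(fit$f_stat, av$F[2], tolerance = 1e-5)
      expect_equal(fit$p, av$`Pr(>F)`[2], tolerance = 1e-5)
    }
  }
  # and on random designs
  set.seed(21)
  for (rep in 1:20) {
    grp <- sample(rep(c("a", "b"), each = 10))
    gt <- sample(0:2, 20, replace = TRUE)
    if (length(unique(gt)) < 2) next
    fit <- fit_snp_glm(grp, gt)
    g <- suppressWarnings(
      glm(I(grp == "b") ~ factor(gt), family = quasibinomial("logit")))
    expect_equal(fit$pct_dev,
                 100 * (g$null.deviance - g$deviance) / g$null.deviance,
                 tolerance = 1e-6)
    if (!fit$separated) {
      av <- suppressWarnings(anova(g, test = "F"))
      expect_equal(fit$p, av$`Pr(>F)`[2], tolerance = 1e-5)
    }
  }
})

test_that("perfect separation and null association behave as expected", {
  grp <- rep(c("a", "b"), each = 3)
  fit <- fit_snp_glm(grp, c(0, 0, 0, 2, 2, 2))
  expect_true(fit$separated)
  expect_equal(fit$pct_dev, 100)
  expect_lt(fit$p, 1e-10)
  # balanced independence: identical genotype composition in both groups
  grp2 <- rep(c("a", "b"), each = 4)
  fit2 <- fit_snp_glm(grp2, c(0, 0, 1, 2, 0, 0, 1, 2))
  expect_equal(fit2$pct_dev, 0, tolerance = 1e-10)
  expect_error(fit_snp_glm(grp, rep(1, 6)), "single observed")
  expect_error(fit_snp_glm(rep("a", 6), c(0, 1, 0, 1, 0, 1)), "two groups")
})

test_that("BH adjustment matches a hand step-up and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)            # single p: FDR = p
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(200)^2
  expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  # NA p-values propagate and are excluded from ranking
  p_na <- c(0.01, NA, 0.5)
  out <- bh_fdr(p_na)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the best coding maximises percent deviance explained", {
  co <- simulate_cohort(small_spec(n_sites = 120, n_pops_sp1 = 2,
                                   n_pops_sp2 = 2, samples_per_pop = 4))
  species <- co$truth$samples$species
  scan <- scan_assignment_markers(co$table, species)
  tested <- which(!is.na(scan$table$p))
  for (s in tested[seq_len(min(40, length(tested)))]) {
    gt <- co$table$gt[s, ]
    ok <- !is.na(gt)
    for (coding in c("FACTOR_A", "FACTOR_B", "THREE_LEVEL")) {
      coded <- lemnapop:::code_genotype(gt, coding)
      if (length(unique(coded[ok])) < 2) next
      fit <- fit_snp_glm(species, coded)
      expect_gte(scan$table$pct_dev[s] + 1e-6, fit$pct_dev)
    }
  }
})

test_that("scan output is invariant to site order", {
  co <- simulate_cohort(small_spec(n_sites = 150, n_pops_sp1 = 2,
                                   n_pops_sp2 = 2, samples_per_pop = 4))
  species <- co$truth$samples$species
  s1 <- scan_assignment_markers(co$table, species)
  set.seed(3)
  perm <- sample(nrow(co$table$sites))
  s2 <- scan_assignment_markers(
    subset_variant_table(co$table, sites = perm), species)
  back <- order(perm)
  expect_equal(s2$table$pct_dev[back], s1$table$pct_dev)
  expect_equal(s2$table$fdr[back], s1$table$fdr)
  expect_equal(s2$summary$n_significant, s1$summary$n_significant)
})

test_that("scan recovers fixed differences and controls the null", {
  # genotype-level calibration: the 500 parent-fixed sites are truly
  # fixed between the groups in every sample
  spec <- cohort_spec(n_pops_sp1 = 12, n_pops_sp2 = 12, samples_per_pop = 1,
                      n_sites = 2000, fixed_diff_fraction = 0.1,
                      fst_drift = 0, ibd_strength = 0,
                      clone_mutation_rate = 0, seed = 19)
  co <- simulate_cohort(spec)
  tab <- as_variant_table(calls_from_truth(co$truth))
  species <- co$truth$samples$species
  scan <- scan_assignment_markers(tab, species)
  is_fixed <- co$truth$is_fixed
  expect_true(all(scan$table$significant[is_fixed]))
  expect_true(all(scan$table$separated[is_fixed]))
  expect_true(all(scan$table$pct_dev[is_fixed] == 100))
  expect_true(all(scan$table$diff_class[is_fixed] == "hom_vs_het"))
  # empirical FDR among significant calls controlled
  n_sig <- scan$summary$n_significant
  n_false <- sum(scan$table$significant & !is_fixed)
  expect_lte(n_false / max(1, n_sig), 0.05 + 2 * sqrt(0.05 / max(1, n_sig)))
  # permuted labels: near-zero significant fraction
  set.seed(8)
  scan_perm <- scan_assignment_markers(tab, sample(species))
  expect_lte(scan_perm$summary$frac_significant, 0.005)
})

test_that("read-level scan still recovers nearly all fixed sites", {
  spec <- cohort_spec(n_pops_sp1 = 12, n_pops_sp2 = 12, samples_per_pop = 1,
                      n_sites = 2000, fixed_diff_fraction = 0.1,
                      fst_drift = 0, ibd_strength = 0,
                      clone_mutation_rate = 0, missing_rate = 0.01, seed = 19)
  co <- simulate_cohort(spec)
  ft <- filter_variants(co$table)
  fixed_ft <- co$truth$is_fixed[match(site_key(ft), site_key(co$table))]
  scan <- scan_assignment_markers(ft, co$truth$samples$species)
  # occasional 1/3-dosage hets miscalled 0/0 by the diploid-caller
  # emulation cost a site or two the 80% deviance bar; recovery stays high
  expect_gte(mean(scan$table$significant[fixed_ft]), 0.95)
})

test_that("null p-values are calibrated up to their discreteness", {
  spec <- cohort_spec(n_pops_sp1 = 12, n_pops_sp2 = 12, samples_per_pop = 1,
                      n_sites = 2500, fixed_diff_fraction = 0,
                      fst_drift = 0, ibd_strength = 0,
                      clone_mutation_rate = 0, seed = 23)
  co <- simulate_cohort(spec)
  tab <- as_variant_table(calls_from_truth(co$truth))
  species <- co$truth$samples$species
  set.seed(41)
  perm1 <- sample(species)
  perm2 <- sample(species)
  pv <- function(labels) {
    vapply(seq_len(nrow(tab$sites)), function(s) {
      gt <- tab$gt[s, ]
      if (length(unique(gt)) < 2) return(NA_real_)
      fit_snp_glm(labels, gt)$p
    }, 0)
  }
  p1 <- pv(perm1)
  p2 <- pv(perm2)
  ok <- !is.na(p1) & !is.na(p2)
  expect_gt(sum(ok), 2000)
  # tail calibration of the F-test p-values
  expect_lt(abs(mean(p1[ok] <= 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(p1[ok] <= 0.10) - 0.10), 0.03)
  # distributional agreement between two independent null draws
  # (two-sample KS accommodates the discreteness of small-n designs)
  ks <- suppressWarnings(stats::ks.test(p1[ok], p2[ok]))
  expect_gt(ks$p.value, 0.01)
})
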