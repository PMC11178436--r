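test_that("identical spec and seed give byte-identical cohorts", {
  spec <- small_spec(n_sites = 200)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1$table$gt, co2$table$gt)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(co1$table, f1)
  write_vcf(co2$table, f2)
  expect_identical(readLines(f1), readLines(f2))
  co3 <- simulate_cohort(small_spec(n_sites = 200, seed = 43))
  expect_false(identical(co1$table$gt, co3$table$gt))
})

test_that("population placement is deterministic and stays in the box", {
  spec <- cohort_spec(n_pops_sp1 = 23, n_pops_sp2 = 0, n_sites = 10,
                      region_extent_km = 200, seed = 7)
  c1 <- place_populations(spec)
  c2 <- place_populations(spec)
  expect_identical(c1, c2)
  expect_true(all(c1$x_km >= 0 & c1$x_km <= 200))
  expect_true(all(c1$y_km >= 0 & c1$y_km <= 200))
  # max pairwise great-circle distance bounded by the box diagonal
  d <- geo_distance_matrix(c1)
  corners <- data.frame(lat = range(c1$lat), lon = range(c1$lon))
  diag_m <- geo_distance_matrix(corners)[1, 2]
  expect_lte(max(d), diag_m * 1.001)
  one <- place_populations(cohort_spec(n_pops_sp1 = 1, n_pops_sp2 = 0,
                                       n_sites = 10, seed = 1))
  expect_equal(nrow(one), 1)
})

test_that("founder drift matches the Balding-Nichols variance (MC oracle)", {
  fst <- 0.3
  spec <- cohort_spec(n_pops_sp1 = 2, n_pops_sp2 = 0, n_sites = 10000,
                      fixed_diff_fraction = 0, fst_drift = fst,
                      ibd_strength = 0, seed = 5)
  fo <- simulate_founders(spec, place_populations(spec))
  # standardized squared drift (p_k - p)^2 / (p (1 - p)) has mean fst
  z <- (fo$freq_m[1, ] - fo$p_anc)^2 / (fo$p_anc * (1 - fo$p_anc))
  # independent Monte-Carlo oracle: direct Beta draws at matched p_anc
  set.seed(123)
  theta <- (1 - fst) / fst
  pk <- rbeta(length(fo$p_anc), fo$p_anc * theta, (1 - fo$p_anc) * theta)
  z_oracle <- (pk - fo$p_anc)^2 / (fo$p_anc * (1 - fo$p_anc))
  se <- sd(z_oracle) / sqrt(length(z_oracle))
  expect_equal(mean(z), fst, tolerance = 0.05)
  expect_lt(abs(mean(z) - mean(z_oracle)), 6 * se)
})

test_that("fst_drift zero collapses population frequencies to ancestral", {
  spec <- cohort_spec(n_pops_sp1 = 3, n_pops_sp2 = 0, n_sites = 500,
                      fixed_diff_fraction = 0, fst_drift = 0, seed = 2)
  fo <- simulate_founders(spec, place_populations(spec))
  for (k in 1:3) expect_equal(unname(fo$freq_m[k, ]), fo$p_anc)
})

test_that("spatial correlation of founder frequencies yields a Mantel signal", {
  spec <- cohort_spec(n_pops_sp1 = 12, n_pops_sp2 = 0, n_sites = 2000,
                      fixed_diff_fraction = 0, fst_drift = 0.3,
                      ibd_strength = 400, seed = 8)
  coords <- place_populations(spec)
  fo <- simulate_founders(spec, coords)
  d_freq <- as.matrix(dist(fo$freq_m))
  d_geo <- as.matrix(dist(coords[, c("x_km", "y_km")]))
  mt <- mantel_test(d_freq, d_geo, nperm = 499, seed = 1)
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)
})

test_that("true dosage fractions live on the {0, 1/3, 1/2, 2/3, 1} grid", {
  co <- simulate_cohort(small_spec(n_sites = 300))
  grid <- c(0, 1 / 3, 1 / 2, 2 / 3, 1)
  expect_true(all(co$truth$dos_lm %in% grid))
  sp <- co$truth$samples$species
  expect_true(all(co$truth$dos_lm[, sp == "Lm"] %in% c(0, 1 / 2, 1)))
  expect_true(all(co$truth$dos_lm[, sp == "Lj"] %in% c(0, 1 / 3, 2 / 3, 1)))
})

test_that("hybrid compositions give the textbook dosages at fixed sites", {
  # all sites fixed between parents, no mutation: M/M/T sits at 1/3
  spec <- small_spec(fixed_diff_fraction = 1, clone_mutation_rate = 0,
                     n_sites = 100)
  co <- simulate_cohort(spec)
  lj <- co$truth$samples$species == "Lj"
  expect_true(all(co$truth$dos_lm[, lj] == 1 / 3))
  expect_true(all(co$truth$dos_lm[, !lj] == 0))
  # M/T/T at the same sites sits at 2/3
  spec2 <- small_spec(fixed_diff_fraction = 1, clone_mutation_rate = 0,
                      n_sites = 100, ploidy_sp2 = "MTT")
  co2 <- simulate_cohort(spec2)
  expect_true(all(co2$truth$dos_lm[, co2$truth$samples$species == "Lj"] ==
                    2 / 3))
})

test_that("clone-mates are identical when the clone mutation rate is zero", {
  spec <- small_spec(clone_mutation_rate = 0, missing_rate = 0, n_sites = 400)
  co <- simulate_cohort(spec)
  pops <- co$truth$samples$population
  for (p in unique(pops)) {
    idx <- which(pops == p)
    for (j in idx[-1]) {
      expect_identical(co$truth$dos_lm[, idx[1]], co$truth$dos_lm[, j])
    }
  }
})

test_that("read sampling hits the binomial mean and respects depth zero", {
  tab <- simulate_allele_balance_sample(10000, "MMT", mean_depth = 60,
                                        error_rate = 0, seed = 3)
  af <- tab$ad_alt[, 1] / tab$dp[, 1]
  se <- sqrt((1 / 3) * (2 / 3) / (60 * 10000))
  expect_lt(abs(mean(af) - 1 / 3), 3 * se * 2)  # extra slack for Poisson depth
  # zero dosage, zero error: no alt reads, 0/0 calls wherever callable
  tab0 <- simulate_cohort(small_spec(fixed_diff_fraction = 1,
                                     clone_mutation_rate = 0,
                                     error_rate = 0, missing_rate = 0,
                                     n_sites = 200))
  lm_cols <- tab0$truth$samples$species == "Lm"
  expect_true(all(tab0$table$ad_alt[, lm_cols] == 0))
  expect_true(all(tab0$table$gt[, lm_cols] == 0, na.rm = TRUE))
})

test_that("perfect-caller view maps dosages to diploid calls", {
  co <- simulate_cohort(small_spec(n_sites = 150))
  gt <- calls_from_truth(co$truth)
  expect_true(all(gt[co$truth$dos_lm == 0] == 0L))
  expect_true(all(gt[co$truth$dos_lm == 1] == 2L))
  expect_true(all(gt[co$truth$dos_lm == 1 / 3] == 1L))
})

test_that("cohorts round-trip through VCF losslessly", {
  co <- simulate_cohort(small_spec(n_sites = 120, missing_rate = 0.1))
  dir <- tempfile()
  paths <- write_cohort(co$table, co$truth, dir)
  expect_true(all(file.exists(paths)))
  back <- read_vcf(paths[["vcf"]])
  expect_identical(unname(back$gt), unname(co$table$gt))
  expect_identical(unname(back$dp), unname(co$table$dp))
  expect_identical(unname(back$ad_alt), unname(co$table$ad_alt))
  expect_identical(back$samples, co$table$samples)
  expect_identical(back$sites$subgenome, co$table$sites$subgenome)
  # missing calls are written as ./.
  vcf_lines <- readLines(paths[["vcf"]])
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_true(any(grepl("\\./\\.", body)))
  # every contig is declared in the header with its sub-genome tag
  hdr <- grep("^##contig", vcf_lines, value = TRUE)
  for (ctg in unique(co$table$sites$contig)) {
    expect_true(any(grepl(paste0("ID=", ctg, ","), hdr)))
  }
  expect_true(all(grepl("SUBGENOME=M", hdr)))
  meta <- read_metadata(paths[["metadata"]])
  expect_identical(meta$sample, co$truth$samples$sample)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(fst_drift = 1.2), "fst_drift")
  expect_error(cohort_spec(mean_depth = 0), "mean_depth")
  expect_error(cohort_spec(n_pops_sp1 = 0, n_pops_sp2 = 0))
  expect_error(cohort_spec(missing_rate = -0.1), "missing_rate")
})
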