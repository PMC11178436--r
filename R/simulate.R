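#' Place populations uniformly in the sampling region
#'
#' Draws one coordinate per population, uniform over the square sampling
#' box, and converts the planar km coordinates to latitude/longitude
#' around a fixed anchor so that downstream geographic machinery
#' (haversine distances, metadata files) sees realistic decimal degrees.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame with one row per population: `population`,
#'   `species` (`"Lm"` or `"Lj"`), planar `x_km`/`y_km`, and `lat`/`lon`.
#' @export
place_populations <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_pops <- spec$n_pops_sp1 + spec$n_pops_sp2
  x <- runif(n_pops, 0, spec$region_extent_km)
  y <- runif(n_pops, 0, spec$region_extent_km)
  base_lat <- 46.2
  base_lon <- 6.1
  km_per_deg <- 111.1949  # 2*pi*6371/360
  data.frame(
    population = sprintf("P%02d", seq_len(n_pops)),
    species = rep(c("Lm", "Lj"), c(spec$n_pops_sp1, spec$n_pops_sp2)),
    x_km = x, y_km = y,
    lat = base_lat + y / km_per_deg,
    lon = base_lon + x / (km_per_deg * cospi(base_lat / 180)),
    stringsAsFactors = FALSE
  )
}

# Balding-Nichols population frequencies with distance-decaying
# correlation.  Marginally each population frequency is
# Beta(p*theta, (1-p)*theta) with theta = (1-F)/F, i.e. variance
# F * p * (1-p); spatial correlation enters through a Gaussian copula
# with Corr = exp(-d_km / ibd_km).  Sites with p in {0, 1} stay fixed.
bn_drift_frequencies <- function(p_anc, dist_km, fst, ibd_km) {
  n_pops <- nrow(dist_km)
  n_sites <- length(p_anc)
  if (n_pops == 0 || n_sites == 0) {
    return(matrix(numeric(0), n_pops, n_sites))
  }
  if (fst <= 0) {
    return(matrix(rep(p_anc, each = n_pops), n_pops, n_sites))
  }
  if (ibd_km > 0 && n_pops > 1) {
    cc <- exp(-dist_km / ibd_km)
    lc <- chol(cc + diag(1e-10, n_pops))
    z <- crossprod(lc, matrix(rnorm(n_pops * n_sites), n_pops, n_sites))
  } else {
    z <- matrix(rnorm(n_pops * n_sites), n_pops, n_sites)
  }
  u <- pnorm(z)
  theta <- (1 - fst) / fst
  freq <- matrix(0, n_pops, n_sites)
  poly <- p_anc > 0 & p_anc < 1
  for (k in seq_len(n_pops)) {
    freq[k, poly] <- qbeta(u[k, poly], p_anc[poly] * theta,
                           (1 - p_anc[poly]) * theta)
    freq[k, !poly] <- p_anc[!poly]
  }
  freq
}

#' Simulate per-population founder allele frequencies and genotypes
#'
#' Ancestral M-genome frequencies are drawn from Uniform(0.05, 0.95);
#' a fraction of sites is instead fixed between the parental genomes
#' (M allele = REF everywhere, T allele = ALT).  Population frequencies
#' drift around the ancestral value under the Balding-Nichols model,
#' spatially correlated per `ibd_strength` (see [cohort_spec()]).  Each
#' pond founder is a single clone whose haplotypes are Bernoulli draws
#' from its population frequencies.
#'
#' @param spec a [cohort_spec()].
#' @param coords output of [place_populations()].
#' @return A list of class `cohort_founders`: site annotations
#'   (`p_anc`, `is_fixed`, T-site frequencies), per-population frequency
#'   matrices `freq_m` / `freq_t` (populations x sites), and per-population
#'   founder haplotype matrices.
#' @export
simulate_founders <- function(spec, coords) {
  stopifnot(inherits(spec, "cohort_spec"), nrow(coords) >= 1)
  set.seed(spec$seed + 1L)
  n_pops <- nrow(coords)
  nm <- spec$n_sites
  nt <- spec$n_sites_t

  n_fixed <- round(spec$fixed_diff_fraction * nm)
  is_fixed <- rep(FALSE, nm)
  if (n_fixed > 0) is_fixed[sample.int(nm, n_fixed)] <- TRUE
  # alt-allele frequency prior skewed toward low frequencies: in a
  # reference-based VCF the reference allele is the majority state at
  # most discovered SNPs, so the cohort-wide alt-frequency spectrum is
  # far from uniform; Beta(0.8, 4) rescaled to [0.02, 0.98] captures that
  p_anc <- 0.02 + 0.96 * stats::rbeta(nm, 0.8, 4)
  p_anc[is_fixed] <- 0           # no M-internal polymorphism at fixed sites
  t_allele_m <- as.integer(is_fixed)  # T haplotype allele at M-genome sites
  p_anc_t <- 0.02 + 0.96 * stats::rbeta(nt, 0.8, 4)

  dmat <- as.matrix(stats::dist(coords[, c("x_km", "y_km")]))
  freq_m <- bn_drift_frequencies(p_anc, dmat, spec$fst_drift, spec$ibd_strength)
  freq_t <- bn_drift_frequencies(p_anc_t, dmat, spec$fst_drift, spec$ibd_strength)

  copies2 <- ploidy_copies(spec$ploidy_sp2)
  founders <- vector("list", n_pops)
  names(founders) <- coords$population
  for (k in seq_len(n_pops)) {
    is_sp2 <- coords$species[k] == "Lj"
    m_copies <- if (is_sp2) copies2[["m"]] else 2L
    t_copies <- if (is_sp2) copies2[["t"]] else 0L
    hap_m <- matrix(rbinom(nm * m_copies, 1L, freq_m[k, ]), nm, m_copies)
    # T haplotypes seen through the M reference: parental T allele
    hap_tm <- if (t_copies > 0) {
      matrix(rep(t_allele_m, t_copies), nm, t_copies)
    } else {
      matrix(integer(0), nm, 0)
    }
    hap_t <- if (t_copies > 0) {
      matrix(rbinom(nt * t_copies, 1L, freq_t[k, ]), nt, t_copies)
    } else {
      matrix(integer(0), nt, 0)
    }
    founders[[k]] <- list(m_copies = m_copies, t_copies = t_copies,
                          hap_m = hap_m, hap_tm = hap_tm, hap_t = hap_t)
  }
  structure(list(p_anc = p_anc, is_fixed = is_fixed,
                 t_allele_m = t_allele_m, p_anc_t = p_anc_t,
                 freq_m = freq_m, freq_t = freq_t,
                 founders = founders, coords = coords),
            class = "cohort_founders")
}

#' Simulate the samples of a cohort (hidden truth)
#'
#' Clone-mates copy their pond founder's haplotypes; independently per
#' site, with probability `clone_mutation_rate`, one randomly chosen
#' haplotype flips its allele.  The returned truth records, per sample,
#' species, ploidy composition, clone membership and coordinates, and,
#' per site, the true allele dosage fraction under both alignment views.
#'
#' @param spec a [cohort_spec()].
#' @param founders output of [simulate_founders()].
#' @return A list of class `cohort_truth` with elements `samples` (data
#'   frame), dosage matrices `dos_lm` (sites x samples; all haplotypes
#'   piled on the M reference, so values lie in {0, 1/3, 1/2, 2/3, 1}),
#'   `dos_lj_m` and `dos_lj_t` (per-sub-genome views), per-sample
#'   haplotype matrices, and the site annotations.
#' @export
simulate_samples <- function(spec, founders) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(founders, "cohort_founders"))
  set.seed(spec$seed + 2L)
  coords <- founders$coords
  nm <- spec$n_sites
  nt <- spec$n_sites_t
  n_pops <- nrow(coords)
  n_samples <- sum(spec$samples_per_pop)

  sample_ids <- character(n_samples)
  samp <- data.frame(
    sample = character(n_samples), species = character(n_samples),
    ploidy = character(n_samples), population = character(n_samples),
    clone = character(n_samples), lat = numeric(n_samples),
    lon = numeric(n_samples), m_copies = integer(n_samples),
    t_copies = integer(n_samples), stringsAsFactors = FALSE
  )
  dos_lm <- matrix(0, nm, n_samples)
  dos_lj_m <- matrix(0, nm, n_samples)
  dos_lj_t <- matrix(NA_real_, nt, n_samples)
  hap_m <- vector("list", n_samples)   # M-site alleles, cols = M then T copies
  hap_t <- vector("list", n_samples)

  idx <- 0L
  for (k in seq_len(n_pops)) {
    fo <- founders$founders[[k]]
    n_hap <- fo$m_copies + fo$t_copies
    for (s in seq_len(spec$samples_per_pop[k])) {
      idx <- idx + 1L
      id <- sprintf("%s_s%d", coords$population[k], s)
      sample_ids[idx] <- id
      hm <- cbind(fo$hap_m, fo$hap_tm)
      ht <- fo$hap_t
      mu <- spec$clone_mutation_rate
      if (mu > 0) {
        mut <- which(runif(nm) < mu)
        if (length(mut)) {
          j <- sample.int(n_hap, length(mut), replace = TRUE)
          hm[cbind(mut, j)] <- 1L - hm[cbind(mut, j)]
        }
        if (fo$t_copies > 0) {
          mut_t <- which(runif(nt) < mu)
          if (length(mut_t)) {
            j <- sample.int(fo$t_copies, length(mut_t), replace = TRUE)
            ht[cbind(mut_t, j)] <- 1L - ht[cbind(mut_t, j)]
          }
        }
      }
      hap_m[[idx]] <- hm
      hap_t[[idx]] <- ht
      dos_lm[, idx] <- rowSums(hm) / n_hap
      dos_lj_m[, idx] <- rowSums(hm[, seq_len(fo$m_copies), drop = FALSE]) /
        fo$m_copies
      if (fo$t_copies > 0) dos_lj_t[, idx] <- rowSums(ht) / fo$t_copies
      samp[idx, c("sample", "species", "ploidy", "population", "clone")] <-
        c(id, coords$species[k],
          if (coords$species[k] == "Lm") "M/M"
          else gsub("(?<=.)(?=.)", "/", spec$ploidy_sp2, perl = TRUE),
          coords$population[k], paste0(coords$population[k], "_c1"))
      samp$lat[idx] <- coords$lat[k]
      samp$lon[idx] <- coords$lon[k]
      samp$m_copies[idx] <- fo$m_copies
      samp$t_copies[idx] <- fo$t_copies
    }
  }
  colnames(dos_lm) <- colnames(dos_lj_m) <- colnames(dos_lj_t) <- sample_ids
  names(hap_m) <- names(hap_t) <- sample_ids
  structure(list(samples = samp, dos_lm = dos_lm, dos_lj_m = dos_lj_m,
                 dos_lj_t = dos_lj_t, hap_m = hap_m, hap_t = hap_t,
                 p_anc = founders$p_anc, is_fixed = founders$is_fixed,
                 p_anc_t = founders$p_anc_t, coords = coords),
            class = "cohort_truth")
}

# shared read sampler: depth ~ Poisson(depth_mean), alt reads ~
# Binomial(depth, d*(1-e) + (1-d)*e); diploid-caller emulation on the
# alt fraction with thresholds t_low/t_high and a minimum callable depth.
sample_reads_and_call <- function(dosage, depth_mean, error_rate,
                                  missing_rate = 0,
                                  t_low = 0.15, t_high = 0.85,
                                  min_call_depth = 4L) {
  n <- length(dosage)
  dp <- rpois(n, depth_mean)
  p_alt <- dosage * (1 - error_rate) + (1 - dosage) * error_rate
  p_alt[is.na(p_alt)] <- 0
  alt <- rbinom(n, dp, p_alt)
  alt[dp == 0] <- 0L
  af <- ifelse(dp > 0, alt / dp, NA_real_)
  gt <- rep(NA_integer_, n)
  callable <- dp >= min_call_depth & !is.na(dosage)
  gt[callable & af <= t_low] <- 0L
  gt[callable & af > t_low & af < t_high] <- 1L
  gt[callable & af >= t_high] <- 2L
  if (missing_rate > 0) gt[runif(n) < missing_rate] <- NA_integer_
  list(dp = as.integer(dp), alt = as.integer(alt),
       ref = as.integer(dp - alt), gt = gt)
}

#' Simulate read depths and diploid-model genotype calls
#'
#' Per site and sample, total depth is Poisson with the view-specific
#' mean, alternative reads are Binomial at the error-perturbed true
#' dosage, and genotypes are called as a diploid caller would: alt
#' fraction <= 0.15 gives 0/0, >= 0.85 gives 1/1, anything between gives
#' 0/1; sites with depth below 4 (or hit by `missing_rate`) are missing.
#' Site QUAL is `min(99, 3 * mean depth)`, a monotone stand-in whose
#' ordering is what the quality filter exercises.
#'
#' Under the `"Lm"` reference view every haplotype contributes to the
#' M-genome sites (mimicking the misalignment of the T copy onto the M
#' reference), so a triploid M/M/T heterozygote appears with dosage 1/3.
#' Under `"Lj"` reads are split by sub-genome of origin: M sites receive
#' `mean_depth * m_copies / 2`, T sites `mean_depth * t_copies / 2`, so a
#' diploid M/M sample has essentially zero T-side coverage and an M/M/T
#' hybrid shows the 2:1 coverage ratio.
#'
#' @param spec a [cohort_spec()].
#' @param truth output of [simulate_samples()].
#' @return A `variant_table` (see [read_vcf()] for the layout).
#' @export
simulate_reads_and_calls <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "cohort_truth"))
  set.seed(spec$seed + 3L)
  n_samples <- nrow(truth$samples)
  sample_ids <- truth$samples$sample
  bases <- c("A", "C", "G", "T")

  make_sites <- function(n, prefix, subgenome) {
    contig <- paste0(prefix, ifelse(seq_len(n) <= ceiling(n / 2), "chr1", "chr2"))
    pos <- integer(n)
    for (ctg in unique(contig)) {
      sel <- contig == ctg
      pos[sel] <- 100L * seq_len(sum(sel))
    }
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(contig = contig, pos = pos, ref = ref, alt = unname(alt),
               qual = NA_real_, subgenome = subgenome,
               stringsAsFactors = FALSE)
  }

  if (spec$reference == "Lm") {
    sites <- make_sites(spec$n_sites, "Lm_", "M")
    dos <- truth$dos_lm
    depth_mean <- matrix(spec$mean_depth, spec$n_sites, n_samples)
  } else {
    sites <- rbind(make_sites(spec$n_sites, "Lm_", "M"),
                   make_sites(spec$n_sites_t, "Lt_", "T"))
    dos <- rbind(truth$dos_lj_m, truth$dos_lj_t)
    depth_mean <- rbind(
      outer(rep(1, spec$n_sites), spec$mean_depth * truth$samples$m_copies / 2),
      outer(rep(1, spec$n_sites_t), spec$mean_depth * truth$samples$t_copies / 2)
    )
  }
  n_sites <- nrow(sites)
  gt <- matrix(NA_integer_, n_sites, n_samples)
  ad_ref <- ad_alt <- dp <- matrix(0L, n_sites, n_samples)
  for (j in seq_len(n_samples)) {
    rc <- sample_reads_and_call(dos[, j], depth_mean[, j],
                                spec$error_rate, spec$missing_rate)
    gt[, j] <- rc$gt
    dp[, j] <- rc$dp
    ad_ref[, j] <- rc$ref
    ad_alt[, j] <- rc$alt
  }
  sites$qual <- pmin(99, 3 * rowMeans(dp))
  colnames(gt) <- colnames(dp) <- colnames(ad_ref) <- colnames(ad_alt) <-
    sample_ids
  new_variant_table(sites, gt, ad_ref, ad_alt, dp, sample_ids)
}

#' Simulate a whole cohort in one call
#'
#' Convenience wrapper chaining [place_populations()],
#' [simulate_founders()], [simulate_samples()] and
#' [simulate_reads_and_calls()].
#'
#' @param spec a [cohort_spec()].
#' @return A list with `spec`, `coords`, `founders`, `truth` and `table`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_pops_sp1 = 2, n_pops_sp2 = 1,
#'                                       samples_per_pop = 2, n_sites = 100,
#'                                       seed = 1))
#' dim(cohort$table$gt)
#' @export
simulate_cohort <- function(spec) {
  coords <- place_populations(spec)
  founders <- simulate_founders(spec, coords)
  truth <- simulate_samples(spec, founders)
  table <- simulate_reads_and_calls(spec, truth)
  list(spec = spec, coords = coords, founders = founders,
       truth = truth, table = table)
}

#' Simulate a single sample at a fixed true allele dosage
#'
#' Direct route to the allele-balance machinery: simulates read depths
#' and calls for one sample whose true dosage is constant across sites,
#' as happens at parent-fixed sites in a hybrid (dosage 1/3 for M/M/T,
#' 2/3 for M/T/T) or at heterozygous sites in a diploid (dosage 1/2).
#'
#' @param n_sites number of informative sites.
#' @param composition `"MM"` (diploid heterozygote, dosage 1/2), `"MMT"`
#'   (dosage 1/3) or `"MTT"` (dosage 2/3).
#' @param mean_depth,error_rate read model parameters as in [cohort_spec()].
#' @param seed integer seed.
#' @param sample_id name given to the single sample.
#' @return A one-sample `variant_table`.
#' @examples
#' tab <- simulate_allele_balance_sample(500, "MMT", seed = 1)
#' @export
simulate_allele_balance_sample <- function(n_sites = 10000,
                                           composition = c("MM", "MMT", "MTT"),
                                           mean_depth = 60, error_rate = 0.001,
                                           seed = 1L, sample_id = "s1") {
  composition <- match.arg(composition)
  dosage <- switch(composition, MM = 1 / 2, MMT = 1 / 3, MTT = 2 / 3)
  set.seed(seed)
  rc <- sample_reads_and_call(rep(dosage, n_sites), mean_depth, error_rate)
  sites <- data.frame(
    contig = "Lm_chr1", pos = 100L * seq_len(n_sites),
    ref = "A", alt = "T", qual = pmin(99, 3 * rc$dp),
    subgenome = "M", stringsAsFactors = FALSE
  )
  gt <- matrix(rc$gt, ncol = 1, dimnames = list(NULL, sample_id))
  new_variant_table(sites, gt,
                    matrix(rc$ref, ncol = 1, dimnames = list(NULL, sample_id)),
                    matrix(rc$alt, ncol = 1, dimnames = list(NULL, sample_id)),
                    matrix(rc$dp, ncol = 1, dimnames = list(NULL, sample_id)),
                    sample_id)
}

#' Genotype calls from the hidden truth (perfect caller)
#'
#' Maps true allele dosages straight to diploid-model genotype calls
#' (dosage 0 -> 0/0, 1 -> 1/1, anything intermediate -> 0/1) without
#' simulating reads.  This is the sequencing-noise-free view used for
#' calibration experiments that target the downstream statistics rather
#' than the caller: a parent-fixed site really is fixed between the
#' species groups in every sample.
#'
#' @param truth a `cohort_truth` from [simulate_samples()].
#' @param view `"Lm"` (all haplotypes on the M reference) or `"Lj_m"`
#'   (M sub-genome only).
#' @return Integer genotype matrix (sites x samples, codes 0/1/2).
#' @export
calls_from_truth <- function(truth, view = c("Lm", "Lj_m")) {
  stopifnot(inherits(truth, "cohort_truth"))
  view <- match.arg(view)
  dos <- if (view == "Lm") truth$dos_lm else truth$dos_lj_m
  gt <- matrix(1L, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  gt[dos == 0] <- 0L
  gt[dos == 1] <- 2L
  gt
}

#' Generate per-sample haplotype sequences for the k-mer path
#'
#' Embeds the simulated M-genome alleles into a random sequence backbone
#' (one SNP every `spacing` bases) and emits one sequence per physical
#' haplotype per sample.  Samples that differ in genotype then differ in
#' k-mer content around the variant positions, which is what the
#' reference-free kinship consumes.
#'
#' @param truth a `cohort_truth` from [simulate_samples()].
#' @param spacing distance in bases between consecutive SNPs; must be
#'   comfortably above the k-mer size divided by 2 to keep variant
#'   neighbourhoods mostly independent.
#' @param seed integer seed for the backbone.
#' @return Named list (one element per sample) of character vectors of
#'   haplotype sequences.
#' @export
cohort_sequences <- function(truth, spacing = 40L, seed = 99L) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(seed)
  nm <- nrow(truth$dos_lm)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, nm * spacing + spacing, replace = TRUE)
  site_pos <- spacing * seq_len(nm)
  ref <- backbone[site_pos]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  lapply(truth$hap_m, function(hm) {
    apply(hm, 2, function(h) {
      s <- backbone
      s[site_pos] <- ifelse(h == 1L, alt, ref)
      paste(s, collapse = "")
    })
  })
}
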