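#' Specify a synthetic duckweed cohort
#'
#' Builds the parameter object consumed by the cohort simulator.  The
#' defaults describe a two-species survey at the scale of a regional pond
#' survey: eight *L. minor* (diploid, genome M) populations and four
#' *L. japonica* (triploid M/M/T hybrid) populations spread over a
#' 200 km region, each pond founded by a single clone.
#'
#' Within-species differentiation follows the Balding-Nichols model:
#' population allele frequencies are Beta-distributed around an ancestral
#' frequency with variance `fst_drift * p * (1 - p)`.  Spatial isolation
#' by distance is induced by correlating the per-population drift draws
#' through a Gaussian copula whose correlation decays as
#' `exp(-d_km / ibd_strength)`.
#'
#' A fraction `fixed_diff_fraction` of sites carry a fixed difference
#' between the two parental genomes (M allele = REF, T allele = ALT);
#' these are the sites that make triploid hybrids visible as 1/3 or 2/3
#' allele dosages when reads are interpreted against the M reference.
#'
#' @param n_pops_sp1,n_pops_sp2 number of populations of species 1
#'   (diploid M/M) and species 2 (hybrid, see `ploidy_sp2`).  At least one
#'   population overall is required.
#' @param samples_per_pop samples collected per pond; a scalar or a vector
#'   recycled across all `n_pops_sp1 + n_pops_sp2` populations.
#' @param n_sites number of biallelic SNP sites on the M sub-genome.
#' @param n_sites_t number of sites on the T sub-genome (used only when
#'   `reference = "Lj"`).
#' @param fixed_diff_fraction proportion of M-genome sites fixed between
#'   the two parental genomes.
#' @param fst_drift Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param clone_mutation_rate per-site probability that a clone-mate
#'   differs from its pond founder.
#' @param region_extent_km side length of the square sampling region.
#' @param ibd_strength correlation length (km) of founder-frequency decay
#'   with distance; `0` disables spatial correlation.
#' @param mean_depth expected sequencing depth per site for a diploid
#'   sample.
#' @param error_rate per-read miscall probability (symmetric).
#' @param missing_rate per-genotype missingness probability applied on
#'   top of the depth-driven missingness.
#' @param ploidy_sp2 haplotype composition of species-2 samples: `"MMT"`
#'   (default, two M copies + one T copy), `"MTT"` or `"MT"`.
#' @param reference which alignment view the emitted variant table
#'   emulates: `"Lm"` (M reference only; all haplotypes pile up on M
#'   sites, so triploid dosages appear as thirds) or `"Lj"` (combined
#'   M + T reference; reads are assigned to the sub-genome of their
#'   haplotype of origin).
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   outputs.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_pops_sp1 = 2, n_pops_sp2 = 1, n_sites = 200, seed = 7)
#' @export
cohort_spec <- function(n_pops_sp1 = 8, n_pops_sp2 = 4, samples_per_pop = 4,
                        n_sites = 5000, n_sites_t = n_sites,
                        fixed_diff_fraction = 0.1, fst_drift = 0.3,
                        clone_mutation_rate = 0.001, region_extent_km = 200,
                        ibd_strength = 100, mean_depth = 60,
                        error_rate = 0.001, missing_rate = 0.02,
                        ploidy_sp2 = c("MMT", "MTT", "MT"),
                        reference = c("Lm", "Lj"), seed = 1L) {
  ploidy_sp2 <- match.arg(ploidy_sp2)
  reference <- match.arg(reference)
  n_pops <- n_pops_sp1 + n_pops_sp2
  stopifnot(
    n_pops_sp1 >= 0, n_pops_sp2 >= 0, n_pops >= 1,
    n_sites >= 1, n_sites_t >= 1,
    all(samples_per_pop >= 1),
    fixed_diff_fraction >= 0, fixed_diff_fraction <= 1,
    fst_drift >= 0, fst_drift < 1,
    clone_mutation_rate >= 0, clone_mutation_rate <= 1,
    error_rate >= 0, error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    region_extent_km > 0, ibd_strength >= 0, mean_depth > 0,
    length(seed) == 1, is.finite(seed)
  )
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  spec <- list(
    n_pops_sp1 = as.integer(n_pops_sp1),
    n_pops_sp2 = as.integer(n_pops_sp2),
    samples_per_pop = samples_per_pop,
    n_sites = as.integer(n_sites),
    n_sites_t = as.integer(n_sites_t),
    fixed_diff_fraction = fixed_diff_fraction,
    fst_drift = fst_drift,
    clone_mutation_rate = clone_mutation_rate,
    region_extent_km = region_extent_km,
    ibd_strength = ibd_strength,
    mean_depth = mean_depth,
    error_rate = error_rate,
    missing_rate = missing_rate,
    ploidy_sp2 = ploidy_sp2,
    reference = reference,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      x$n_pops_sp1, "diploid (M/M) +", x$n_pops_sp2,
      paste0("hybrid (", gsub("(.)", "\\1/", x$ploidy_sp2), "\b) populations\n"))
  cat("  samples/pop:", paste(unique(x$samples_per_pop), collapse = "-"),
      " sites (M):", x$n_sites,
      if (x$reference == "Lj") paste(" sites (T):", x$n_sites_t) else "",
      "\n")
  cat("  Fst:", x$fst_drift, " fixed-diff:", x$fixed_diff_fraction,
      " depth:", x$mean_depth, " error:", x$error_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

# haplotype copy numbers implied by a species-2 composition string
ploidy_copies <- function(ploidy_sp2) {
  switch(ploidy_sp2,
         MMT = c(m = 2L, t = 1L),
         MTT = c(m = 1L, t = 2L),
         MT  = c(m = 1L, t = 1L),
         stop("unknown ploidy composition: ", ploidy_sp2))
}
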