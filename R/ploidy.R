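#' Alternative-allele-ratio spectrum of a sample
#'
#' At every heterozygous call (0/1) with depth at least `min_depth`, the
#' alternative read fraction `r = AD_alt / (AD_ref + AD_alt)` is
#' computed and histogrammed in bins of width 0.01 over (0, 1).  The
#' modal bin is located after smoothing the histogram with a 3-bin
#' moving average; bins are centred on exact percent values and filled
#' by linear binning so the theoretical dosage modes sit mid-bin and do
#' not alias against the discrete read-fraction support.  In a diploid the spectrum
#' peaks at 1/2; in a triploid hybrid carrying one (two) divergent
#' copies it peaks at 1/3 (2/3) - e.g. 15 alternative among 45 reads
#' gives a 1:2 ratio.
#'
#' Only heterozygous calls enter: homozygous calls contribute nothing
#' but sequencing-error noise to allele balance.  The default
#' `min_depth = 20` keeps the binomial spread of `r` (SD about 0.11 at
#' depth 20) from blurring the 1/3 vs 1/2 modes.
#'
#' @param table a `variant_table` with AD present.
#' @param sample sample name or column index.
#' @param min_depth minimum depth for a site to enter the spectrum.
#' @param min_sites informativeness threshold: below this many usable
#'   het sites the spectrum is flagged uninformative (with a warning).
#' @return An object of class `allele_ratio_spectrum`: bin `counts`
#'   (length 100), `bin_centers`, raw `ratios`, `n_sites`, smoothed
#'   `mode` (bin center) and `mode_height`, and `informative`.
#' @export
allele_ratio_spectrum <- function(table, sample, min_depth = 20,
                                  min_sites = 200) {
  stopifnot(inherits(table, "variant_table"))
  j <- if (is.character(sample)) match(sample, table$samples) else sample
  if (is.na(j) || j < 1 || j > length(table$samples)) {
    stop("unknown sample: ", sample)
  }
  tot <- table$ad_ref[, j] + table$ad_alt[, j]
  use <- !is.na(table$gt[, j]) & table$gt[, j] == 1L &
    table$dp[, j] >= min_depth & tot > 0
  r <- table$ad_alt[use, j] / tot[use]
  r <- r[r > 0 & r < 1]
  n <- length(r)
  # bins centred on exact percent values so the theoretical dosage modes
  # (33%, 50%, 67%) sit mid-bin; counts are accumulated by linear
  # binning (each observation split between the two nearest centres in
  # proportion to proximity), which suppresses the aliasing between the
  # percent grid and the discrete read-fraction support k/depth
  x <- r * 100
  k <- floor(x)
  w <- x - k
  idx <- pmin(pmax(c(k, k + 1L), 1L), 99L)
  inc <- c(1 - w, w)
  counts <- numeric(99)
  agg <- tapply(inc, idx, sum)
  counts[as.integer(names(agg))] <- agg
  smoothed <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  smoothed[is.na(smoothed)] <- 0
  mode_idx <- which.max(smoothed)
  informative <- n >= min_sites
  if (!informative) {
    warning("only ", n, " usable heterozygous sites (need ", min_sites,
            "); spectrum flagged uninformative")
  }
  structure(list(
    sample = table$samples[j], counts = counts,
    bin_centers = seq_len(99) / 100, ratios = r, n_sites = n,
    mode = if (n > 0) mode_idx / 100 else NA_real_,
    mode_height = if (n > 0) counts[mode_idx] else NA_real_,
    min_depth = min_depth, informative = informative
  ), class = "allele_ratio_spectrum")
}

#' @export
print.allele_ratio_spectrum <- function(x, ...) {
  cat("allele-ratio spectrum:", x$sample, "-", x$n_sites,
      "het sites, mode at", sprintf("%.1f%%", 100 * x$mode),
      if (!x$informative) "(uninformative)" else "", "\n")
  invisible(x)
}

# dosage windows: boundaries midway between adjacent theoretical modes,
# with extra allowance below 1/3 and above 2/3 because observed ratios
# tend to run slightly low/high of theory at finite depth
default_dosage_windows <- function() {
  list(TRIPLOID_MMT = c(0.28, 0.41),   # [lo, hi)
       DIPLOID_HET  = c(0.45, 0.55),   # [lo, hi]
       TRIPLOID_MTT = c(0.59, 0.72))   # (lo, hi]
}

#' Classify hybrid dosage from an allele-ratio spectrum
#'
#' Assigns the spectrum mode to one of three disjoint windows -
#' `[0.28, 0.41)` triploid with one divergent copy (M/M/T),
#' `[0.45, 0.55]` diploid heterozygote, `(0.59, 0.72]` triploid with two
#' divergent copies (M/T/T).  A mode outside every window, or two
#' windows holding nearly equal shares of the spectrum mass (within
#' `mass_margin` of each other), yields `AMBIGUOUS`; an uninformative
#' spectrum yields `UNINFORMATIVE`.
#'
#' @param spectrum an [allele_ratio_spectrum()].
#' @param windows named list of window bounds (see
#'   `default_dosage_windows`).
#' @param mass_margin minimum lead (as a fraction of het sites) the
#'   winning window must have over the runner-up.
#' @return An object of class `dosage_class`: `class` (one of
#'   `DIPLOID_HET`, `TRIPLOID_MMT`, `TRIPLOID_MTT`, `AMBIGUOUS`,
#'   `UNINFORMATIVE`), `confidence` (fraction of het sites inside the
#'   winning window), window `masses` and the `mode`.
#' @export
classify_hybrid_dosage <- function(spectrum,
                                   windows = default_dosage_windows(),
                                   mass_margin = 0.10) {
  stopifnot(inherits(spectrum, "allele_ratio_spectrum"))
  if (!spectrum$informative || spectrum$n_sites == 0) {
    return(structure(list(class = "UNINFORMATIVE", confidence = NA_real_,
                          masses = NULL, mode = spectrum$mode),
                     class = "dosage_class"))
  }
  r <- spectrum$ratios
  in_window <- function(w, x) {
    x >= w[1] & x <= w[2]
  }
  masses <- vapply(windows, function(w) mean(in_window(w, r)), numeric(1))
  mode <- spectrum$mode
  hit <- vapply(windows, function(w) in_window(w, mode), logical(1))
  cls <- if (!any(hit)) {
    "AMBIGUOUS"
  } else {
    names(windows)[which(hit)[1]]
  }
  srt <- sort(masses, decreasing = TRUE)
  if (length(srt) >= 2 && (srt[1] - srt[2]) < mass_margin) cls <- "AMBIGUOUS"
  conf <- if (cls %in% names(masses)) unname(masses[cls]) else NA_real_
  structure(list(class = cls, confidence = conf, masses = masses,
                 mode = mode),
            class = "dosage_class")
}

#' @export
print.dosage_class <- function(x, ...) {
  cat("dosage class:", x$class,
      if (!is.na(x$confidence)) {
        sprintf("(%.0f%% of het sites in window, mode %.2f)",
                100 * x$confidence, x$mode)
      } else "", "\n")
  invisible(x)
}

#' Sub-genome coverage summary and species/dosage call
#'
#' Mean read depth per sub-genome over all sites of a combined
#' (M + T) reference view, the M:T coverage ratio, and the fraction of
#' T-sub-genome sites with any coverage.  A sample with essentially no
#' T coverage is called pure M (diploid *L. minor*-like); otherwise the
#' coverage ratio calls the hybrid composition: near 2 means M/M/T,
#' near 1 means M/T, near 0.5 means M/T/T.
#'
#' @param table a `variant_table` whose contigs carry both `M` and `T`
#'   sub-genome tags.
#' @param sample sample name or index.
#' @param t_zero_frac threshold on the fraction of covered T sites below
#'   which the sample is called pure M.
#' @return List of class `subgenome_coverage`: mean depths, `ratio`,
#'   `frac_t_covered` and the composition `call` (`pure_M`, `MMT`,
#'   `MT`, `MTT` or `flagged`).
#' @export
subgenome_coverage <- function(table, sample, t_zero_frac = 0.05) {
  stopifnot(inherits(table, "variant_table"))
  j <- if (is.character(sample)) match(sample, table$samples) else sample
  if (is.na(j)) stop("unknown sample: ", sample)
  sg <- table$sites$subgenome
  for (need in c("M", "T")) {
    if (!any(sg %in% need)) stop("no sites tagged sub-genome ", need)
  }
  dp_m <- table$dp[sg %in% "M", j]
  dp_t <- table$dp[sg %in% "T", j]
  mean_m <- mean(dp_m)
  mean_t <- mean(dp_t)
  frac_t <- mean(dp_t > 0)
  ratio <- if (mean_t > 0) mean_m / mean_t else NA_real_
  call <- if (frac_t < t_zero_frac) {
    "pure_M"
  } else if (!is.na(ratio) && ratio >= 1.5 && ratio <= 2.5) {
    "MMT"
  } else if (!is.na(ratio) && ratio >= 0.75 && ratio <= 1 / 0.75) {
    "MT"
  } else if (!is.na(ratio) && ratio >= 0.4 && ratio <= 1 / 1.5) {
    "MTT"
  } else {
    "flagged"
  }
  structure(list(sample = table$samples[j], mean_depth_m = mean_m,
                 mean_depth_t = mean_t, ratio = ratio,
                 frac_t_covered = frac_t, call = call),
            class = "subgenome_coverage")
}

#' @export
print.subgenome_coverage <- function(x, ...) {
  cat(sprintf("sub-genome coverage %s: M %.1fx, T %.1fx (ratio %s, %.0f%% T sites covered) -> %s\n",
              x$sample, x$mean_depth_m, x$mean_depth_t,
              if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio),
              100 * x$frac_t_covered, x$call))
  invisible(x)
}

#' Per-sub-genome distances and their Mantel correlations
#'
#' Splits the SNPs by sub-genome tag (any tags present: M, T, plastid
#' partitions, ...), recomputes the pairwise allele-sharing distances
#' within each partition with at least `min_snps` sites, and reports the
#' Mantel correlation between every pair of partition-specific distance
#' matrices.  Concordant partitions (r near 1) are what is expected when
#' all divergence postdates a single hybridisation event.
#'
#' @param table a `variant_table` with sub-genome tags.
#' @param min_snps minimum SNPs for a partition to be used (smaller
#'   partitions are skipped with a warning).
#' @param nperm,seed passed to [mantel_test()].
#' @return List of class `subgenome_correlation`: `distances` (named
#'   list of matrices) and `correlations` (data frame sub_a, sub_b,
#'   n_snps_a, n_snps_b, r, p).
#' @export
subgenome_distance_correlation <- function(table, min_snps = 50,
                                           nperm = 999, seed = NULL) {
  stopifnot(inherits(table, "variant_table"))
  sg <- table$sites$subgenome
  tags <- unique(sg[!is.na(sg)])
  if (length(tags) < 2) stop("need at least 2 sub-genomes with tagged sites")
  dists <- list()
  for (tag in tags) {
    n_snp <- sum(sg %in% tag)
    if (n_snp < min_snps) {
      warning("partition ", tag, " has only ", n_snp,
              " SNPs (need ", min_snps, "); skipped")
      next
    }
    dists[[tag]] <- pairwise_allele_distance(
      subset_variant_table(table, sites = sg %in% tag))
  }
  if (length(dists) < 2) stop("fewer than 2 usable partitions")
  combos <- utils::combn(names(dists), 2)
  res <- data.frame(sub_a = combos[1, ], sub_b = combos[2, ],
                    r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combos))) {
    mt <- mantel_test(dists[[combos[1, i]]], dists[[combos[2, i]]],
                      nperm = nperm, seed = seed)
    res$r[i] <- mt$r
    res$p[i] <- mt$p
  }
  structure(list(distances = dists, correlations = res),
            class = "subgenome_correlation")
}
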