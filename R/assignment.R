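# Recode a 0/1/2 genotype vector under one of the three coding schemes
# used by the assignment scan: the full three-level factor, or the two
# collapsed two-level factors comparing one homozygous state to the rest.
code_genotype <- function(gt, scheme = c("FACTOR_A", "FACTOR_B", "THREE_LEVEL")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         THREE_LEVEL = gt,
         FACTOR_A = as.integer(gt != 0L),  # 0/0 vs {0/1, 1/1}
         FACTOR_B = as.integer(gt == 2L))  # 1/1 vs {0/1, 0/0}
}

# x * log(y) with the 0 * log(0) = 0 convention
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Quasibinomial GLM of group membership on a genotype factor
#'
#' Fits the logistic-link model `group ~ genotype` (binary response =
#' membership in the second group; categorical predictor) and returns
#' the percent of null deviance explained, the quasibinomial F statistic
#' `F = ((D_null - D_res) / ddf) / phi` with `phi` the Pearson dispersion
#' of the fitted model, and the F-test p-value.  Because the predictor
#' is categorical the MLE has a closed form (fitted probability = group
#' mean within each genotype class), which is what this function
#' computes; `stats::glm(family = quasibinomial)` gives identical
#' deviances.
#'
#' Perfect separation (residual deviance below `eps`) is reported with
#' `pct_dev = 100` and `separated = TRUE`; the p-value is then computed
#' with the deviance and dispersion floored at `eps`, which drives p to
#' the numerical floor.  Downstream filtering on `pct_dev` alone (the
#' 80% rule) is unaffected by this choice.
#'
#' @param groups factor (or vector) with exactly two levels among the
#'   non-missing genotypes.
#' @param genotype genotype factor (any coding); `NA`s are dropped
#'   together with the matching group entries.
#' @param eps separation floor for deviance and dispersion.
#' @return List with `pct_dev`, `f_stat`, `p`, `separated`, `df` (model,
#'   residual) and the two deviances.
#' @examples
#' fit_snp_glm(rep(c("a", "b"), each = 4),
#'             c(0, 0, 0, 1, 1, 2, 2, 2))
#' @export
fit_snp_glm <- function(groups, genotype, eps = 1e-8) {
  ok <- !is.na(genotype) & !is.na(groups)
  g <- factor(genotype[ok])
  grp <- factor(groups[ok])
  if (nlevels(grp) != 2) stop("need exactly two groups among non-missing data")
  if (nlevels(g) < 2) stop("genotype factor has a single observed level")
  y <- as.integer(grp == levels(grp)[2])
  n <- length(y)
  p_cell <- tapply(y, g, mean)
  p_hat <- p_cell[as.integer(g)]
  d_res <- -2 * sum(xlogy(y, p_hat) + xlogy(1 - y, 1 - p_hat))
  p_bar <- mean(y)
  d_null <- -2 * sum(xlogy(y, p_bar) + xlogy(1 - y, 1 - p_bar))
  ddf <- nlevels(g) - 1
  rdf <- n - nlevels(g)
  if (rdf < 1) stop("no residual degrees of freedom")
  denom <- p_hat * (1 - p_hat)
  pearson <- ifelse(denom > 0, (y - p_hat)^2 / denom, 0)
  phi <- sum(pearson) / rdf
  separated <- d_res < eps
  pct_dev <- if (separated) 100 else 100 * (d_null - d_res) / d_null
  d_res_eff <- max(d_res, eps)
  phi_eff <- max(phi, eps)
  f_stat <- ((d_null - d_res_eff) / ddf) / phi_eff
  p <- pf(f_stat, ddf, rdf, lower.tail = FALSE)
  list(pct_dev = pct_dev, f_stat = f_stat, p = p, separated = separated,
       df = c(model = ddf, residual = rdf),
       d_null = d_null, d_res = d_res)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement; `NA`/`NaN`
#' p-values are excluded from the ranking and propagated unchanged.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of FDR values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Per-SNP scan for species assignment markers
#'
#' For every site, fits the quasibinomial GLM under all three genotype
#' codings (three-level; 0/0 vs rest; 1/1 vs rest), keeps the coding
#' with the highest percent deviance explained (ties favour the
#' two-level codings, A before B), enters one p-value per site into a
#' single Benjamini-Hochberg correction, and flags sites with
#' `FDR < fdr_thresh` and `pct_dev >= dev_thresh` as assignment markers.
#' Significant sites are further classed by the modal genotypes of the
#' two groups: `hom_vs_hom` (fixed difference), `hom_vs_het`, or
#' `other`.
#'
#' @param table a filtered `variant_table`.
#' @param groups two-level factor/vector over all samples (e.g. species).
#' @param fdr_thresh,dev_thresh significance thresholds (defaults 0.05
#'   and 80; the deviance threshold is inclusive).
#' @param min_per_group minimum non-missing samples required in each
#'   group for a site to be tested.
#' @return An object of class `assignment_scan`: `table` (one row per
#'   site with best coding, pct_dev, F, p, fdr, significance, difference
#'   class and separation flag) and `summary` (counts, fraction
#'   significant, difference-class split among significant sites).
#' @export
scan_assignment_markers <- function(table, groups, fdr_thresh = 0.05,
                                    dev_thresh = 80, min_per_group = 3) {
  stopifnot(inherits(table, "variant_table"))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != length(table$samples)) {
    stop("need one group label per sample")
  }
  if (any(table(groups) == 0)) stop("each group needs at least one sample")
  n_sites <- nrow(table$sites)
  schemes <- c("FACTOR_A", "FACTOR_B", "THREE_LEVEL")
  best_coding <- rep(NA_character_, n_sites)
  pct_dev <- f_stat <- pval <- rep(NA_real_, n_sites)
  separated <- rep(NA, n_sites)
  diff_class <- rep(NA_character_, n_sites)
  skip_reason <- rep(NA_character_, n_sites)

  for (s in seq_len(n_sites)) {
    gt <- table$gt[s, ]
    ok <- !is.na(gt)
    if (min(table(groups[ok])[levels(groups)], na.rm = FALSE) < min_per_group ||
        anyNA(table(groups[ok])[levels(groups)])) {
      skip_reason[s] <- "too_few_per_group"
      next
    }
    best <- NULL
    for (sc in schemes) {
      coded <- code_genotype(gt, sc)
      if (length(unique(coded[ok])) < 2) next
      fit <- fit_snp_glm(groups, coded)
      if (is.null(best) || fit$pct_dev > best$pct_dev + 1e-9) {
        best <- fit
        best$coding <- sc
      }
    }
    if (is.null(best)) {
      skip_reason[s] <- "single_genotype_level"
      next
    }
    best_coding[s] <- best$coding
    pct_dev[s] <- best$pct_dev
    f_stat[s] <- best$f_stat
    pval[s] <- best$p
    separated[s] <- best$separated
    # modal genotype per group (original three-level codes)
    modal <- vapply(levels(groups), function(lv) {
      x <- gt[ok & groups == lv]
      as.integer(names(which.max(table(x))))
    }, integer(1))
    diff_class[s] <- if (all(modal %in% c(0L, 2L)) && modal[1] != modal[2]) {
      "hom_vs_hom"
    } else if (any(modal %in% c(0L, 2L)) && any(modal == 1L)) {
      "hom_vs_het"
    } else {
      "other"
    }
  }
  fdr <- bh_fdr(pval)
  significant <- !is.na(fdr) & fdr < fdr_thresh & pct_dev >= dev_thresh
  res <- data.frame(
    contig = table$sites$contig, pos = table$sites$pos,
    best_coding = best_coding, pct_dev = pct_dev, f_stat = f_stat,
    p = pval, fdr = fdr, significant = significant,
    diff_class = diff_class, separated = separated,
    skip_reason = skip_reason, stringsAsFactors = FALSE
  )
  tested <- !is.na(pval)
  if (!any(tested)) warning("no site could be tested")
  sig_classes <- table(factor(diff_class[significant],
                              levels = c("hom_vs_hom", "hom_vs_het", "other")))
  summary <- list(
    n_sites = n_sites,
    n_tested = sum(tested),
    n_skipped = sum(!tested),
    n_significant = sum(significant),
    frac_significant = if (any(tested)) sum(significant) / sum(tested) else NA,
    class_split = as.list(sig_classes / max(1, sum(significant))),
    fdr_thresh = fdr_thresh, dev_thresh = dev_thresh
  )
  structure(list(table = res, summary = summary), class = "assignment_scan")
}

#' @export
print.assignment_scan <- function(x, ...) {
  s <- x$summary
  cat("assignment scan:", s$n_tested, "of", s$n_sites, "sites tested;",
      s$n_significant,
      sprintf("significant (%.2f%%) at FDR < %g & %%-DEV >= %g\n",
              100 * s$frac_significant, s$fdr_thresh, s$dev_thresh))
  if (s$n_significant > 0) {
    cat(sprintf("  difference classes: hom-vs-hom %.1f%%, hom-vs-het %.1f%%, other %.1f%%\n",
                100 * s$class_split$hom_vs_hom, 100 * s$class_split$hom_vs_het,
                100 * s$class_split$other))
  }
  invisible(x)
}
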