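# Principal-coordinates embedding of a distance matrix (Gower double
# centering of -D^2/2).  Axes with negative eigenvalues are kept
# separately: squared distances computed on them enter with a minus
# sign (the standard correction for non-Euclidean dissimilarities).
pcoa_embed <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  lim <- tol * max(abs(e$values), 1e-300)
  pos <- e$values > lim
  neg <- e$values < -lim
  list(
    pos = e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos)),
    neg = e$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-e$values[neg]), sum(neg)),
    ids = rownames(d)
  )
}

# distances to group centroids in a PCoA embedding; squared real-axis
# deviation minus squared imaginary-axis deviation, floored at 0
centroid_distances <- function(embed, groups) {
  groups <- factor(groups)
  z2 <- numeric(length(groups))
  for (lv in levels(groups)) {
    sel <- groups == lv
    cp <- colMeans(embed$pos[sel, , drop = FALSE])
    cn <- colMeans(embed$neg[sel, , drop = FALSE])
    dp <- sweep(embed$pos[sel, , drop = FALSE], 2, cp)
    dn <- sweep(embed$neg[sel, , drop = FALSE], 2, cn)
    z2[sel] <- rowSums(dp^2) - rowSums(dn^2)
  }
  sqrt(pmax(z2, 0))
}

#' Distances to group centroids (multivariate dispersion)
#'
#' Embeds the distance matrix by principal coordinates (double centering
#' of `-D^2 / 2`) and returns each sample's distance to its group
#' centroid, with the usual negative-eigenvalue correction: squared
#' deviations on negative-eigenvalue axes are subtracted and the result
#' floored at zero before the square root.  With a single group this
#' yields distances to the overall centroid.
#'
#' @param d symmetric distance matrix (n >= 3).
#' @param groups group labels (one per sample); defaults to one group.
#' @return Named numeric vector of centroid distances.
#' @export
distances_to_centroid <- function(d, groups = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("need one group label per sample")
  embed <- pcoa_embed(d)
  z <- centroid_distances(embed, groups)
  names(z) <- rownames(d)
  z
}

# one-way ANOVA F statistic on a numeric response
oneway_f <- function(z, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(z)
  gm <- tapply(z, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(groups)])^2)
  ((ssb / (k - 1)) / (ssw / (n - k)))
}

#' Permutation test for homogeneity of multivariate dispersion
#'
#' Computes each sample's distance to its group centroid (see
#' [distances_to_centroid()]), the one-way ANOVA F statistic over those
#' distances, and a permutation p-value obtained by permuting the group
#' labels `nperm` times and recomputing the centroid distances and F in
#' the fixed embedding, with the observed-included convention
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + nperm)`.
#'
#' @param d symmetric distance matrix.
#' @param groups group labels; at least 2 groups of at least 2 samples.
#' @param nperm number of permutations (default 9999).
#' @param seed integer seed for reproducibility.
#' @return List of class `dispersion_test`: `f_stat`, `p`,
#'   `group_means` (mean dispersion per group), `distances`, `nperm`,
#'   `seed`.
#' @export
dispersion_test <- function(d, groups, nperm = 9999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2)) stop("every group needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  embed <- pcoa_embed(d)
  z <- centroid_distances(embed, groups)
  f_obs <- oneway_f(z, groups)
  exceed <- 0L
  for (b in seq_len(nperm)) {
    gp <- sample(groups)
    zp <- centroid_distances(embed, gp)
    if (oneway_f(zp, gp) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(
    f_stat = f_obs, p = (1 + exceed) / (1 + nperm),
    group_means = tapply(z, groups, mean), distances = z,
    nperm = nperm, seed = seed
  ), class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("dispersion test: F = %.3f, p = %.4g (%d permutations)\n",
              x$f_stat, x$p, x$nperm))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the corresponding off-diagonal upper
#' triangles; the null distribution comes from jointly permuting rows
#' and columns of the second matrix.  One-sided (upper) p-value with the
#' observed-included convention `p = (1 + #\{r_perm >= r_obs\}) /
#' (1 + nperm)`, so with 9999 permutations the smallest attainable p is
#' exactly 0.0001.
#'
#' @param d1,d2 symmetric distance matrices over the same samples in the
#'   same order.
#' @param nperm number of permutations (default 9999).
#' @param seed integer seed.
#' @return List of class `mantel_result`: `r`, `p`, `nperm`, `seed`.
#' @export
mantel_test <- function(d1, d2, nperm = 9999, seed = NULL) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices must match in size")
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (sd(v1) == 0 || sd(d2[ut]) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- cor(v1, d2[ut])
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nperm)) {
    p <- sample.int(n)
    dp <- d2[p, p]
    if (cor(v1, dp[ut]) >= r_obs) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + nperm),
                 nperm = nperm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$nperm))
  invisible(x)
}

#' Within- and between-group distance summary
#'
#' Mean pairwise distance within groups (overall and per group) and
#' between groups, using only groups with at least `min_size` samples
#' and only off-diagonal entries.
#'
#' @param d symmetric distance matrix.
#' @param groups group labels per sample.
#' @param min_size minimum group size for a group to be retained
#'   (default 3).
#' @return List of class `group_distance_summary`: `within_mean`,
#'   `between_mean` (NA with a flag when fewer than 2 groups survive),
#'   `per_group` means, pair counts and retained group names.
#' @export
within_between_summary <- function(d, groups, min_size = 3) {
  d <- as.matrix(d)
  if (length(groups) != nrow(d)) stop("need one group label per sample")
  groups <- as.character(groups)
  sizes <- table(groups)
  retained <- names(sizes)[sizes >= min_size]
  keep <- groups %in% retained
  d <- d[keep, keep, drop = FALSE]
  g <- groups[keep]
  same <- outer(g, g, "==")
  ut <- upper.tri(d)
  within_vals <- d[ut & same]
  between_vals <- d[ut & !same]
  per_group <- vapply(retained, function(lv) {
    sel <- g == lv
    mean(d[sel, sel][upper.tri(d[sel, sel])])
  }, numeric(1))
  structure(list(
    within_mean = if (length(within_vals)) mean(within_vals) else NA_real_,
    between_mean = if (length(between_vals)) mean(between_vals) else NA_real_,
    between_defined = length(retained) >= 2,
    per_group = per_group,
    n_within_pairs = length(within_vals),
    n_between_pairs = length(between_vals),
    groups_used = retained
  ), class = "group_distance_summary")
}

#' @export
print.group_distance_summary <- function(x, ...) {
  cat(sprintf("group distances: within %.4f (%d pairs), between %s (%d pairs), %d groups\n",
              x$within_mean, x$n_within_pairs,
              if (x$between_defined) sprintf("%.4f", x$between_mean) else "NA",
              x$n_between_pairs, length(x$groups_used)))
  invisible(x)
}

#' Great-circle distance matrix from sample coordinates
#'
#' Haversine distances in meters on a sphere of radius 6,371,000 m.
#' Latitudes outside [-90, 90] fail loudly: coordinate typos (a
#' latitude of 7.4 for a Swiss pond, say) would otherwise silently
#' wreck every isolation-by-distance statistic downstream.
#'
#' @param metadata data frame with columns `lat`, `lon` in decimal
#'   degrees, and optionally `sample` for the dimnames.
#' @return Symmetric matrix of distances in meters.
#' @export
geo_distance_matrix <- function(metadata) {
  lat <- metadata$lat
  lon <- metadata$lon
  if (is.null(lat) || is.null(lon)) stop("metadata needs lat and lon columns")
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite coordinates")
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude outside [-90, 90]: check the metadata for ",
         "transposed or truncated coordinates")
  }
  r_earth <- 6371000
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  h <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  d <- 2 * r_earth * asin(pmin(sqrt(h), 1))
  ids <- if (!is.null(metadata$sample)) metadata$sample else rownames(metadata)
  dimnames(d) <- list(ids, ids)
  d
}

#' Isolation-by-distance test
#'
#' Physical distances in meters (haversine), floored at `floor_m` to
#' protect the log of within-pond zeros, then log10-transformed.  The
#' genetic distance matrix is tested against the log-physical matrix
#' with a Mantel test, and additionally with an ordinary least-squares
#' fit of genetic on log-physical pair distances (ANOVA F and Pearson
#' r) - noting that pairs are not independent, so the regression p is
#' descriptive.
#'
#' @param d_gen genetic distance matrix (samples in metadata order).
#' @param metadata data frame with `lat`/`lon` (and `sample`).
#' @param nperm,seed Mantel permutation settings.
#' @param floor_m floor for physical distances before log10 (meters).
#' @param exclude_within if `TRUE`, pairs at zero raw physical distance
#'   (same pond) are excluded from the regression (the Mantel test
#'   always uses the full floored matrix).
#' @return List of class `ibd_result`: `mantel` (a `mantel_result`),
#'   `anova_f`, `anova_p`, `pearson_r`, `n_pairs`.
#' @export
ibd_test <- function(d_gen, metadata, nperm = 9999, seed = NULL,
                     floor_m = 1, exclude_within = FALSE) {
  d_gen <- as.matrix(d_gen)
  d_geo <- geo_distance_matrix(metadata)
  if (!all(dim(d_gen) == dim(d_geo))) {
    stop("genetic matrix and metadata disagree on sample count")
  }
  if (all(d_geo[upper.tri(d_geo)] == 0)) {
    stop("all samples co-located: no physical distance variation")
  }
  d_log <- log10(pmax(d_geo, floor_m))
  mt <- mantel_test(d_gen, d_log, nperm = nperm, seed = seed)
  ut <- upper.tri(d_gen)
  gen_v <- d_gen[ut]
  log_v <- d_log[ut]
  if (exclude_within) {
    keep <- d_geo[ut] > 0
    gen_v <- gen_v[keep]
    log_v <- log_v[keep]
  }
  fit <- lm(gen_v ~ log_v)
  av <- anova(fit)
  structure(list(
    mantel = mt, anova_f = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
    pearson_r = cor(gen_v, log_v), n_pairs = length(gen_v)
  ), class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf("IBD: Mantel r = %.3f (p = %.4g), Pearson r = %.3f, ANOVA F = %.2f (p = %.3g), %d pairs\n",
              x$mantel$r, x$mantel$p, x$pearson_r, x$anova_f, x$anova_p,
              x$n_pairs))
  invisible(x)
}
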