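#' Pairwise allele-sharing genetic distance
#'
#' For each pair of samples, over the sites where both genotype calls
#' are present, the per-site mismatch is `|dosage_i - dosage_j| / 2`
#' with dosage(0/0) = 0, dosage(0/1) = 1, dosage(1/1) = 2, and the
#' distance is the mean mismatch - i.e. the fraction of alleles that
#' differ between the two individuals, ignoring sites with pairwise
#' missing data.  Heterozygote vs heterozygote counts as 0 (identical
#' unphased dosage).
#'
#' @param x a `variant_table` or an integer genotype matrix
#'   (sites x samples, codes 0/1/2/NA).
#' @return A symmetric numeric matrix with zero diagonal and sample IDs
#'   as dimnames; the per-pair count of sites used is attached as
#'   attribute `"n_shared"`.  Pairs with zero shared sites get `NA` and
#'   a warning.
#' @examples
#' gt <- cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 0L))
#' pairwise_allele_distance(gt)
#' @export
pairwise_allele_distance <- function(x) {
  gt <- if (inherits(x, "variant_table")) x$gt else as.matrix(x)
  n <- ncol(gt)
  if (n < 2) stop("need at least 2 samples")
  if (nrow(gt) < 1) stop("need at least 1 site")
  ids <- colnames(gt)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(nrow(gt), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(gt[, i]) & !is.na(gt[, j])
      k <- sum(ok)
      ns[i, j] <- ns[j, i] <- k
      d[i, j] <- d[j, i] <-
        if (k > 0) mean(abs(gt[ok, i] - gt[ok, j])) / 2 else NA_real_
    }
  }
  diag(ns) <- colSums(!is.na(gt))
  if (anyNA(d)) {
    warning("some sample pairs share no called sites; distances set to NA")
  }
  attr(d, "n_shared") <- ns
  d
}

#' Convert a kinship matrix to a distance matrix
#'
#' `D = 1 - K` elementwise; the diagonal is forced to zero and negative
#' entries are floored at zero with a warning (their count is attached
#' as attribute `"n_floored"`).
#'
#' @param k square symmetric kinship matrix.
#' @return A distance matrix of the same dimension.
#' @export
kinship_to_distance <- function(k) {
  k <- as.matrix(k)
  if (nrow(k) != ncol(k)) stop("kinship matrix must be square")
  if (max(abs(k - t(k)), na.rm = TRUE) > 1e-8) {
    stop("kinship matrix must be symmetric")
  }
  d <- 1 - k
  diag(d) <- 0
  n_neg <- sum(d < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " negative distance entries floored at 0")
    d[d < 0] <- 0
  }
  attr(d, "n_floored") <- n_neg
  d
}

#' Agglomerative clustering of samples from a distance matrix
#'
#' Average-linkage (UPGMA-style, configurable) hierarchical clustering,
#' reported as a newick string with branch lengths, plus a flat grouping
#' cut either at a height threshold or into `k` groups.
#'
#' @param d symmetric distance matrix (no missing values).
#' @param method linkage passed to [stats::hclust()].
#' @param h,k cut height or number of groups for the flat grouping
#'   (height 0.15 by default when neither is given).
#' @return A list with elements `hclust`, `newick` and `groups` (named
#'   integer vector).
#' @export
cluster_samples <- function(d, method = "average", h = NULL, k = NULL) {
  d <- as.matrix(d)
  if (anyNA(d)) {
    stop("distance matrix has missing pairs; impute or drop low-overlap ",
         "samples before clustering")
  }
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (n == 1) {
    return(list(hclust = NULL, newick = paste0(ids, ";"),
                groups = setNames(1L, ids)))
  }
  hc <- hclust(as.dist(d), method = method)
  newick <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(h) && is.null(k)) h <- 0.15
  groups <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  list(hclust = hc, newick = newick, groups = groups)
}

#' Write / read a square distance matrix as TSV
#'
#' @param d distance matrix with sample IDs as dimnames.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_tsv <- function(d, path) {
  out <- data.frame(sample = rownames(d), as.data.frame(d),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}
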