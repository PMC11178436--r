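# reverse-complement a character vector of k-mers
revcomp_kmers <- function(kmers) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
}

#' Count canonical k-mers in a set of sequences
#'
#' Slides a window of odd length `k` (default 31, the usual choice for
#' reference-free kinship) over every sequence, canonicalises each
#' k-mer to the lexicographic minimum of itself and its reverse
#' complement, drops windows containing non-ACGT characters, and retains
#' k-mers seen at least `min_count` times (the count threshold removes
#' one-off sequencing-error k-mers).
#'
#' @param sequences character vector (or `Biostrings::DNAStringSet`) of
#'   sequences over A/C/G/T/N.
#' @param k odd k-mer size; even `k` is an error because canonical form
#'   would be ambiguous for palindromes.
#' @param min_count minimum total count for a k-mer to enter the profile.
#' @param sample_id identifier stored in the profile.
#' @return An object of class `kmer_profile`: list with `sample`, `k`,
#'   and `counts` (named integer vector over canonical k-mers).
#' @examples
#' count_canonical_kmers("ACGTACGT", k = 3, min_count = 1)
#' @export
count_canonical_kmers <- function(sequences, k = 31, min_count = 2,
                                  sample_id = "sample") {
  if (k %% 2 == 0) stop("k must be odd (even k makes canonical form ambiguous)")
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  sequences <- toupper(sequences)
  all_kmers <- character(0)
  for (s in sequences) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1)
    all_kmers <- c(all_kmers, substring(s, starts, starts + k - 1))
  }
  if (length(all_kmers)) {
    all_kmers <- all_kmers[!grepl("[^ACGT]", all_kmers)]
  }
  if (length(all_kmers) == 0) {
    return(structure(list(sample = sample_id, k = k,
                          counts = setNames(integer(0), character(0))),
                     class = "kmer_profile"))
  }
  rc <- revcomp_kmers(all_kmers)
  canon <- ifelse(all_kmers <= rc, all_kmers, rc)
  tab <- table(canon)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[counts >= min_count]
  structure(list(sample = sample_id, k = k, counts = counts),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("kmer_profile:", x$sample, "-", length(x$counts),
      paste0("canonical ", x$k, "-mers\n"))
  invisible(x)
}

#' Presence/absence k-mer kinship matrix
#'
#' A documented simplification of pipeline-style k-mer kinship: over the
#' union of the samples' canonical k-mers, k-mers present in fewer than
#' `min_samples` or more than `max_samples` samples are removed
#' (monomorphic patterns carry no relatedness information), and
#' `K[i, j]` is the fraction of retained k-mers whose presence state
#' agrees between samples `i` and `j`.  Feed the result to
#' [kinship_to_distance()] for `D = 1 - K`.
#'
#' @param profiles list of `kmer_profile` objects (>= 2).
#' @param min_samples,max_samples presence filter bounds; defaults 2 and
#'   `n - 1`.
#' @return Symmetric kinship matrix in `[0, 1]` with unit diagonal;
#'   the number of retained k-mers is attached as attribute `"n_kmers"`.
#' @export
kmer_kinship <- function(profiles, min_samples = 2,
                         max_samples = length(profiles) - 1) {
  n <- length(profiles)
  if (n < 2) stop("need at least 2 k-mer profiles")
  ids <- vapply(profiles, function(p) p$sample, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  kmer_sets <- lapply(profiles, function(p) names(p$counts))
  universe <- unique(unlist(kmer_sets))
  pres <- vapply(kmer_sets, function(s) universe %in% s,
                 logical(length(universe)))
  pres <- matrix(pres, nrow = length(universe), ncol = n)
  n_present <- rowSums(pres)
  keep <- n_present >= min_samples & n_present <= max_samples
  if (!any(keep)) stop("no k-mer passes the presence filter")
  pres <- pres[keep, , drop = FALSE]
  kin <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      kin[i, j] <- kin[j, i] <- mean(pres[, i] == pres[, j])
    }
  }
  attr(kin, "n_kmers") <- sum(keep)
  kin
}

#' Read sequences for the k-mer path
#'
#' Thin wrapper over Biostrings readers accepting FASTA or FASTQ
#' (optionally gzipped).
#'
#' @param path sequence file.
#' @param format `"fasta"` or `"fastq"`; guessed from the extension by
#'   default.
#' @return Character vector of sequences.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  x <- if (format == "fastq") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  as.character(x)
}
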