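# Internal constructor for the central genotype container.  A
# variant_table holds biallelic SNP sites (rows) by samples (columns):
# genotype codes 0/1/2/NA (= 0/0, 0/1, 1/1, ./.), allele depths, total
# depth, site QUAL and an optional sub-genome tag per contig.
new_variant_table <- function(sites, gt, ad_ref, ad_alt, dp, samples) {
  stopifnot(nrow(sites) == nrow(gt), ncol(gt) == length(samples),
            all(dim(gt) == dim(dp)), all(dim(gt) == dim(ad_ref)),
            all(dim(gt) == dim(ad_alt)))
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt,
                 dp = dp, samples = samples),
            class = "variant_table")
}

#' Build a variant table from a bare genotype matrix
#'
#' Convenience constructor for genotype-level analyses (e.g. scans on
#' perfect-caller calls from [calls_from_truth()]): sites get synthetic
#' positions, QUAL 99 and, unless supplied, zero depth fields.
#'
#' @param gt integer genotype matrix (sites x samples, codes 0/1/2/NA)
#'   with sample IDs as column names.
#' @param ad_ref,ad_alt,dp optional matching depth matrices.
#' @param contig contig name for all sites.
#' @param subgenome sub-genome tag for all sites.
#' @return A `variant_table`.
#' @export
as_variant_table <- function(gt, ad_ref = NULL, ad_alt = NULL, dp = NULL,
                             contig = "chr1", subgenome = NA_character_) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  n <- nrow(gt)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gt)))
  colnames(gt) <- samples
  zero <- matrix(0L, n, ncol(gt), dimnames = list(NULL, samples))
  sites <- data.frame(contig = contig, pos = 100L * seq_len(n),
                      ref = "A", alt = "T", qual = 99,
                      subgenome = subgenome, stringsAsFactors = FALSE)
  new_variant_table(sites, gt,
                    if (is.null(ad_ref)) zero else ad_ref,
                    if (is.null(ad_alt)) zero else ad_alt,
                    if (is.null(dp)) zero else dp,
                    samples)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "biallelic SNPs x",
      length(x$samples), "samples\n")
  sg <- unique(x$sites$subgenome)
  if (any(!is.na(sg))) cat("  sub-genomes:", paste(sg, collapse = ", "), "\n")
  cat("  missing genotypes:",
      sprintf("%.1f%%", 100 * mean(is.na(x$gt))), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a variant table by sites and/or samples
#'
#' @param table a `variant_table`.
#' @param sites logical or integer index over rows (sites).
#' @param samples logical/integer/character index over samples.
#' @return A `variant_table`.
#' @export
subset_variant_table <- function(table, sites = NULL, samples = NULL) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(sites)) sites <- seq_len(nrow(table$sites))
  if (is.null(samples)) samples <- seq_along(table$samples)
  if (is.character(samples)) samples <- match(samples, table$samples)
  new_variant_table(
    table$sites[sites, , drop = FALSE],
    table$gt[sites, samples, drop = FALSE],
    table$ad_ref[sites, samples, drop = FALSE],
    table$ad_alt[sites, samples, drop = FALSE],
    table$dp[sites, samples, drop = FALSE],
    table$samples[samples]
  )
}

#' Write a variant table as plain-text VCF 4.2
#'
#' Emits GT:AD:DP per sample and site QUAL; contigs carry their
#' sub-genome tag as a `SUBGENOME` key in the `##contig` header lines.
#' Output formatting is fully deterministic, so identical tables produce
#' byte-identical files.
#'
#' @param table a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  sites <- table$sites
  contigs <- unique(sites$contig)
  contig_len <- vapply(contigs, function(ctg) {
    max(sites$pos[sites$contig == ctg]) + 1000L
  }, integer(1))
  contig_sg <- vapply(contigs, function(ctg) {
    sg <- unique(sites$subgenome[sites$contig == ctg])
    if (length(sg) != 1 || is.na(sg[1])) "." else as.character(sg[1])
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lemnapop",
    sprintf("##contig=<ID=%s,length=%d,SUBGENOME=%s>",
            contigs, contig_len, contig_sg),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  gt_str <- matrix("./.", nrow(table$gt), ncol(table$gt))
  ok <- !is.na(table$gt)
  gt_str[ok] <- c("0/0", "0/1", "1/1")[table$gt[ok] + 1L]
  fields <- matrix(paste0(gt_str, ":", table$ad_ref, ",", table$ad_alt,
                          ":", table$dp),
                   nrow(table$gt), ncol(table$gt))
  body <- paste(
    sites$contig, sites$pos, ".", sites$ref, sites$alt,
    formatC(sites$qual, digits = 6, format = "g"), "PASS", ".", "GT:AD:DP",
    apply(fields, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x with per-sample GT (AD and DP optional; without them
#' the depth-dependent operations are unavailable).  Multi-allelic and
#' non-SNP records are skipped and counted; sub-genome tags are read
#' from `SUBGENOME=` keys on `##contig` header lines when present.
#'
#' @param path a VCF file (plain text or bgzipped).
#' @return A `variant_table`; the number of skipped records is attached
#'   as attribute `"n_skipped"` and reported via a message.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has no sample columns: ", path)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF has no variant records: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " multi-allelic or non-SNP record(s)")
  }
  v <- v[snp, ]
  fix <- vcfR::getFIX(v)

  # sub-genome tags from ##contig lines
  meta <- v@meta
  contig_lines <- grep("^##contig=", meta, value = TRUE)
  sg_map <- c()
  for (line in contig_lines) {
    id <- sub(".*[<,]ID=([^,>]+).*", "\\1", line)
    sg <- if (grepl("SUBGENOME=", line)) {
      sub(".*SUBGENOME=([^,>]+).*", "\\1", line)
    } else {
      NA_character_
    }
    sg_map[id] <- sg
  }
  subgenome <- unname(sg_map[fix[, "CHROM"]])
  if (length(subgenome) == 0) subgenome <- rep(NA_character_, nrow(fix))
  subgenome[subgenome == "."] <- NA_character_

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  norm <- gsub("\\|", "/", gt_raw)
  code[norm == "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm == "1/1"] <- 2L

  fmt <- strsplit(v@gt[1, "FORMAT"], ":")[[1]]
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- apply(ad, 2, function(x) {
      as.integer(vapply(strsplit(x, ","), function(p) p[1], "NA"))
    })
    ad_alt <- apply(ad, 2, function(x) {
      as.integer(vapply(strsplit(x, ","), function(p) {
        if (length(p) >= 2) p[2] else NA_character_
      }, "NA"))
    })
    ad_ref[is.na(ad_ref)] <- 0L
    ad_alt[is.na(ad_alt)] <- 0L
  } else {
    ad_ref <- ad_alt <- matrix(0L, nrow(code), ncol(code))
  }
  if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    storage.mode(dp) <- "integer"
    dp[is.na(dp)] <- 0L
  } else {
    dp <- ad_ref + ad_alt
  }
  sites <- data.frame(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    subgenome = subgenome, stringsAsFactors = FALSE
  )
  samples <- colnames(gt_raw)
  dimnames(code) <- dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(dp) <-
    list(NULL, samples)
  out <- new_variant_table(sites, code, ad_ref, ad_alt, dp, samples)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Apply the cohort site filters
#'
#' Keeps sites with `QUAL >= qual_min` and with depth between `dp_min`
#' and `dp_max` (inclusive) in at least `ceiling(completeness *
#' n_samples)` samples - the standard filter for these cohorts (quality
#' 20; coverage between 10 and 1000 in at least 80% of samples).  No
#' sample is ever dropped, and the filter is idempotent.
#'
#' @param table a `variant_table` with DP available.
#' @param qual_min minimum site QUAL (inclusive).
#' @param dp_min,dp_max inclusive per-sample depth bounds.
#' @param completeness required fraction of samples in depth range, in
#'   `(0, 1]`; the count threshold is rounded up.
#' @param coverage_from `"DP"` (default) or `"AD"` (sum of allele depths)
#'   as the per-sample coverage source.
#' @return The filtered `variant_table`, with per-rule rejection counts
#'   in attribute `"filter_counts"`.
#' @export
filter_variants <- function(table, qual_min = 20, dp_min = 10, dp_max = 1000,
                            completeness = 0.8,
                            coverage_from = c("DP", "AD")) {
  stopifnot(inherits(table, "variant_table"))
  coverage_from <- match.arg(coverage_from)
  if (!(completeness > 0 && completeness <= 1)) {
    stop("completeness must be in (0, 1]")
  }
  cov <- if (coverage_from == "DP") table$dp else table$ad_ref + table$ad_alt
  n_samples <- length(table$samples)
  need <- ceiling(completeness * n_samples)
  in_range <- cov >= dp_min & cov <= dp_max
  in_range[is.na(in_range)] <- FALSE
  pass_cov <- rowSums(in_range) >= need
  pass_qual <- !is.na(table$sites$qual) & table$sites$qual >= qual_min
  keep <- pass_qual & pass_cov
  out <- subset_variant_table(table, sites = keep)
  attr(out, "filter_counts") <- c(
    input = nrow(table$sites),
    fail_qual = sum(!pass_qual),
    fail_coverage = sum(!pass_cov),
    kept = sum(keep)
  )
  out
}

#' Write a cohort (VCF + metadata + truth) to disk
#'
#' @param table a `variant_table`.
#' @param truth a `cohort_truth`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_cohort <- function(table, truth, dir) {
  stopifnot(inherits(table, "variant_table"), inherits(truth, "cohort_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv")
  )
  write_vcf(table, paths[["vcf"]])
  meta <- truth$samples[, c("sample", "population", "lat", "lon", "species")]
  write.table(meta, paths[["metadata"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$samples, paths[["truth_samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  site_truth <- data.frame(site = seq_along(truth$p_anc),
                           p_anc = truth$p_anc, is_fixed = truth$is_fixed)
  write.table(site_truth, paths[["truth_sites"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample`, `population`, `lat`, `lon`
#' and optionally `species`.
#'
#' @param path TSV file.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  need <- c("sample", "population", "lat", "lon")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta
}
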