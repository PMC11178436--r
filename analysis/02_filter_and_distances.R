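#!/usr/bin/env Rscript
# Apply the cohort site filters (QUAL >= 20; depth 10-1000 in >= 80% of
# samples), compute allele-sharing distances, cluster the samples, and
# check that a reference-free k-mer kinship tells the same story on a
# thinned-down cohort.

suppressPackageStartupMessages(library(lemnapop))

tab <- read_vcf("results/cohort/cohort.vcf")
meta <- read_metadata("results/cohort/metadata.tsv")

ft <- filter_variants(tab)
cat("site filter:\n")
print(attr(ft, "filter_counts"))

d <- pairwise_allele_distance(ft)
write_distance_tsv(d, "results/distance.tsv")
cl <- cluster_samples(d, k = length(unique(meta$population)))
writeLines(cl$newick, "results/dendrogram.nwk")
cat("\nflat grouping vs sampled ponds:\n")
print(table(cl$groups, meta$population[match(rownames(d), meta$sample)]))

# k-mer cross-check on a smaller cohort (sequence reconstruction at
# 5000 sites x 54 samples would dominate the runtime for no extra insight)
spec_k <- cohort_spec(n_pops_sp1 = 2, n_pops_sp2 = 1, samples_per_pop = 3,
                      n_sites = 300, missing_rate = 0, seed = 2024)
ck <- simulate_cohort(spec_k)
seqs <- cohort_sequences(ck$truth, spacing = 40, seed = 1)
profiles <- lapply(names(seqs), function(id) {
  count_canonical_kmers(seqs[[id]], k = 31, min_count = 1, sample_id = id)
})
d_kmer <- kinship_to_distance(kmer_kinship(profiles))
d_snp <- pairwise_allele_distance(ck$table)
mt <- mantel_test(d_kmer, d_snp, nperm = 999, seed = 1)
cat("\nk-mer vs SNP distance concordance: ")
print(mt)
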