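# small cohorts shared across test files; sizes chosen so the whole
# suite stays fast while every downstream statistic still has signal
small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_pops_sp1 = 3, n_pops_sp2 = 2, samples_per_pop = 3,
         n_sites = 800, seed = 42),
    list(...)
  )
  do.call(cohort_spec, args)
}

# map rows of a (possibly filtered) table back to original site indices
site_key <- function(table) paste(table$sites$contig, table$sites$pos)

# independent hand-rolled BH step-up (oracle for bh_fdr)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
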