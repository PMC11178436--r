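---
title: "Methods: cryptic hybrid detection and clonal structure in duckweed cohorts"
author: "lemnapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic hybrid detection and clonal structure in duckweed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemnapop)
```

## The problem

Common duckweed (*Lemna minor*) is a workhorse of experimental ecology, but
it is morphologically almost indistinguishable from *L. japonica*, its
hybrid with *L. turionifera*.  Whole-genome sequencing of pond-collected
cohorts therefore has to answer three questions at once: which samples are
which species, what ploidy and parental-genome dosage do the hybrids carry,
and how is genetic variation distributed within and between ponds in these
predominantly clonal populations.  `lemnapop` implements the analysis chain
for all three questions, together with a synthetic-cohort generator so that
every statistic can be validated against a known truth.

Notation: M denotes the *L. minor* parental genome, T the *L. turionifera*
genome.  An M/M/T individual is a triploid carrying two M haplotypes and
one T haplotype.

## Genotype model and site filters

Input is a diploid-caller VCF (GT, AD, DP per sample, site QUAL), i.e.
calls take only the values 0/0, 0/1, 1/1 or missing even for triploid
samples.  Sites are filtered with the standard cohort rule: QUAL at least
20, and per-sample depth between 10 and 1000 in at least 80% of samples.
Both bounds are inclusive and the completeness count is rounded up; the
source text of the filter leaves boundary semantics open, so the
conservative inclusive/ceiling reading is used.  Coverage is taken from DP
by default, with an AD-sum fallback (`coverage_from = "AD"`) because
callers differ in which of the two they populate reliably.

## Allele-sharing distance

The genetic distance between two samples is the fraction of alleles that
differ, over the sites where both are called: per-site mismatch
$|g_i - g_j|/2$ with $g \in \{0, 1, 2\}$ alternative alleles, averaged over
shared sites.  Two unphased heterozygotes count as identical (mismatch 0);
this is the natural dosage reading of "fraction of alleles that differed"
and is what the brute-force oracle in the test suite enumerates.  Pairs
with no shared sites are flagged `NA` rather than silently zero.  Average
linkage is the default for the dendrograms, matching heatmap-style
practice.

## Reference-free k-mer kinship

The k-mer module is a deliberately simplified stand-in for external k-mer
pipelines: canonical 31-mers (lexicographic minimum of the k-mer and its
reverse complement; odd k enforced), a count threshold (default 2) to
remove one-off sequencing-error k-mers, a presence filter keeping k-mers
in at least 2 and at most $n-1$ samples, and kinship defined as the
fraction of retained k-mers with equal presence state.  This is *not* the
algorithm of any specific external tool — those are used as black boxes in
practice and their internals are replaceable; what matters here is the
comparison path (kinship $\to$ distance via $1-K$, then Mantel
concordance with the SNP distance), which the tests exercise end to end.

## Assignment-marker scan

Each SNP is tested for association with the two-species partition with a
quasibinomial (logistic-link) GLM under three genotype codings: the full
three-level factor, and the two collapsed factors 0/0 vs rest and 1/1 vs
rest.  The coding with the highest percent of null deviance explained
(%-DEV) is kept per site; ties favour the two-level codings because they
spend one less degree of freedom.  With a categorical predictor and binary
response, the maximum-likelihood fit is the cell means of the response, so
deviances are computed in closed form; `stats::glm` reproduces them to
numerical precision and serves as the independent oracle in the tests.
The F statistic is $((D_0 - D_r)/\Delta df)/\hat\varphi$ with
$\hat\varphi$ the Pearson dispersion, and one p-value per site enters a
single Benjamini–Hochberg correction.  Markers with FDR < 0.05 *and*
%-DEV $\ge$ 80 are significant; the deviance bar (inclusive, per the "at
least 80%" reading) is what keeps population-specific variants from
masquerading as species markers in large cohorts.

Perfect separation is the expected outcome at fixed differences, not an
error: it is reported as %-DEV = 100 with a `separated` flag, and the
p-value is computed with deviance and dispersion floored at $10^{-8}$,
which drives it to the numerical floor.  Users filtering on %-DEV alone
are unaffected by the flooring.  Because the best-of-three coding
selection reuses the data, the post-selection p-values are
anti-conservative; the FDR is applied to them anyway (matching standard
practice for this scan), and the calibration tests therefore check
uniformity on *single-coding* p-values, where it actually holds.  Null
p-values at two-dozen-sample designs are strongly discrete (a few hundred
distinct values, atoms at 1), so distributional calibration is asserted
with a two-sample Kolmogorov–Smirnov test against an independent null
draw plus explicit tail checks $P(p \le \alpha) \approx \alpha$; a
one-sample KS against the continuous uniform would reject mechanically on
discreteness alone.

## Allele-balance ploidy inference

At heterozygous calls with depth at least 20, the alternative-read
fraction $r = AD_{alt}/(AD_{ref}+AD_{alt})$ concentrates around the allele
dosage: 1/2 in diploids, 1/3 in M/M/T triploids (two reference-parent
copies), 2/3 in M/T/T.  The per-sample spectrum is a 1%-wide histogram of
$r$ smoothed with a 3-bin moving average; its modal bin classifies the
sample via three disjoint windows ([0.28, 0.41) M/M/T; [0.45, 0.55]
diploid het; (0.59, 0.72] M/T/T).  Window boundaries sit midway between
adjacent theoretical modes, with extra allowance below 1/3 and above 2/3
because observed ratios at finite depth tend to run slightly outside
theory.  Two windows holding nearly equal mass (within 10% of the sites)
or a mode outside every window yield `AMBIGUOUS`; fewer than 200 usable
het sites yields `UNINFORMATIVE`.  The minimum depth of 20 keeps the
binomial spread of $r$ (SD $\approx$ 0.11 at depth 20) from blurring the
1/3 vs 1/2 modes; a mixture-model fit would be the next refinement and is
deliberately out of scope at these site counts.

Two estimator details matter at simulation-grade depth distributions.
The histogram bins are centred on exact percent values, and counts are
accumulated by *linear binning* (each observation is split between the
two nearest bin centres in proportion to proximity).  With plain edge
binning, the discrete support of $r$ — multiples of $1/\mathrm{depth}$ —
resonates against the percent grid when depth is tightly concentrated
(e.g. Poisson around 60), and the modal bin can jump two bins off theory;
real cohorts, whose depth spans an order of magnitude, smear these atoms.
Linear binning removes the aliasing without changing bin width, smoothing
or the mode rule, and over repeated simulations keeps the mode within one
bin of 1/3, 1/2 and 2/3.

## Sub-genome coverage

On a combined M + T reference, reads from a diploid M/M sample have
essentially nowhere to go on the T side, while an M/M/T triploid covers M
at twice the depth of T.  `subgenome_coverage()` reports mean depth per
sub-genome, their ratio, and the fraction of T sites with any coverage;
a sample with under 5% covered T sites is called pure M, and otherwise
the ratio windows [1.5, 2.5], [0.75, 1.33] and [0.4, 0.67] call M/M/T,
M/T and M/T/T.  Splitting the SNPs by sub-genome (including plastid
partitions when tagged) and correlating the partition-specific distance
matrices (Mantel) asks whether both parental genomes tell the same
post-hybridisation story — a correlation near 1 is what a single shared
hybrid origin predicts.

## Structure statistics

Within- and between-group distance summaries use only groups with at
least three samples.  Homogeneity of within-group dispersion follows the
principal-coordinates construction: embed $-D^2/2$ by double centering,
keep positive- and negative-eigenvalue axes separately, and compute each
sample's distance to its group centroid with squared deviations on
negative axes subtracted and the result floored at zero.  The test
statistic is the one-way ANOVA F over these distances; its p-value comes
from permuting group labels in the fixed embedding with the
observed-included convention $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$.
The implementation is verified against the reference multivariate
dispersion implementation in `vegan` to $10^{-8}$.

Mantel tests use the Pearson correlation over off-diagonal upper
triangles, jointly permuting rows and columns of the second matrix, with
the same +1 convention — so with the default 9999 permutations the
smallest attainable p is exactly $10^{-4}$.  Isolation by distance
correlates the genetic distance matrix with great-circle distances
(haversine, sphere radius 6,371,000 m) floored at 1 m — same-pond pairs
would otherwise blow up the log — and log10-transformed; alongside the
Mantel test an ordinary least-squares regression of genetic on
log-physical pair distance reports ANOVA F and Pearson r, with the usual
caveat that pairs are not independent.  Latitudes outside [−90, 90] are a
hard error: coordinate typos are common in field metadata and silently
corrupt every downstream spatial statistic.  A flag excludes same-pond
pairs from the regression; the Mantel test always uses the full floored
matrix because masking entries breaks its permutation structure.

## The synthetic-cohort generator

The generator emulates exactly the structure the analyses assume, and is
itself first-class, tested code:

* **Sampling design.** Populations (default 8 diploid + 4 hybrid ponds,
  3–6 samples each) placed uniformly in a 200 km box, mirroring a
  regional pond survey; one founding clone per pond.
* **Drift.** Population allele frequencies follow the Balding–Nichols
  model (Beta around the ancestral frequency with variance
  $F_{ST}\,p(1-p)$, default $F_{ST} = 0.3$), verified against a direct
  Monte-Carlo Beta oracle.
* **Isolation by distance.** Drift draws are coupled through a Gaussian
  copula whose correlation decays as $\exp(-d/\lambda)$ with
  $\lambda$ = `ibd_strength` km (default 100); this preserves the
  Balding–Nichols marginals exactly while inducing a positive Mantel
  signal, and $\lambda = 0$ switches it off.
* **Ancestral frequencies** are drawn from $0.02 + 0.96\,\mathrm{Beta}(0.8, 4)$,
  i.e. skewed toward low alternative-allele frequencies.  A uniform prior
  would give every individual ~35% heterozygosity and a hybrid nearly
  equal spectrum mass at 1/3 and 2/3 — unlike any reference-aligned
  cohort, where the reference allele is the majority state at most
  discovered SNPs and the 33% mode dominates.
* **Hybrids.** Species-2 samples carry M/M/T by default (M/T/T and M/T
  behind a flag); a configurable fraction of sites (default 10%) is fixed
  between the parental genomes, with the M allele as reference.
* **Clonality.** Clone-mates copy the pond founder and then mutate with a
  small per-site probability (default $10^{-3}$), flipping one randomly
  chosen haplotype.
* **Reads and calls.** Depth is Poisson (mean 60), alternative reads are
  Binomial at the error-perturbed dosage (error $10^{-3}$ per read,
  symmetric, no mapping bias), and genotypes are called like a diploid
  caller: alt fraction $\le 0.15 \to$ 0/0, $\ge 0.85 \to$ 1/1, otherwise
  0/1, minimum callable depth 4, plus 2% random missingness.  The
  thresholds are chosen so binomial noise at filter-passing depth rarely
  flips calls — rarely, not never: at depth 60 a true 1/3-dosage het is
  called 0/0 with probability $\approx 2\times10^{-3}$, which is why
  exact-recovery claims are made at genotype level (`calls_from_truth()`)
  while read-level tests assert high (not perfect) recovery.
* **Two reference views.** `reference = "Lm"` emulates alignment to the
  M genome alone: all haplotypes pile onto the M sites, so hybrid
  dosages appear as thirds (this is the view for allele-balance and the
  assignment scan).  `reference = "Lj"` assigns reads to the sub-genome
  of their haplotype of origin, with per-site depth scaled by copy
  number — a diploid then has empty T contigs and an M/M/T hybrid shows
  the 2:1 coverage ratio.  QUAL is `min(99, 3 x mean depth)`, a monotone
  stand-in whose ordering is all the quality filter consumes.

What the generator does **not** emulate: linkage disequilibrium along
chromosomes, indels and multi-allelic sites, mapping bias, pooled
multi-clone samples, and the slight downward shift of observed allele
ratios seen in real data (its error model is symmetric, so tests assert
the theoretical modes).  Passing tests therefore validate the statistics
under idealised sampling noise, not robustness to alignment artefacts.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything from scratch at
sizes chosen to keep the full run in minutes while leaving each statistic
ample signal: spectra at 10,000 sites and depth 60; scan calibration on a
5,500-site, 12 + 12-sample cohort; whole-cohort recovery on 12 ponds,
54 samples and 3,000 sites; 500 reduced-scale replicates
(population-level founder-frequency distances, 199 permutations each) for
the null Mantel calibration.  All randomness flows from explicit integer
seeds; identical spec + seed reproduces cohorts byte-for-byte, including
the written VCF.

## Known limitations

* Hexaploids with two divergent copies are indistinguishable from
  triploids by allele balance alone; the classification windows make no
  attempt to resolve them.
* The scan handles exactly two groups; multi-group designs and
  kinship-corrected mixed models are out of scope.
* The k-mer module is in-memory and suited to test-scale sequence sets,
  not genome-scale read archives.
* Outlier samples are handled by an explicit exclusion list in the
  pipeline configuration, not detected automatically.
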