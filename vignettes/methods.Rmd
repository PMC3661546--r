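---
title: "Methods: pairwise population genetic differences for genes and gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise population genetic differences for genes and gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgendiff)
```

This vignette is the package's account of its statistical machinery: the
models behind each of the eleven features, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where more than one reasonable
convention exists.

## Inputs, QC and gene assignment

Genotypes enter as alt-allele dosages in {0, 1, 2, NA} (from VCF GT fields
via `read_vcf()`, or the simple TSV dialect). Only bi-allelic autosomal
SNPs are supported; multi-allelic and non-SNP records are skipped and
counted. Missing genotypes are excluded from every frequency denominator —
no imputation anywhere.

Quality control retains a SNP only if it passes **in every population**
(configurable to pooled testing): Hardy–Weinberg exact p ≥ 0.001, call
rate ≥ 0.75, minor allele frequency ≥ 0.01. The per-population scope is the
conservative reading consistent with requiring genes to be usable in all
populations simultaneously; pooled testing would conflate true
differentiation with HWE failure. The HWE test is the exact conditional
test — the distribution of the heterozygote count given the allele counts
is computed in closed form on the log scale and the two-sided p-value sums
all outcomes no more probable than the observed one. An exact test matters
here: chi-square approximations are unreliable exactly where the 0.001
threshold bites (small expected counts), and the test suite checks the
implementation against a brute-force enumeration oracle for every genotype
table with up to 30 individuals.

Coordinates follow the two standard conventions: VCF positions are
1-based, gene regions (BED) are 0-based half-open, and a SNP belongs to a
gene iff `pos − 1 ∈ [start, end)`. Genes keep at least 2 SNPs or are
dropped; gene sets (GMT) are pruned to catalogue genes and keep at least
10 members or are dropped.

## Allele-frequency features

For each gene, frequencies are **reference-oriented**: at every SNP the
tracked allele is the minor allele in a designated reference population
(first panel population by default), with ties at 0.5 broken toward the
VCF alt allele so orientation is deterministic. The allele-frequency
difference between populations *i* and *j* is the mean absolute per-SNP
difference d = (1/m) Σₖ |p_ik − p_jk| ∈ [0, 1]. SNPs monomorphic in both
populations contribute |p − p| = 0 and are kept — the quantity is
well-defined — whereas they are excluded from FST, where the estimator is
undefined.

FST uses the Weir–Cockerham variance-component estimator for two
populations, computed from sample sizes, allele frequencies and observed
heterozygosities; per-SNP components a (among populations), b (among
individuals) and c (within individuals) are combined across a gene's SNPs
as the ratio of sums θ = Σa / Σ(a+b+c). The ratio-of-sums combination has
lower bias than averaging per-SNP ratios (available via
`gene_fst(method = "average")`); negative estimates are possible near
θ = 0 and are reported as computed, not truncated. Under Balding–Nichols
sampling the estimator recovers the simulation's F: the acceptance script
measures θ ≈ 0.10 at F = 0.1 with 2 × 100 diploids and 2,000 SNPs, and
monotone increase over F ∈ {0.01, 0.05, 0.1, 0.2}.

## LD-pattern features

Two-locus haplotype frequencies come from the standard EM for unphased
genotypes: all genotype classes phase unambiguously except the double
heterozygote, whose mass is split between cis and trans in proportion to
p₁₁p₀₀ : p₁₀p₀₁ at each E-step. Initialization is the
linkage-equilibrium product of marginal frequencies, convergence is a
maximum frequency change below 1e-8 (cap 1000 iterations). The
initialization is deterministic, so results are reproducible; EM converges
to a stationary point of the likelihood, and the tests verify its
log-likelihood dominates exhaustive simplex-grid scans. From the fitted
frequencies, D = p₁₁ − p_Ap_B, r² = D²/(p_A(1−p_A)p_B(1−p_B)), and
D′ = |D|/D_max with the usual sign-dependent D_max. Monomorphic loci give
undefined r²/D′, which propagate as missing.

Haplotype blocks use the four-gamete test: a SNP pair "recombines" if all
four gametes have EM frequency at or above 0.01 (the conventional
existence threshold; configurable). Gamete existence is judged from the
EM frequencies rather than naive counting so that missing data and double
heterozygotes are handled consistently with the r²/D′ machinery. The
partition is greedy left-to-right: a block is a maximal contiguous run in
which **every** SNP pair passes; because validity of a run is hereditary,
greedy extension equals the longest-valid-run partition, which the tests
confirm against a brute-force partitioner. Runs of length 1 are not
blocks: `block_number` counts multi-SNP blocks only. Per gene and
population: block number, mean block span (end − start + 1, bp), and SNP
density as the mean over blocks of SNPs per kb of block span (the
per-block-then-average reading; the alternative — total SNPs over total
span — weights big blocks more and is not used). Zero blocks give missing
block features, which propagate to missing difference records.

Block haplotype spectra come from a multi-locus EM over the haplotype
space restricted to haplotypes compatible with the observed genotypes;
blocks longer than 8 SNPs are fit by partition–ligation (chunk EMs, top-8
haplotypes per chunk concatenated into a candidate set, final EM
restricted to candidates). Haplotype diversity is Nei's unbiased
H = (n/(n−1))(1 − Σ p_h²) with n counting chromosomes (2 × complete
samples), averaged over a gene's blocks. The unbiasing factor and the
chromosome convention are deliberate choices among the common variants;
`unbiased = FALSE` gives the plain form. A consequence worth noting: H can
slightly exceed 1 (bounded by n/(n−1)), so differences of H are bounded by
n/(n−1) rather than exactly 1.

## TagSNP transferability

Tag selection is a greedy pairwise cover: repeatedly pick the SNP covering
the most uncovered SNPs, where coverage means r² ≥ 0.8 (self-coverage
included), ties to the lower index. The coverage property — every SNP
covered by at least one tag — holds by construction and is asserted in the
tests, along with proximity to the exhaustive minimum cover on small
instances. Multi-marker tagging is out of scope; the capture criterion
used downstream is purely pairwise.

Transferability is directed: tags selected in population B are evaluated
in population A, a SNP of A being **captured** when its r² with some B tag
is strictly greater than 0.8, with r² computed in population A (the
natural choice — transferability asks how well foreign tags describe the
local LD structure). The selection threshold is inclusive (≥ 0.8) while
capture is strict (> 0.8); the boundary case r² exactly 0.8 is the one
place the two rules disagree, and both rules are kept as stated rather
than unified silently. `captured_percent` is 100 × captured/m;
`avg_max_r2` is the mean over captured SNPs of the maximum r² with any
tag, missing when nothing is captured.

## From features to difference records

Every (gene, feature, unordered population pair) yields one record:

* vector features (`maf`; `r2`/`dprime` per SNP pair) — mean absolute
  difference over units defined in both populations;
* scalar features (`block_number`, `block_size`, `snp_density`,
  `hap_diversity`) — absolute difference, the m = 1 case of the same
  formula;
* `tag_percent` — absolute difference of tag *fractions* (percent/100),
  keeping the record on the same [0, 1] scale as the other tag-family
  records;
* directed features (`captured_percent`, `avg_max_r2`) — the two
  directions' deviations from perfect transfer are averaged and scaled to
  [0, 1]: ((100 − c_{A→B}) + (100 − c_{B→A}))/2/100, and analogously with
  1 − avg_max_r2. If one direction is missing the other is used alone.
  The symmetrization is an explicit package convention — directed values
  are also available by calling `transferability()` directly;
* `fst` — already a pairwise quantity; the record *is* the gene θ for
  that pair, not a difference of differences.

Missing values propagate: a feature missing in either population gives a
missing record, never an implicit zero. Gene-set scores are equal-weight
means over member genes with non-missing values (genes in several sets
count fully in each); a superset's score is therefore the size-weighted
mean of any partition of it, which the tests verify algebraically.
Reference summaries use quartiles with linear interpolation
(`stats::quantile` type 7) and percentile rank = 100 × fraction of values
strictly below the query.

## Synthetic data

The generator emulates the shape of multi-population genotype panels:
ancestral frequencies Uniform(0.05, 0.95); per-population frequencies
Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F) (F = 0 degenerates to the
ancestral value exactly); within each gene, SNPs grouped into blocks, each
(block, population) getting a small haplotype pool from which diploids
draw two haplotypes — small pools give strong within-block LD, blocks are
mutually at equilibrium; uniform missingness. By default pool columns that
come out monomorphic are redrawn (`ascertain = TRUE`), mimicking the
ascertainment of genotyping arrays toward common polymorphic SNPs; this
biases marginal frequencies away from the edges, so model-recovery studies
(e.g. estimating F) should set `ascertain = FALSE`, as the acceptance
script does.

Defaults (3 populations × 30 samples, 20 genes × 6 SNPs, F = 0.1,
blocks of 3 SNPs from pools of 4, 2% missingness) are sized for desk-scale
reproducibility; the acceptance runs use 3 × 50 samples with 50 genes × 8
SNPs for the cardinality study and 2 × 100 samples with 2,000 SNPs for the
F-recovery study. What the generator does **not** emulate: recombination
maps and distance-decaying LD, demographic history, selection, genotyping
error correlated with assay chemistry, and realistic site-frequency
spectra. Passing tests therefore demonstrate correctness of the
estimators and plumbing under a controlled model — not robustness to every
property of real panels.

## Numerical choices and limitations

* EM tolerance 1e-8 / 1000 iterations; partition–ligation keeps 8
  haplotypes per chunk — restricted-space EM can in principle miss mass
  that a full EM would find, which matters only for blocks > 8 SNPs.
* The exact HWE test adds 1e-12 slack when comparing outcome
  probabilities, so ties at machine precision count as "no more probable".
* `difference records` for `block_size` are in bp and unbounded; all
  [0, 1]-family features stay in [0, 1] except `hap_diversity` (see
  above).
* FST is two-population by design; simultaneous multi-population θ and
  haplotype-based FST are out of scope.
* Phased input is not used even if present: the EM treats all input as
  unphased.
* With `max_pair_distance` set, distant SNP pairs are skipped in r²/D′
  maps and treated as r² = 0 for tagging — a deliberate cost cap for very
  large gene regions.
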