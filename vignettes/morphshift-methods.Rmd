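---
title: "morphshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `morphshift`, the
choices made where the underlying procedures admit more than one
reasonable implementation, and what the synthetic-data generator does
and does not emulate.

## The question and the estimand

Pea aphid lineages come in two reproductive modes: cyclical
parthenogens (CP), which produce males, sexual females and
parthenogenetic females, and obligate parthenogens (OP), which have
lost the sexual phase and produce only parthenogenetic females and
occasional, effectively matingless, males. If intra-locus sexual
conflict shaped morph-biased expression, its relaxation in OP lineages
should move expression towards the parthenogenetic-female optimum.

The estimand is, per gene and per morph shared by both modes
(parthenogenetic females and males),

$$\mathrm{ratio}_{g,m} = \log_2\frac{\overline{\mathrm{CPM}}^{OP}_{g,m} + 0.05}
{\overline{\mathrm{CPM}}^{CP}_{g,m} + 0.05},$$

summarized as the median over a gene class (*Mdn*) and tested against
zero with a Wilcoxon signed-rank test. Positive values mean higher
expression in OP. The pseudocount of 0.05 CPM guards against division
by zero; it is configurable (`shift_params(pseudocount = )`) and as it
grows all ratios shrink monotonically towards zero, so it should stay
small relative to typical CPM values.

Gene classes (morph-biased M/F/P vs unbiased, degree + vs ++,
tissue-biased, X vs autosome) are learned on an *independent* outgroup
dataset, never on the focal data, to avoid using the same data as
explanatory and response variable. The leave-one-out check
(`leave_one_out_check()`) quantifies what happens if classes are
instead learned on one focal CP lineage: each CP lineage in turn
provides the classification while the ratio is recomputed without it.

## Normalization

TMM normalization follows the canonical algorithm: the reference
library is the one whose upper-quartile/library-size ratio (p = 0.75)
is closest to the mean of those ratios; each library's factor is 2 to
the precision-weighted mean of M-values against the reference after
trimming 30% of M-values and 5% of A-values on each side, computed over
genes expressed in both libraries; factors are rescaled to geometric
mean 1. These trim and weighting constants are the defaults of the
standard implementation, which the package's tests use as an
independent oracle (agreement to 1e-6 on random matrices). Counts may
be fractional here (normalization is count-scale free); they are
rounded only where the exact test requires integers.

Expression filtering retains genes with CPM strictly above 1 in at
least 8 of the 40 focal libraries (2 of 6 for the whole-body outgroup,
2 of 18 for the tissue outgroup). Averaging is two-stage — replicates
within lineage, then lineages within mode — and on the CPM scale, not
the log scale, because the log is taken only once, of the ratio of the
averaged values. With balanced replication the two-stage mean equals
the pooled mean; with unbalanced values it does not, and the pipeline
always uses the two-stage form.

## Classification by exact tests

With two replicates per group, genewise dispersions are unidentifiable,
so a single common negative-binomial dispersion is estimated by
conditional maximum likelihood: counts are mapped to a common effective
library size by a quantile-mapping adjustment (the mean of a normal and
a gamma quantile transform, switching to upper-tail mapping above the
mean so large counts do not saturate), and the conditional likelihood
given per-gene group totals is maximized over the dispersion, iterating
the equalize/maximize pair twice. On Poisson data the estimate
collapses to the boundary; on NB data with 5000 genes it is within a
few percent of the truth (tested at 20%).

The two-group exact test conditions on the per-gene total of the
equalized, integer-rounded pseudo-counts: under a common dispersion the
group totals are themselves negative binomial, and the two-sided
p-value is `min(1, 2 x smaller tail mass)` of the conditional
distribution of the group-A total. At zero dispersion and equal sizes
this is exactly the conditional binomial test, and for small totals it
matches exhaustive enumeration of all per-sample count splits (both
used as test oracles). The fold change is computed on the CPM scale
with a small proportional prior count (2 at the geometric-mean library
size) to avoid log of zero; the prior is exposed
(`nb_exact_test(prior_count = )`).

A gene is morph-biased when it is overexpressed by the same morph in
both pairwise comparisons with the two other morphs, with BH-adjusted
p < 0.05 and |log2FC| > 1 — both strict inequalities, so exact ties at
a threshold do not qualify — and morph-limited when additionally
|log2FC| > 2 in both. The identical dual rule applies to the three
tissues within each morph. Direction is read from the sign of the fold
change in each comparison. p-values are adjusted per comparison.

## Shift tests and subdivisions

Zero ratios are dropped before the signed-rank test (the usual
treatment); the reported median is over all finite ratios. The exact
signed-rank distribution is used for n <= 25 without ties in |ratio|,
otherwise the continuity-corrected normal approximation — matching the
behaviour of the standard R implementation the analysis builds on.
Subdivision panels (degree, chromosome, tissue) are restricted to
morph-biased genes carrying the relevant key; tissue panels exclude
genes without a tissue call, and empty levels are skipped with a
warning rather than an error.

## Genetic and transcriptomic divergence

SNPs are retained when genotype quality is strictly above 20 ("above"
read literally) and depth is at least 80 in **every** library — the
per-library reading of the depth rule; a summed-depth reading would be
much weaker and is not offered. Only biallelic SNPs (single-base REF
and ALT) are considered. With one diploid individual per lineage,
allele frequencies are dosage/2, so a heterozygote contributes 0.5 to
Nei's identity terms. Nei's standard distance uses identity
probabilities averaged across loci (ratio of averages); a pair sharing
no alleles anywhere is reported as infinite rather than clamped.
Neighbour joining and Newick output use `ape`; bootstrap support
resamples SNP loci with replacement.

Transcriptomic distances are Euclidean between replicate-averaged
lineage profiles within one morph, after per-gene standardization
across the compared lineages. "Standardization" defaults to z-scoring
(center and unit variance), with center-only available as a switch,
since per-gene normalization before Euclidean distance most commonly
means z-scoring; zero-variance genes are dropped with a warning.
Lineage-level (rather than sample-level) distances match the
focal-lineage averaging that follows. The genetic correction divides
each transcriptomic pair value by the corresponding Nei distance before
focal averaging. Mantel tests use Spearman correlation with 999
permutations by default (the count is not fixed by the procedure and is
configurable), seeded. The PCA of genotypes is centered and unscaled by
default (scaling is a switch), as dosages are already on a common
scale.

## The synthetic-data generator

`simulate_counts()` draws library counts as
NB(mean = baseline x 2^(morph effect) x 2^(lineage effect) x 2^(delta)
scaled to the library size, dispersion phi_g), with:

* baseline log2 expression ~ Normal(5.5, 2) (CPM scale), with a 20%
  near-silent fraction (7 log2 units lower) so the expression filter
  has real work;
* per-gene dispersions ~ logNormal(log 0.08, 0.5), typical bulk RNA-seq
  biological variation;
* library sizes ~ logNormal(log 1e6, 0.15) — a desk-scale stand-in for
  deep sequencing, paired with 5000 genes so per-gene counts are
  realistic;
* class fractions M = 0.10, F = 0.10, P = 0.05, unbiased = 0.75, biased
  effect 2 log2 units (30% of biased genes drawn morph-limited at 3.2);
  half of the biased genes also carry a tissue bias in their own morph
  (gonads weighted double), expressed in the 18-library tissue
  outgroup;
* per-(gene, lineage) random effects ~ Normal(0, 0.15 log2), shared
  across the morphs of a lineage because lineages are clonal genotypes;
* injected OP-to-CP shifts delta = 0.13 for (parthenogenetic female,
  F-class), 0.13 for (male, P-class) and 0.85 for testis-biased
  male-biased genes — the headline effect sizes of the study system —
  applied to OP libraries of the target morph.

X-linkage is assigned uniformly at random (fraction 0.3, roughly the X
share of the aphid genome) independently of class, so chromosome
subdivisions are null by default.

`simulate_genotypes()` drifts allele frequencies from a shared
ancestral value first by a mode-shared component (SD 0.15) and then by
an independent per-lineage component (SD 0.2), clamped to [0, 1];
dosages are drawn with common random numbers across lineages so zero
drift gives identical genotypes. The defaults put within-mode Nei
distances near 0.15 — the scale observed in the real lineage panel —
while the shared mode component still separates modes cleanly on the
NJ tree and PCA.

What the generator does **not** emulate: fractional multi-mapped
counts (counts are integer NB draws, as the exact test requires); GC or
length biases; any coupling between genetic distance and expression
divergence — lineage expression effects are drawn independently of the
genotypes, so Mantel correlations are null by construction and the
Mantel machinery is validated by calibration, not by effect recovery;
and the unexplained bimodality of male-biased gene shifts seen in real
data, which is a descriptive feature with no defining computation.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of injected effects, not biological realism of every
data feature.

## Compositional closure and parameter recovery

CPM are relative abundances: injecting a positive shift on ~10% of
genes necessarily depresses the CPM of every other gene by the total
content increase (about -0.012 log2 under the defaults). TMM cannot
undo this, because a 0.13 log2 shift sits far inside the biological
spread of M-values and is untrimmable (the large 0.85 testis shift, by
contrast, is largely absorbed). The unbiased class — which has no
injected shift by construction — measures this closure term directly,
which is why recovery checks read each class median relative to the
same-morph unbiased median; with that reference the injected 0.13 /
0.13 / 0.85 are recovered within +-3 standard errors over 20 simulation
seeds. The same logic applies to real data: class medians are best
interpreted against the unbiased class, which the study design itself
uses as the reference point.

## Problem sizes and reproducibility

The default design is the study layout: 40 focal libraries (4 CP
lineages x 3 morphs x 2 replicates + 4 OP lineages x 2 morphs x 2
replicates), a 6-library whole-body outgroup, an 18-library tissue
outgroup, and 11449 candidate SNPs for the 8 focal lineages, with 5000
genes as the package's desk-scale default. The test suite uses smaller
gene counts (500-2500) and fewer bootstrap/permutation replicates
(50-200) chosen to keep each property sharply testable at interactive
runtimes; `scripts/acceptance.R` runs the full default design. Every
source of randomness derives from a single seed (sub-seeds are fixed
offsets), so all outputs — including bootstrap supports and Mantel
p-values — are bit-reproducible given the seed, and every written
output records the seed and a configuration hash.

## Known limitations

* Common dispersion only: tagwise/trended dispersion and GLM-based
  differential expression are out of scope; with 2 replicates per group
  the common-dispersion exact test is the classical choice, but genes
  with atypical dispersion will be mis-calibrated individually.
* The classifier's sensitivity is limited for weakly expressed genes
  (CPM of order 1) at 2 replicates; such genes pass the lenient
  outgroup filter but carry little information, which is visible in the
  recovery tests.
* Whether the depth filter should be per-library or summed, and whether
  genotype PCA should scale per SNP, are not settled by the procedure
  definitions; the package defaults to per-library and unscaled, with
  the PCA choice switchable.
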