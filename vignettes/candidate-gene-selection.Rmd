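---
title: "Detecting step-wise selection on a candidate gene: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting step-wise selection on a candidate gene: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsweep)
```

`hapsweep` implements the population-genetic analysis chain used to
argue that a candidate gene in a highly inbred crop has been under
step-wise positive selection — each of two alleles swept in a different
lineage, so that the species as a whole maintains both, the hallmark of
balancing selection. This vignette explains each statistic, the
assumptions behind it, the tunable parameters, the numerical
conventions, and what the synthetic panel does and does not emulate.

## The setting and its assumptions

The package targets panels of predominantly selfing plants (rice-like):
genotypes are effectively haploid, so every statistic here treats
homozygous calls as single alleles and sets heterozygous calls aside
site-wise, alongside missing calls. This "effective haploidy"
convention is applied uniformly — in r², in π, in amino-acid markers,
in haplotype scores — because mixing a rare heterozygote into
statistics defined on alleles would need a phasing model the data do
not support. Genotype codes are `0` (ref/ref), `1` (alt/alt), `2`
(het), `-1` (missing); all genomic coordinates are 1-based inclusive,
all window arithmetic half-open `[start, end)`, and the conversions to
external conventions (BED's 0-based half-open) happen only in the IO
layer.

## Coding variants and association

Coding positions count from +1 at the first coding base, 5'→3' on the
coding strand; minus-strand genes therefore count from the
genomically-rightmost CDS base. A SNP at coding position `p` lies in
codon `ceiling(p/3)`; both alleles' codons are translated with the
standard genetic code and classified as synonymous, nonsynonymous or
nonsense (nonsense changes are retained as association markers — they
are a nonsynonymous subclass and there is no reason to discard them).
Frame integrity (CDS length divisible by 3) is enforced where it
matters — when gene models are read from GFF3 and at translation — not
in the coordinate container, so purely positional operations accept any
interval set.

Association follows the standard candidate-gene recipe for structured
panels:

* markers with minor allele frequency ≤ 0.01 are dropped;
* a greedy LD-pruning pass (windows of 5 markers advancing by 2,
  position-sorted) repeatedly removes, from the first pair in scan
  order with r² > 0.2, the member with the smaller MAF (ties remove
  the later marker — a deterministic convention);
* classical (Torgerson) MDS of the pairwise allele-sharing distance
  1 − IBS supplies stratification covariates; the first two axes enter
  each per-marker OLS fit of the phenotype;
* two-sided t-tests on the marker slopes are Benjamini–Hochberg
  adjusted across **all** markers jointly, and a gene is called
  significant when the minimum adjusted p over its markers is below
  0.05. The gene-level aggregation rule (min marker p) is the simplest
  rule consistent with per-marker FDR control; it is deliberately
  exposed as a parameter-free convention rather than hidden.

Two design choices deserve emphasis. First, MDS axes carry a
deterministic sign (first nonzero loading positive) so runs are
reproducible. Second, the pipeline computes the stratification
coordinates after **leaving out the focal ±10 kb** (configurable via
`mds_exclude_bp`). On a desk-scale chromosome the deeply diverged
candidate region contributes a noticeable share of the genome-wide
distance matrix; axes fitted on all sites then partially encode the
tested marker itself and absorb its association signal. Leaving the
tested locus out of the covariate computation is the standard remedy
(the same logic as leave-one-chromosome-out in mixed-model GWAS) and
becomes a no-op as the genome grows.

## The ω sweep scan

For a putative sweep centre, split the surrounding SNPs into a left and
a right flank. The ω statistic is the mean r² within the flanks
(pooling both) divided by the mean r² between them. A completed sweep
leaves strong LD within each flank — recombinant escape haplotypes are
shared by runs of neighbouring sites — but none across the selected
site, so ω spikes there.

The scan evaluates ω on an arithmetic grid (5 kb spacing, anchored at
position = spacing), maximizing over all flank extents between
`minwin` = 500 bp and `maxwin` = 25 kb realized by SNP positions —
enumerating realized extents gives the identical optimum to scanning
every base pair at bounded cost. SNPs are binary-encoded with
heterozygous/missing calls excluded pairwise and no imputation.
Undefined r² values (monomorphic pairs, fewer than two complete
samples) are excluded from the sums with the pair counts adjusted; a
grid point with no admissible split, or a zero between-flank mean, is
flagged undefined rather than infinite. Grid points within 500 kb of a
centromere-mask interval carry no ω (pericentromeric LD is anomalous).

Per chromosome, the defined grid points whose ω reaches the k-th
largest value, k = max(1, floor(0.05 × n)), are flagged — ties at the
threshold are all flagged (conservative inclusion, deterministic), so
the flagged fraction can exceed the nominal 5%. Runs of consecutive
flagged points merge into regions `[point − spacing/2, point +
spacing/2)`, and a gene is sweep-flagged when its span intersects a
region under half-open logic.

Because a sweep is a **within-population** event, the pipeline scans
each cultivated subpopulation separately and flags a gene that falls in
the top 5% of any scanned group; pooling diverged lineages instead
mixes the two swept haplotype blocks and dilutes the within-flank
versus between-flank contrast the statistic needs.

## Windowed π and the focal contrast

Per non-overlapping 100-bp window, π is the average pairwise difference
per callable base: at each variant site with n ≥ 2 usable calls and k
alternate alleles the mean pairwise difference is k(n−k)/C(n,2) —
algebraically 2p̂q̂·n/(n−1) — summed over sites and divided by the
window's callable length (positions whose site has fewer than two
usable calls are subtracted; positions without a variant record count
as invariant). This estimator equals the exhaustive mean pairwise
Hamming distance exactly, which the test suite asserts on every small
instance; the plain 2p̂q̂ variant (no finite-sample factor) is exposed
via `estimator = "2pq"` because the conventions of windowed-π scripts
vary and the choice should be visible. Samples missing more than 80%
of the region's sites are excluded first. A region shorter than one
window yields a single truncated window with a warning.

The contrast takes the window-π values of a 4-kb focal region centred
on the gene and of the two 8-kb flanks completing a 20-kb set, runs a
one-way ANOVA, and performs all three pairwise comparisons with
Fisher's LSD t-tests on the pooled mean square error. When Bartlett's
test rejects variance homogeneity at 0.05 the pairwise tests switch to
Welch; when every group has zero variance the means are compared
directly with a warning. The verdict is `focal_reduced` only when the
focal mean is below both flanks **and** both focal–flank comparisons
are significant at α = 0.05. A step-down multiple-range procedure in
the style of REGWQ is deliberately not implemented: it is a
statistical-suite-specific procedure, and ANOVA + LSD with a Welch
fallback covers the same decision with standard, well-understood
components. An optional `log(x + eps)` transform (eps defaulting to
half the smallest positive value) is available for variance
stabilisation.

## Haplotype network

Region sequences are filtered (sites with > 20% missing dropped, then
sequences with > 30% missing dropped), and each remaining missing call
is imputed by the majority allele among the 3 nearest sequences
(Hamming distance over shared non-missing sites, computed on the
pre-imputation matrix so the result cannot depend on processing order;
distance ties break by row order, vote ties by the global major
allele). The network-imputation programs used in practice do not
document their algorithm, so this package substitutes the simplest
deterministic, locally consistent rule and says so; haplotype counts on
real data can therefore differ from those of other imputation tools.

Identical sequences collapse to haplotypes (nodes ordered
lexicographically by sequence for reproducibility) and the minimum
spanning network is built level by level over increasing Hamming
weights: at each weight, every edge joining two components that were
distinct at the start of that level is added. This construction yields
exactly the union of all minimum spanning trees — the Excoffier–Smouse
network that population-genetics suites compute at ε = 0 — which the
test suite verifies against exhaustive spanning-tree enumeration via
Prüfer sequences on small instances. An ε > 0 relaxation (admit edges
within ε of a level's weight) is exposed but defaults off. Distances
use segregating sites only; invariant sites contribute nothing.

## Haplotype scores and modality

Region SNPs with pooled MAF ≥ 0.2 are scored A=1, T=2, C=3, G=4, and a
sample's haplotype score is the mean over its usable markers
(heterozygous/missing markers drop out of that sample's mean — the
scoring rule is defined on single bases). Scores live in [1, 4]; a
monomorphic region gives every sample the same score.

Modality is judged by Sarle's bimodality coefficient
b = (g₁² + 1) / (g₂ + 3(n−1)² / ((n−2)(n−3))), with g₁ the moment
sample skewness and g₂ the excess kurtosis; b > 5/9 (the uniform
distribution's value) is called bimodal. The raw coefficient is always
reported alongside the verdict because 5/9 is a heuristic boundary, not
a test with a sampling distribution; at panel sizes of a few dozen the
coefficient is noisy, which is why the pipeline reports it per
subpopulation and for the pooled in-species panel (the outgroup,
being a set of distinct species rather than part of the study
population, is summarised separately).

## The synthetic panel

The generator's defaults define the study conditions every stochastic
test runs under: a 250-kb chromosome at 6 SNPs/kb (the density of a
dense rice resequencing panel) carrying one focal gene (1.5-kb CDS, 4-kb
focal region) and nine background genes; 200 samples split into an
outgroup of 30 wild-relative species, two wild ecotypes of 44, and two
cultivated subspecies of 41; derived-allele FNP frequencies of 0 /
0.84 / 0.03 / 0.995 / 0.005 (outgroup, wild A, wild B, cultivars A/B);
missing calls at 3% and heterozygotes at 0.5% (the FNP itself kept
heterozygote-free); and an LTSS phenotype of baseline 55% with −20%
per derived allele, ±5% lineage offsets, and Gaussian noise (sd 8%),
truncated to [0, 100].

Three structural features matter more than the numbers:

* **Background structure** is a hierarchical Beta (F-model) frequency
  tree — ancestral → lineage (F = 0.07) → subpopulation (F = 0.05) —
  with sites independent given the frequencies. It is not a
  coalescent: there is no background LD beyond what structure induces,
  no recombination map, and no demography. That is sufficient to
  exercise stratification, pruning and the scans, and it keeps the
  generator fast and fully deterministic per seed.
* **The outgroup is a star phylogeny**: each outgroup sample deviates
  privately from the ancestral haplotype at rate 0.3 per site rather
  than sharing drifted frequencies. Relative species do not share
  segregating polymorphism; modelling them as a panmictic population
  would create common "splitter" sites and spurious bimodality in
  their score distribution.
* **The balanced locus** is explicit: 70% of sweep-region sites carry
  two coherent, anciently diverged haplotypes linked to the FNP (a
  sample carries its FNP-matching haplotype with probability 0.9,
  deviating per site with probability 0.02). The ancestral haplotype
  draws from low-scoring bases and the derived one from high-scoring
  bases with probability 0.9, so the two groups separate on the 1–4
  score scale the way the emulated study's score modes do. This last
  choice is honest artifice: a real pair of diverged haplotypes need
  not separate on the base-score scale, and passing modality tests on
  synthetic data says nothing about whether any particular real locus
  will.

The sweep itself is hitchhiking with recombinant escape: every carrier
of the selected allele receives the lineage donor haplotype in a
contiguous segment around the selected site, out to an independent
random breakpoint per side, with escape probability growing linearly
with distance so the mean escaped fraction equals the configured
intensity (for intensity ≤ 0.5; 1 returns the input unchanged). A
per-site independent-mutation model was considered and rejected: it
reduces diversity but produces no within-flank LD, hence no ω
signature — nested escape segments are what create it. The focal CDS
carries no variant besides the FNP, matching the single
protein-changing polymorphism of the kind of candidate gene the
package targets (and keeping the causal marker from being LD-pruned
against intra-gene proxies).

What the generator does **not** emulate: coalescent genealogies and
background LD decay, gene flow and admixture, genotype-calling error
structure beyond uniform missingness, multi-chromosome genomes, indels
and structural variation, or any phenotype architecture beyond a
single additive locus with population offsets. Passing the recovery
tests therefore demonstrates that the statistics detect the signals
they are designed for under their stated assumptions — not that those
assumptions hold in any particular real panel.

## Numerical conventions and degenerate inputs

* r² is undefined (NA) with fewer than two complete effective-haploid
  pairs or a monomorphic member; undefined values propagate as
  flagged, never as zero.
* ω: overlapping flank sets are an error; empty between-flank sums
  give NA, not infinity. The grid is anchored at position = spacing.
* Quantile thresholds flag all ties ("higher" convention).
* Pruning removal ties break toward the later marker; MDS signs are
  fixed; haplotype nodes sort lexicographically; all randomness flows
  from one root seed expanded per stage, and a rerun with the same
  configuration is byte-identical.
* Degenerate inputs (all-zero distance matrices, all-undefined ω
  tracks, zero-variance contrast groups, regions with no SNPs) warn
  and return well-defined empty or fallback results rather than
  erroring mid-pipeline.

## Test scale

The deterministic oracle checks run on deliberately tiny instances
(≤ 20 SNPs for ω, ≤ 6 sequences for π, ≤ 7 haplotypes for the MSN,
≤ 10 markers for pruning, ≤ 1000 p-values for BH) where exhaustive
enumeration is exact. The stochastic calibration and recovery suites
use the generator's default panel (200 samples, 250 kb, 1,500 SNPs)
with 25 replicates for recovery rates, 50 for the permutation null,
and 100 for the contrast and modality nulls — sizes chosen so the
binomial uncertainty of each rate is small relative to its acceptance
margin while a full suite run stays interactive.

## Known limitations

* The ω implementation maximizes over realized-extent splits at grid
  points; it is validated against exhaustive enumeration, not against
  any external scanner's output, whose internal maximization schedule
  may differ.
* Gene-level significance is min-marker-p; no formal gene-based test
  (burden, VEGAS-style) is attempted.
* The MSN is not a median-joining network: no inferred median vectors.
* π has no bootstrap confidence intervals, and no Tajima's D, θ_W or
  F_ST are provided.
* With fewer than ~30 scores per group the bimodality coefficient is
  noisy; treat verdicts on small groups as descriptive.
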