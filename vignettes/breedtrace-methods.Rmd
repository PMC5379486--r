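---
title: "Methods: dissecting a long-term breeding pedigree with breedtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a long-term breeding pedigree with breedtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedtrace)
```

## The setting

Elite inbred crop cultivars are typically bred by *improving crossing*:
an elite line (the receptor, used as recurrent parent) is crossed to a
donor carrying a target trait, and a new receptor is selected from the
offspring. Repeated over decades this produces a pedigree with a trunk
of sequential receptors, side branches that merge back in, and groups of
derivative cultivars bred from the focal elite line for different
objectives (e.g. grain quality versus yield). breedtrace asks, from a
SNP panel over such a pedigree: where did selection act, which haplotype
blocks of the focal cultivar were assembled when and from whom, how much
phenotypic variance do the selected QTLs explain, and what can
phenotype-based selection achieve at all under given population sizes,
heritabilities and mutation rates.

All analyses run on two S4 containers: `GenotypeMatrix` (a
`RangedSummarizedExperiment` of 0/1/2 alternate-allele dosages with
marker coordinates and line metadata) and `PedigreeGraph` (the DAG of
crosses with the trunk "pedigree flow" ordering). A synthetic-data
module (`generatePedigree()`, `simulateGenotypes()`,
`simulatePanmicticLines()`, `plantFeatures()`, `simulatePhenotypes()`)
generates panels with the statistical structure the analyses assume, so
every stage is testable without external data.

## Sweep scanning

`windowStats()` tiles each chromosome with 10-kb windows (configurable
width and step; tiles anchored at position 1 are the default for
determinism, since the original sliding-window tools do not document
their step) and computes per window the number of segregating sites
\(S\), nucleotide diversity \(\pi\) (sum of per-site mean pairwise
differences), Watterson's \(\theta_W = \sum_{seg} 1/a_1(n)\), and
Tajima's D with the 1989 variance estimate. Missing calls are excluded
per site (pairwise deletion), so the haplotype sample size \(n\) varies
by site; D's variance term uses the median per-site \(n\) over the
window's segregating sites. A heterozygous dosage contributes one
haplotype of each allele.

Two consequences of inbreeding matter here. First, a fully homozygous
line contributes two identical haplotypes, which leaves \(\pi\) roughly
unbiased but deflates \(\theta_W\) (the same segregating sites are
divided by a larger \(a_1\)), shifting D positive genome-wide; this is
the known behavior of frequency-spectrum statistics in selfing panels
and is why sweep calling uses an *empirical* quantile rather than an
absolute D threshold. Second, the neutral-calibration fixture
(`simulatePanmicticLines(..., inbred = FALSE)`) draws Hardy–Weinberg
diploids from a pool whose allele-frequency density is proportional to
\(1/p\) — the standing neutral spectrum, under which \(\pi\) and
\(\theta_W\) have equal expectation — so that genome-wide mean D on
neutral data is near zero and the test actually checks centering. The
pool's lower frequency bound defaults to 0.002, well below \(1/2n\) for
the panel sizes used, because truncating the rare tail biases D upward.

`callSweeps()` keeps windows at or below the genome-wide 5% quantile of
defined D values (computed genome-wide, not per chromosome; ties at the
threshold are included) and merges kept windows separated by at most
5 kb. `clusterTemporalPatterns()` then builds a block-by-line
conservation matrix against the focal cultivar (identity at or above
85% within the block), orders lines by approval year, clusters block
rows by average-linkage hierarchical clustering on Hamming distance,
and reports per cluster the change-point year minimizing within-segment
variance of the mean conservation profile — the four canonical patterns
are "conserved after an early year", "conserved after a late year",
"varied after a late year" and "varied throughout".

## Haplotype-block tracing

`pairwiseR2()` treats inbred lines as known-phase haplotypes
(heterozygous or missing calls excluded pairwise) and computes
\(r^2 = (p_{AB}-p_Ap_B)^2/(p_Ap_ap_Bp_b)\); monomorphic pairs are
undefined rather than zero. `findHaplotypeBlocks()` partitions each
chromosome greedily: a block extends while the candidate marker's
median \(r^2\) against the block's members is at least 0.4, and
single-marker blocks are discarded. This deterministic rule stands in
for confidence-interval block definitions whose exact algorithm is not
reproducible from their published description; the cut-off and the rule
are configurable.

`traceOrigin()` walks the trunk receptors backward from the focal
cultivar. A block stays traceable while every consecutive receptor
matches the focal genotype at \(\ge 85\%\) identity; one sub-threshold
receptor terminates the chain even if an earlier cultivar matches —
sequential inheritance is the false-positive control, since an elite
haplotype cannot skip a generation. The origin is the earliest cultivar
of the unbroken chain, attributed to that receptor's donor parent when
the donor also matches and the preceding receptor does not (the block
entered through that cross). Identity is dosage equality over jointly
called markers; a heterozygote against a homozygote counts as a
mismatch (strict, appropriate for inbreds). Blocks conserved through at
least four sequential receptor generations (`callCHTB()`; "more than
three" read strictly, configurable) are conserved traceable blocks, and
`derivativeConservation()` cross-classifies them by whether every
member of each derivative group still matches the focal genotype.

## QTL variance decomposition

`markerFilter()` applies the chip-quality filter (missing fraction
< 0.80, MAF > 0.05, both strict). `associateQTL()` is a deliberately
simple association scan — OLS of line-mean phenotype on dosage with the
top genotype principal components as covariates, an adaptive
permutation threshold, and distance-based clumping of significant
markers into peaks. It stands in for a compressed mixed model, which is
off-the-shelf machinery outside this package's scope; missing dosages
are mean-imputed for the PCA and the scan.

*Original PVE* of a QTL is the \(R^2\) of the single-marker regression.
*Corrected PVE* comes from the joint multi-locus model: QTL \(k\)
receives the share \(\hat\beta_k\,\widehat{cov}(g_k,y)/\widehat{var}(y)\),
the classical decomposition whose terms sum exactly to the full-model
\(R^2\). For a single QTL, or mutually orthogonal QTLs, each share
equals the original PVE. The share is negative when a QTL's joint-model
coefficient opposes its marginal covariance with the trait — the
suppression signature of antagonistic, LD-coupled QTLs. We use this
decomposition rather than sequential \(\Delta R^2\) because nested
least-squares \(R^2\) on common data is non-decreasing, so a
sequential definition can never produce the negative corrected PVE that
defines the complex-interaction architecture; the covariance shares
can, while keeping the same exact-sum property. One caveat is
documented rather than enforced: under suppression a share may exceed
the QTL's original PVE (enhancement), so "corrected \(\le\) original"
holds for orthogonal designs but not universally. Aliased (perfectly
collinear) QTLs are assigned a share of zero with a warning.

`classifyTrait()` operationalizes the four architecture groups from the
PVE distributions: any corrected PVE below −0.01 marks
`COMPLEX_INTERACTION` (precedence); a QTL with original PVE \(\ge\) 0.30
and no other corrected PVE \(\ge\) 0.05 is `MAJOR`; a major QTL plus a
minor one in \([0.05, 0.30)\) is `MAJOR_PLUS_MINOR`; otherwise
`LOW_PVE`. All three constants are arguments. The −0.01 threshold is
deliberately small: sampling noise alone does not push an orthogonal
QTL's share that far negative at panel sizes near 90 lines, while
genuine suppression comfortably does.

`accumulatedPVETrajectory()` sums, for each receptor along the flow,
the positive corrected PVEs of the QTLs whose favorable homozygote the
receptor carries (missing calls do not count; negative shares are
clamped for the display column and kept in a signed companion column).
`ancestralConsistency()` counts, for each cultivar with at least ten
genotyped pedigree ancestors, the recent ancestors differing at no more
than one QTL dosage — major-effect traits show high consistency,
complex-interaction traits low.

## The selection simulator

`runSimulation()` implements the classical four-module artificial
selection model: (1) an initial population of \(N\) diploids drawn in
Hardy–Weinberg proportions at each QTL; (2) phenotypes from QTL effects
plus Gaussian noise; (3) truncation selection — individuals ranked by
phenotype, the top \(1-f\) surviving (replaced fraction \(f = 0.5\) by
default, constant per run); (4) reproduction — offspring fill the
replaced slots by random mating among survivors (uniform parents with
replacement, selfing permitted, Mendelian segregation at unlinked
loci), and every transmitted allele mutates at the *modified* rate
\(\mu' = \mu \times s(\mathrm{pve}\cdot h^2)\), where \(s(\cdot)\) is an
S-shaped selection-probability curve. Mutation is directional
(unfavorable to favorable) by default, modeling selected variants
entering a breeding program; symmetric mutation is available.

Variance scale: total genetic variance is normalized to 1, QTL \(j\)
contributing \(\mathrm{pve}_j\); noise variance is
\(1/h^2 - \sum_j \mathrm{pve}_j\) — the unmodeled polygenic background
plus environment, redrawn each generation. The background is treated as
non-heritable, a simplification that makes selection on the focal QTL
slightly conservative. Allele effects are calibrated at the initial
frequency, or at 0.5 when the favorable allele starts absent or fixed
(the frequency at which a given effect size corresponds to the stated
PVE in a segregating population).

The S-curve (`selectionProbability()`) is a cubic smoothstep between
inflection points at PVE 0.10 and 0.25 with a floor of 0.05: breeders
essentially cannot see a QTL below a 10% share of phenotypic variance
and reliably select one above 25%. The exact published shape of this
curve is unavailable; smoothstep is the simplest continuous monotone
form honoring both inflections. The curve's argument is
\(\mathrm{pve}\cdot h^2\), the QTL's realized share of *phenotypic*
variance: this makes heritability act on selectability as well as on
response, which is what produces the observed collapse of progress at
\(h^2 = 0.2\).

Two defaults deserve justification. The initial favorable-allele
frequency defaults to 0: any standing favorable variation under
truncation selection fixes within tens of generations at essentially
any PVE and any population size, which would make minimum-PVE and
minimum-population-size questions degenerate; the interesting regime —
and the one the mutation-rate experiments require — is favorable
variants entering via \(\mu'\). The natural mutation rate defaults to
\(10^{-4}\) per allele per generation, the critical rate for a
1000-individual program in the experiments this simulator is built to
reproduce; it should be read as the rate at which usable favorable
variation enters the program, not a per-nucleotide point-mutation rate.

"Sufficient for breeding" is operationalized as at least half of 100
replicates fixing all QTLs (frequency \(\ge 0.99\)) within 100
generations; `minimumPVE()` scans an ascending PVE grid and stops
replicates early once a grid value's verdict is settled (which cannot
change the verdict), and `sweepExperiment()` varies population size,
heritability or mutation rate with everything else fixed. With these
conventions the minimum breedable PVE computed at \(N = 500\) lands
near 16% and at \(N = 5000\) near 11%, and the smallest sustaining
mutation rate at \(N = 1000\) for a 25%-PVE QTL near \(3\times10^{-5}\):
the qualitative orderings (larger populations reach lower PVE; breeding
periods shorten with \(N\); progress collapses at low heritability;
success is mutation-limited) all reproduce, while the absolute
thresholds sit below the published ones — under this reproduction
scheme a new favorable mutant in a strongly selected background
establishes with probability around 0.5–0.6 (a branching-process
calculation confirmed by simulation), and the unpublished details of
the original model (its reproduction algorithm, S-curve floor, replaced
fraction, success criterion) evidently imply a lower establishment
probability. We report what this model computes rather than adjusting
its free constants toward the published numbers.

## The synthetic-data generator

`generatePedigree()` mirrors the canonical shape: a trunk of receptors
(paper-scale: 9, each from a fresh donor), an optional branch merging
in as the donor of the final cross, and quality/yield derivative
groups; years advance 4–8 per generation from a configurable start.
`simulateGenotypes()` gene-drops founder haplotypes (pool frequencies
uniform on 0.05–0.95 by default) down the pedigree with Poisson
crossovers (4 cM/Mb default, no interference), fixes each child to
homozygosity (doubled-haploid equivalent of repeated selfing), biases
an expected 75% of the child genome toward the recurrent parent
(backcross-style improvement), and injects 1% residual heterozygosity
and 2% missingness so that downstream filters are exercised.
`plantFeatures()` writes ground truth into a panel: sweep regions
(post-cutoff lines overwritten with a common haplotype plus singleton
derived alleles — the low-frequency excess that drives Tajima's D
negative) and conserved blocks (trunk receptors from a chosen
generation carry the focal haplotype; all other lines get the focal
haplotype or its complement at random, so the planted region is a
detectable two-haplotype LD block, as real conserved regions are).

`simulatePhenotypes()` builds genetic values
\(G = \sum_i a_ig_i + \sum_{ij}w_{ij}(g_i/2)(g_j/2)\) with \(a_i\)
solved from the target PVE against the *realized* dosage variance
(which is \(2pq(1+F)\) in an inbred panel — calibrating against the
Hardy–Weinberg \(2pq\) would overshoot the planted PVE by up to a
factor of two), \(w_{ij}\) solved analogously from the interaction
variance on the alternate-allele dosage scale, a per-line polygenic
background making total genetic variance up to \(h^2\), and
per-replicate environmental noise of variance \(1-h^2\) (three
replicates by default, the usual randomized-block field design).
`archetypeQTLSpec()` encodes the four architecture groups; notably the
complex-interaction archetype is a repulsion-phase linked pair — a
major QTL plus a small antagonistic QTL in strong LD with it, plus a
mild negative epistatic term — because that configuration, not an
isolated epistatic product between independent loci, is what produces
robustly negative corrected PVE.

## What the synthetic panels do and do not establish

The generator reproduces the features the methods rely on: pedigree LD
and kinship, backcross-skewed inheritance, near-homozygosity with
residual heterozygosity and missingness, planted frequency-spectrum
skews, traceable blocks and calibrated QTL effects. It does not emulate
chip ascertainment bias, per-marker missingness structure, real
recombination landscapes, multi-environment phenotype structure (field
years are i.i.d. replicates here), or linked selection. Passing tests
therefore demonstrate correctness of the statistics and recoverability
of planted signal under the stated model, not performance guarantees on
any particular real panel.

## Numerical conventions and edge cases

Coordinates are 1-based inclusive internally (VCF/GFF convention);
0-based half-open only at BED boundaries. Ranking ties in the simulator
break by stable index; quantiles use R's default type 7; empty windows
yield defined \(\pi = \theta = 0\) with undefined D rather than errors;
undefined block identities (no jointly called marker) are treated as
non-conserved; monomorphic QTLs are dropped from phenotype simulation
with a warning; rank-deficient QTL sets are reported with zero shares
rather than failing. Every random routine takes an explicit seed, and
replicate \(r\) of a simulation uses `seed + r`, so all results are
bit-reproducible.

Problem sizes in the shipped tests — panels of 1,500–2,000 markers over
90–100 lines, 100 simulation replicates, PVE grids at 0.01 resolution —
are the scales at which the recovered quantities stabilize (binomial
standard error of a success fraction at 100 replicates is \(\le 0.05\));
the generator and simulator run unchanged at chip scale (tested at
22,334 markers).
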