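---
title: "Staging low-level somatic mosaicism: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging low-level somatic mosaicism: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `mosaicstage`, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The inference problem

Bulk sequencing of several tissues from one individual at ~500× depth
observes, at each candidate site, an alternate read count out of a total
depth per tissue. Three generative classes of genuine somatic variants
are distinguished by their tissue footprint:

* **early** (pre-gastrulation): one clone fraction shared by all of the
  individual's tissues, mean VAF in the several-percent range;
* **late** (post-gastrulation or post-natal): confined to one organ,
  lower VAF, with blood counts increasing with age;
* **tumor**: confined to a tumor specimen, high VAF.

Against these stand sequencing error (~10⁻³ per base), oxoG damage
artifacts (orientation-biased C>A/G>T), and systematically unreliable
regions (blacklists).

## Presence testing and reciprocal calling

The core statistic is the exact one-sample binomial proportion test: the
presence p-value at a site is P(X ≥ alt) under X ~ Binomial(depth, e),
where e is the background error rate (default 10⁻³). No normal
approximation is used at any depth. Within each tissue, p-values are
Benjamini–Hochberg adjusted across that tissue's sites and presence is
declared at adjusted p ≤ α (default 0.05).

Candidate detection is reciprocal: for every ordered pair of tissues
(A, B) of one individual, A is the case and B the control. A site is a
candidate in A when the case presence test rejects (after BH), the
control count is consistent with absence (control presence p > 0.05),
and the case clears VAF ≥ 0.005 and alt ≥ 3. The published multi-caller
ensemble is not reimplemented; its contract — a call must PASS two
independent callers — is modeled as two flags: `pass_primary` (the
case/control contrast above) and `pass_secondary` (an independent
minimum-VAF plus read-orientation-balance heuristic). Classification
requires both. The thresholds α = 0.05, VAF ≥ 0.005, alt ≥ 3 are package
defaults chosen so that a ~0.5% VAF clone is detectable at 500×; the
source study does not state its callers' internal thresholds.

A variant shared by all tissues at the same clone fraction produces no
case/control contrast and is invisible to pair calling. Such variants
are rescued by the shared-concordance track: a site present (BH-adjusted
presence) in ≥ 2 tissues with no candidate call anywhere is accepted
when, for some anchor tissue, a partner tissue's count is consistent
with the anchor VAF under a two-sided exact binomial test (p ≥ 0.05)
while also rejecting background error. Every present tissue is tried as
the anchor: anchoring only on the highest-VAF tissue biases the null
VAF upward and rejects genuine shared variants at deep coverage.

**Calibration note.** An exact binomial tail test is conservative under
strong discreteness. At depth 500 and e = 10⁻³ the expected error count
is 0.5 and the achievable type-I level at nominal α = 0.05 is 0.0144
(the tail P(X ≥ 3)); near depth 10 000 the discrete level approaches
nominal (0.0487). The acceptance suite therefore checks calibration at
depth 10 000 and conservativeness (level ≤ α) at 500×. This regime was
chosen analytically from the binomial tail, not tuned on test outcomes.

## Filter cascade

* **oxoG filter**: for C>A and G>T substitutions, the artifact-prone
  orientation (F2R1 for C>A, F1R2 for G>T) must carry < 90% of alternate
  reads whenever alt ≤ 20; higher-count calls are exempt, as orientation
  balance is then informative on its own. Other substitution classes
  always pass. A site is removed when every alt-bearing observation
  fails. The 0.9/20 cutoffs follow the spirit of the standard
  orientation-bias method; the exact values are package choices.
* **Region filters**: six BED tracks (common SNPs, segmental
  duplications, simple repeats, mappability < 0.8, off-target, UTR).
  BED intervals are 0-based half-open; site positions are 1-based
  (VCF convention), so interval [50, 200) covers 1-based positions
  51..200. Each track is recorded independently in the verdict; the
  final keep flag is their conjunction, which makes the cascade
  idempotent by construction.

## Stage assignment

Stage follows the organ tally over tissues with declared presence,
with tumor specimens never counting toward the organ set: ≥ 2 distinct
organs → early; exactly one non-tumor organ → late (including presence
in a tumor specimen plus one organ); presence only in tumor specimens →
tumor. Organ granularity is the top-level label (brain, blood, heart,
liver, other); different regions of one organ are one organ. Whether
"multiple organs" should additionally require distinct germ layers is
not decidable from the available description; this package requires
≥ 2 organs only. Per-individual counts are normalized by the number of
tissues examined.

## Signature analysis

SNVs are collapsed to the standard 96 trinucleotide channels
(pyrimidine reference; purine-reference substitutions are
reverse-complemented). De novo extraction is NMF with multiplicative
updates minimizing the generalized Kullback–Leibler divergence — the
standard objective for count catalogs — run 200 iterations (the
objective is non-increasing under these updates) from 50 random
restarts by default, keeping the lowest-error restart; signature
columns are normalized to sum to one with the scale absorbed into
exposures. The factorization of a noiseless mixture is unique only when
the planted configuration is identifiable (signatures with distinct
support, each dominating some group); the planted-recovery tests use
such a configuration deliberately, and exact permutation symmetry is
asserted by permuting the initialization together with the input.
The de novo rank defaults to 3 — one signature per stage group — and is
a parameter.

Refitting onto fixed reference signatures is non-negative least squares
(a self-contained Lawson–Hanson active-set solver; no NNLS
implementation is otherwise available in the dependency set), followed
by iterative pruning of signatures with relative contribution < 0.06 and
refitting, so reported contributions sum to one over retained
signatures. Indels are reduced to six channels — 1 bp
insertions/deletions split at reference homopolymer run length ≤ 4
vs ≥ 5, plus ≥ 2 bp insertions/deletions — sufficient to separate
polymerase-slippage-like from other indel behavior without the full
83-channel classification.

Transcriptional strand asymmetry counts, per pyrimidine substitution
type, whether the pyrimidine of the mutated pair lies on the transcribed
(template) strand — i.e. the pyrimidine strand differs from the
transcript's coding strand — and tests equality of the two counts with
a two-sided exact binomial test at p = 0.5. Exposure profiles are
clustered agglomeratively with average linkage on cosine distance, rows
sorted by label first so leaf order is deterministic.

## Selection statistics

Coding consequences come from codon substitution on the packaged
single-exon gene models under the standard genetic code. The dN/dS
model is a reduced, global-ω version of the maximum-likelihood
trinucleotide approach: counts in 192 strand-specific classes
(coding-strand trinucleotide × alternate base), with per-class rates
λ_c and a single selection coefficient ω acting on nonsynonymous
opportunity,

  n_S,c ~ Poisson(λ_c O_S,c),  n_N,c ~ Poisson(ω λ_c O_N,c),

where the opportunity tensor O counts possible synonymous and
nonsynonymous changes per class over every CDS position × 3 alternate
bases. λ_c is profiled out analytically and ω estimated by 1-D
likelihood optimization; the 95% CI is the profile-likelihood ratio
interval. No per-gene covariates and no indel ω are modeled, because
only global ratios are interpreted. With zero synonymous observations ω
is undefined and flagged rather than reported.

Atypical mutability is operationalized as a low-quantile rule: a
variant is atypical when its context's mutability score is at or below
the 0.10 quantile of the background score distribution (ties at the
quantile count as atypical, which matters when many contexts share the
minimum score). The external mutability statistic this stands in for is
not restated in the available description; the quantile rule is a
declared stand-in. pLI profiles are per-group score multisets compared
by two-sided Wilcoxon rank-sum tests.

## The synthetic world

The generator is a stated world, not a tuning dial. Defaults: 500×
depth (Poisson per site), error 10⁻³, organs brain/blood/liver per
individual plus a tumor specimen for 10% of individuals, ages uniform
0–90. Planted mutation counts are Poisson: early 0.54 per individual;
late per organ 0.67 (brain), 1.12 (liver/heart/other), and
2.0 + 0.16 × age for blood (mean ≈ 9.2 at the mid-cohort age, matching
the reported blood burden with a positive age slope; the
intercept/slope split is a package choice); tumor 8.12. Clone VAFs are
normals truncated to (0, 1]: early mean 0.0617, sd 0.0332; late 0.0150,
sd 0.0329; tumor 0.15, sd 0.05.

**Truncation note.** A normal with mean 0.0150 and sd 0.0329 truncated
at zero has analytic mean 0.0325, not 0.0150 — a coefficient of
variation above 1 is unattainable for a truncated-at-zero normal, so no
truncated normal reproduces the reported late-stage mean ± sd exactly.
The package keeps the reported parameters as the underlying normal's
parameters and tests planted-parameter recovery against the analytic
truncated mean (`truncnorm_mean()`). Consequently the realized late VAF
distribution sits higher than the reported late mean; the early/late
ordering and the order of magnitude are preserved.

Trinucleotide contexts are drawn from stage-specific mixtures of four
packaged spectra (CpG-focused C>T, a broad clock-like profile, T>C-rich,
C>A-rich); the early mixture carries extra T>C. These spectra are
generator parameters, not claims about real mutational processes.
Sites are placed uniformly over genome positions matching the drawn
context, outside blacklist tracks; in-blacklist true positives for the
filter cascade are planted separately and listed in an
expected-filtered manifest. oxoG-like artifacts are injected at a
configurable fraction of noise sites with ≥ 90% of alternate reads
forced onto the artifact-prone orientation. One seeded RNG stream per
individual keeps cohorts stable under re-ordering; identical
configuration and seed give byte-identical output.

What the generator does **not** emulate: germline variation,
copy-number events, read-level error structure (mapping, indel
realignment), position-correlated error, contamination between samples,
germ-layer structure within the early stage, and multi-region sampling
of one organ. A green classification test therefore establishes that
the statistical pipeline recovers the stated world, not that it would
reach the same operating point on real sequencing data.

## Numerical choices and degenerate inputs

* Exact binomial tails throughout; two-sided p-values follow the
  `binom.test` small-probability-sum convention.
* NMF guards denominators at 10⁻¹⁰; KL divergence treats 0·log(0) as 0.
* NNLS uses a tolerance of 10⁻¹⁰ for active-set decisions.
* Empty groups are flagged (NA), never silently dropped: zero-variance
  correlations, all-zero catalogs, zero-synonymous dN/dS, empty
  mutability groups.
* Coordinates: BED 0-based half-open, VCF and internal site positions
  1-based.
* Depth 0 observations are rejected as invalid input; the generator
  floors simulated depth at 1.

## Limitations

The dN/dS model omits per-gene rate covariates, so it should not be
used for per-gene selection claims. The consequence annotator supports
single-exon CDS models only (the packaged gene models are single-exon
by construction). The pair caller assumes identically indexed sites per
tissue, as produced by joint candidate collection. The CLI covers
simulate/run/classify; signature and selection stages on user-supplied
data are driven from R. Tumor specimens are labeled, not inferred:
tumor-status misclassification is out of scope.
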