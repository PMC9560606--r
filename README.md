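# mosaicstage

Staging and characterization of low-level somatic mosaicism from deep
multi-tissue sequencing.

## The problem

During development, somatic mutations arise in clone-forming cells and
persist at low allele fractions in one or several tissues, depending on
when and where they occurred. Mutations acquired before gastrulation seed
multiple organs and sit at relatively high variant allele frequency (VAF,
around 5–7%); mutations acquired later are restricted to a single organ
and sit lower (around 1–3%), with blood accumulating them with age
(clonal hematopoiesis). Tumor specimens carry their own high-VAF clones.
Detecting these variants from ~500× bulk sequencing of matched tissues,
separating them from sequencing artifacts, and assigning each one a
developmental stage is the job of this package.

`mosaicstage` provides, for analysts working with multi-tissue read-count
data (or entirely synthetic cohorts):

- **Reciprocal all-pairs calling** — every ordered pair of tissues of an
  individual is tested case-vs-control with an exact one-sample binomial
  presence test P(X ≥ alt | Binomial(depth, e)) against the background
  error rate e, Benjamini–Hochberg-adjusted within each tissue. The
  published multi-caller ensemble is modeled as two independent pass
  flags whose conjunction is required downstream.
- **Artifact filtering** — a read-orientation oxoG filter (C>A/G>T calls
  with ≥ 90% of alternate reads on the artifact-prone orientation at
  alt ≤ 20) and a BED blacklist cascade (common SNPs, segmental
  duplications, simple repeats, low mappability, off-target, UTR).
- **Stage classification** — presence in ≥ 2 distinct organs → *early*;
  exactly one non-tumor organ → *late*; only a tumor specimen → *tumor*.
  Shared variants invisible to the case/control contrast are rescued by a
  two-sided binomial concordance test between matched tissues.
- **Signature analysis** — 96-channel trinucleotide catalogs, de novo NMF
  (multiplicative updates, generalized Kullback–Leibler objective, 200
  iterations, restart selection), non-negative least-squares refitting
  onto reference signatures with contribution pruning, reduced indel
  channels, transcriptional strand asymmetry, and exposure clustering.
- **Selection statistics** — maximum-likelihood global dN/dS (ω) over 192
  strand-specific trinucleotide rate classes with profile-likelihood
  confidence intervals, atypical context-mutability fractions, and pLI
  profiles of mutated genes.
- **A fully seeded synthetic cohort generator** so every stage of the
  pipeline is testable with no external data: planted early/late/tumor
  clones with the stated VAF distributions, age-dependent blood burden,
  stage-specific spectra, oxoG-like artifacts and blacklist-planted true
  positives.

## Worked example

```r
library(mosaicstage)
res <- run_pipeline(cohort_config(n_individuals = 20, seed = 7),
                    nmf_restarts = 5)
res$cohort
#> mosaic_cohort: 20 individuals, 61 tissues, 228 planted mutations
#> ( early 11, late 210, tumor 7 ), 69 artifacts

res$summaries[, c("group", "n_variants", "per_individual_norm",
                  "vaf_mean", "age_count_r")]
#>        group n_variants per_individual_norm vaf_mean age_count_r
#> 1      early         13               0.217   0.0671     -0.0497
#> 2       late        189               3.112   0.0352      0.7167
#> 3      tumor          7               1.750   0.1424          NA
#> 4 late_blood        145               2.388   0.0369      0.7019
#> 5 late_brain          9               0.150   0.0306      0.1626
#> 6 late_liver         35               0.575   0.0293      0.3070

res$validation$per_stage
#>   stage n_tested n_confirmed precision n_truth recall
#> 1 early       13          11     0.846      11  1.000
#> 2  late      189         178     0.942     210  0.848
#> 3 tumor        7           7     1.000       7  1.000
```

Reading the output: early variants are few, shared across organs and sit
at ~6.7% mean VAF; late variants are organ-private, sit lower (~3.5%),
and their count correlates strongly with age in blood (r ≈ 0.70) — the
clonal-hematopoiesis pattern the generator plants. The validation table
compares the classification against the generator's truth records:
per-stage precision is the fraction of classified variants whose planted
stage matches, recall the fraction of planted mutations recovered.
Reference-signature refitting and the dN/dS module run on the same
output (`res$refit`, `res$selection`).

A command-line interface is installed with the package
(`inst/cli/mosaicstage`):

```sh
mosaicstage simulate --out cohort/ --seed 1 --individuals 20
mosaicstage run      --out run1/   --seed 1 --individuals 20
mosaicstage classify --calls cohort/ --blacklists cohort/ \
                     --meta cohort/tissues.tsv --out cls/
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
model of every stage, the tunable parameters with their defaults, what
the synthetic world does and does not emulate, and known limitations.
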