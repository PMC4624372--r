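---
title: "Quantifying and classifying seminal fluid proteomes under sperm competition"
author: "SFPquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying seminal fluid proteomes under sperm competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Male house mice (*Mus musculus domesticus*) adjust ejaculate production to
social cues: encountering more rival males (a cue of sperm-competition risk)
shifts both sperm production and the protein composition of seminal fluid,
while encountering more females (a cue of mating opportunities) does not.
Testing this requires a chain of quantitative-proteomics and statistical
machinery: label-free peptide intensities must be rolled up to protein
abundances, normalised so samples are comparable, restricted to the proteins
that are actually ejaculated, and then asked — as a single multivariate
question — whether seminal fluid *composition* differs between treatment
groups, with per-protein statistics and morphometric analyses alongside.

`SFPquant` implements that chain end to end:

1. **Top3 quantification** (`top3Quantify()`): protein abundance per sample
   is the arithmetic mean of the protein's three most abundant peptides.
2. **Minimum-peptide filter** (`filterMinPeptides()`): only proteins with at
   least three quantified peptides are analysed.
3. **Normalisation** (`normaliseAbundances()`): median-log-ratio scaling to
   a reference run, over either all proteins or a reference set of
   ejaculated proteins.
4. **Reference subset** (`subsetReference()`): restriction to the secreted
   proteins that could act in the female tract.
5. **Replicated random-forest classification** (`replicatedRF()`): 10,000
   trees per model, 1,000 model replicates, permutation significance,
   variable-importance (VI) selection, proximity MDS and outlier scores.
6. **Univariate statistics** (`screenDifferential()` and friends): Welch
   t-tests with Benjamini–Hochberg q-values, one-way ANOVA screening, fold
   changes, and complete-linkage clustering preparation for heatmaps.
7. **Morphometrics** (`factorialAnova()`, `mixedModelLRT()`): 2×2 general
   linear models of sperm-production measures, and mixed models with an
   enclosure random intercept tested by likelihood ratio.

A synthetic generator (`simulatePeptideTable()`, `simulateMorphometrics()`)
reproduces the statistical structure of the 2×2 design so that every stage
is testable without access to external data.

## The data model

The central container is `ProteinQuant`, a `SummarizedExperiment` with one
`abundance` assay (protein × sample, non-negative, arbitrary intensity
units), per-protein peptide counts in `rowData()`, the sample sheet
(`sc_level`, `mr_level`, `enclosure_id`) in `colData()`, and the
normalisation state (`none`, `all_proteins`, `reference_set`) recorded in
`metadata()`. Replicated-forest output is an `RFSummary` object with
accessors (`medianOOBError()`, `permutationP()`, `viTable()`,
`importantSet()`, `proximityMatrix()`, `mdsCoords()`,
`outlierScoreTable()`).

```{r}
library(SFPquant)
sim <- simulatePeptideTable(simConfig(seed = 1))
pq  <- top3Quantify(sim$peptides, sim$metadata)
sec <- subsetReference(
  normaliseAbundances(filterMinPeptides(pq), "reference_set",
                      sim$reference),
  sim$reference)
fit <- replicatedRF(sec, colData(sec)$sc_level, rfConfig(seed = 1))
```

## Quantification choices

**Top3 ranking.** Peptides are ranked once per protein by their mean
abundance across *all* samples (ties broken by peptide ID), not re-ranked
per sample. A fixed peptide set makes the per-sample values comparable;
re-ranking would let different peptides stand in for the protein in
different samples. The measure is therefore invariant to anything that
happens to peptides ranked fourth or lower. Proteins with fewer than three
peptides are quantified from all available peptides and carry their peptide
count with them; the filter, not the quantifier, decides whether they are
analysed. Missing (peptide, sample) combinations are abundance 0, matching
the complete matrices that label-free exports produce.

**Normalisation.** Commercial label-free packages normalise samples by a
proprietary ratio-to-reference procedure. The deterministic analogue
implemented here: pick as reference run the sample whose log-ratio
distributions to all other samples have minimal total variance (ties go to
the first sample in column order); scale every sample by the exponential of
the median log-ratio of reference to sample over the normalisation protein
set. Zero abundances are excluded from medians (avoiding −∞) but retained
as zeros in the abundance matrix (absence is signal). After normalisation
the median log-ratio of any sample to the reference run is zero over the
normalisation set, and re-running the operation changes nothing (checked to
1e-10 in the tests).

Normalising to the *ejaculated reference set* rather than to all proteins is
the conservative mode: if high-competition males develop larger seminal
vesicles, the ratio of secreted (luminal) to tissue proteins may shift
wholesale, and an all-protein normalisation would convert that composition
shift into spurious per-protein effects.

**The reference set** is the list of 31 secreted seminal-vesicle proteins
known to be transferred to the female at ejaculation that overlap the
quantified proteome (`secretedReferenceSet()`), shipped with the package
together with the published per-protein VI and t-test summary
(`referenceVITable()`).

## The replicated random-forest analysis

A single random forest is stochastic, so one fit is not a result. The
analysis refits the model `nReplicates` times (default 1,000, each with
10,000 trees) under independent derived seeds and summarises:

* **Error.** The out-of-bag (OOB) error is reported as the *lower median*
  across replicates — the lower of the two central order statistics when the
  count is even — so the reported error always corresponds to a realisable
  confusion count out of the n samples, which is also reported
  (e.g. "22 correct : 8 incorrect").
* **Significance.** The permutation test refits one forest per permutation
  of the class labels (default 1,000) and reports the fraction of permuted
  models with OOB error at or below the observed median. Nesting a full
  replicate set inside every permutation would multiply cost a
  thousand-fold without materially changing the tail estimate. A
  `(count+1)/(n+1)` smoothed p-value is reported alongside the raw
  fraction.
* **Variable importance.** Per protein, the mean decrease in OOB accuracy
  when that protein's values are permuted, averaged over replicates, with a
  95% CI (percentile across replicates by default; a normal-approximation
  variant is available because the published interval type is not
  documented). Raw mean-decrease (in percentage points) and the SE-scaled
  variant are both reported: absolute VI magnitudes are
  implementation-specific, so all selection and comparison logic works on
  ranks. A protein is *important* when its mean VI strictly exceeds the
  absolute value of the lowest mean VI — the most negative score is pure
  noise, so its magnitude is a data-driven noise threshold.
* **`mtry` tuning.** Starting from `round(sqrt(p))`, candidates are halved
  and doubled stepwise while the relative OOB improvement is at least 5%,
  each candidate evaluated once under a derived seed; ties go to the
  smallest value. Tuning runs once per analysis, not per replicate.
* **Proximity, MDS, outliers.** The mean proximity matrix (fraction of
  trees in which two samples share a terminal node) feeds classical
  (Torgerson) MDS on `1 − proximity`; axes are sign-fixed so the first
  non-zero loading is positive. The outlier score of sample *i* is
  `n_class / Σ_{j≠i} proximity(i,j)²` over classmates, standardised within
  class by median and MAD; standardised scores above 10 are flagged. When a
  class MAD is zero, zero deviations standardise to zero; a class of size
  one is not evaluable.

Seeds everywhere derive from one master seed through a counter scheme
(`deriveSeed()`), so replicate *k* is reproducible regardless of execution
order and permutations never share a stream with replicates.

## Univariate statistics

The published workflow reported multiple t-tests with Benjamini–Hochberg
q-values alongside the forest. The t-test variant was not stated; Welch
(unequal variances) is the default here, with a `var.equal` switch. Tests
run on normalised, untransformed abundances (matching the published
heatmap's "un-transformed normalised abundances"); a `log10Transform`
option exists for sensitivity analysis, and the same option governs the
ANOVA screen because the in-package screening ANOVA of the original
software may or may not log-transform internally. With two groups the
equal-variance ANOVA F is exactly t², which the tests verify to 1e-10.
Fold changes are ratios of arithmetic group means (high over low
competition). Heatmap preparation averages all biological replicates per
treatment group — the original figure averaged replicates "based on prior
analyses" that are not reproducible from the publication — then row-scales
to mean 0, SD 1 and clusters rows and columns with Euclidean distance and
complete linkage.

## Morphometrics

Sperm-production measures (paired testes mass in g, epididymal sperm count
and daily sperm production in millions, seminal-vesicles mass in g) are
summarised as cell means ± SEM and analysed with a fixed-effects 2×2 ANOVA
with interaction; the design is balanced, so sequential and marginal sums
of squares coincide (F₁,₂₈ at n = 32; F₁,₂₇ with one male excluded). The
published phrase "log-transformed as appropriate" does not say which
measures were transformed, so both scales are available and raw is the
default. Enclosure structure (males share enclosures within a
sperm-competition level) is handled by a linear mixed model with a random
enclosure intercept; fixed terms are tested by likelihood-ratio tests
between ML fits with and without the term (ML is required for LRTs;
variance components are reported from the REML refit). Singular fits (zero
enclosure variance) are reported as such and the LRT still computed.

## What the generator emulates — and what it does not

`simConfig()` defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| `nProteins` | 383 | proteins identified in the study tissue |
| `nSecreted` | 31 | ejaculated proteins in the quantified set |
| `dynamicRangeOrders` | 6 | observed abundance span (decades) |
| `groupSizes` | 7/7/8/8 | proteomics samples per 2×2 cell (n = 30) |
| `enclosureSize` | 4 high-SC, 2 low-SC | males per enclosure |
| `plantedEffects` | SVS 6 ×1.6, SVS 5 ×1.5, CEACAM 10 ×1.4, cathepsin D ÷1.6, annexin A5 ÷1.4 | published directions; magnitudes in the reported 1.2–1.6× band |
| `noiseCV` | 0.6 per (peptide, sample) | calibrated so the protein-level CV after Top3 averaging (≈ CV/√3 ≈ 0.35) matches the between-male variability implied by the published per-protein t statistics |
| `sampleScaleSD` | 0.2 (sdlog) | per-sample loading spread, so normalisation has real work to do |
| `peptideFactorSD` | 0.5 (sdlog) | fixed per-peptide response factors |
| peptides/protein | shifted geometric, min 1; secreted min 3 | calibrated so the expected number of proteins passing the 3-peptide filter is 147 of 383; secreted seminal-fluid proteins are abundant and well-covered, and the study's reference proteins were by construction all retained |
| morphometric means/SDs | published cell means, SEM·√8 | the study's Table of sperm-production parameters; n = 8 males per cell |

The abundance of peptide *j* of protein *i* in sample *s* is

`base_i × peptideFactor_j × foldEffect_i(group_s) × scale_s × noise_js`

with log-uniform `base`, log-normal factors and mean-1 log-normal noise.
Consequences worth knowing: fold effects multiply every peptide of a
protein equally, so noise-free recovery through Top3 + normalisation is
*exact* (the tests assert equality to 1e-10); planted proteins are a
minority of the normalisation set, so the median log-ratio ignores them.

Deliberately **not** emulated: peptide-level missingness beyond absence of
a peptide from a protein, shared peptides and protein-inference ambiguity,
retention-time drift, correlated protein modules, and heavy-tailed
intensity error. Passing tests on synthetic data therefore demonstrate the
statistical machinery, not robustness to those real-data pathologies.

## Numerical and degenerate-input conventions

* Zero abundances: excluded from log-ratio medians, kept in Top3 averages;
  an all-zero protein quantifies as 0 and is retained.
* A sample whose whole normalisation set is zero is an error naming the
  sample; an empty reference intersection is an error.
* Vote ties in per-sample predictions break by class-label order; `mtry`
  ties by smaller value; peptide-rank ties by peptide ID.
* Degenerate tests (zero variance in both groups, constant ANOVA response)
  return p = 1 with a flag rather than `NaN`.
* MDS with more axes requested than positive eigenvalues returns the
  available axes with a warning.
* All result tables serialise numbers at 6 significant digits, and two runs
  with the same master seed are byte-identical (asserted in the tests).

## Problem sizes used in the tests and acceptance script

The shipped checks scale the replicated analysis down so the whole suite
runs in minutes on one CPU: the end-to-end synthetic checks use 100–1,000
trees and tens to hundreds of replicates (e.g. the null-calibration
experiment runs 50 experiments × 200 permutations of 100-tree forests; the
VI-recovery experiment 100 seeds of 500-tree forests), and
`scripts/acceptance.R` runs 200 replicates × 1,000 trees with 200
permutations per label. These are the package's chosen sizes for routine
verification; the full-scale configuration (10,000 × 1,000 × 1,000) is the
`rfConfig()` default for real analyses.

## Known limitations

* The reproduction checks against the original study's quantified tables
  require those supplementary downloads to be supplied by the user
  (`?studyDataFile`); they are not redistributable here.
* VI magnitudes are not comparable across random-forest implementations;
  only ranks and the thresholded set are meaningful surfaces.
* The permutation p-value resolution is `1/nPermutations`; with 1,000
  permutations, p below 0.001 is reported as 0 (the smoothed variant never
  is).
* The mixed models fit a single random intercept; crossed or nested designs
  beyond enclosure-within-treatment are out of scope, as are sperm-motility
  (CASA) analyses and anything upstream of the peptide table (spectra,
  identification, alignment).
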