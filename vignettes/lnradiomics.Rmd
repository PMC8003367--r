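---
title: "Methods: ADC histogram radiomics and decision-tree prediction of nodal metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADC histogram radiomics and decision-tree prediction of nodal metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnradiomics)
```

## The problem and the modelling idea

In endometrial cancer the decision to perform a pelvic lymphadenectomy rests
on the preoperative probability of lymph-node (LN) metastasis. On
diffusion-weighted MRI (DWI), metastatic nodes tend to be larger and to show
restricted diffusion — lower apparent diffusion coefficient (ADC) — than
benign nodes, but single-threshold criteria on node size or mean ADC are only
modestly accurate. The workflow implemented here combines computer-aided node
segmentation, first-order ADC histogram radiomics of the node, the tumor and
their relation, and standard-of-care clinical variables into interpretable
binary decision trees, evaluated per pelvic sidewall ("region"): each patient
contributes a left and a right region, and a patient is positive iff at least
one region is.

The package covers the full chain: synthetic image and cohort simulation →
seeded region-growing segmentation → 109-parameter feature extraction →
fixed printed rules and de-novo CART fitting → diagnostic-accuracy
evaluation. All quantities the tests assert are computed by this code at test
time.

## Segmentation and morphometry

Nodes are bright on DWI, so region growing runs on the DWI-contrast volume
while histogram statistics are taken from the co-registered ADC map. The
growth rule is the simplest reproducible variant: queue-based growth from a
seed voxel with an *adaptive-mean* acceptance test — a candidate is accepted
when its intensity lies within `tolerance` of the current region mean, the
mean being updated at every acceptance. Each voxel is examined once, in FIFO
order, with face connectivity (6-neighbourhood in 3-D) by default; `full`
(26-neighbourhood) is available. The result always contains the seed and is
connected by construction. On two-level images the adaptive-mean test reduces
to a fixed threshold test, which is what the brute-force flood-fill oracle in
the tests exploits. `tolerance` is a free parameter with no universal
default; for the bundled phantoms (DWI contrast 100 per 1e-3 mm²/s of ADC) a
tolerance of 15–40 separates node from background cleanly, and the noiseless
phantom suite requires Dice ≥ 0.95 against the geometric truth masks.

Morphometry follows the radiologic convention of in-plane measurement:
on the largest-area axial slice (ties → lowest slice index), the long axis is
the maximal pairwise distance between voxel centres, the short axis the
maximal extent perpendicular to the long-axis direction, and the area the
voxel count × in-plane pixel area. Degenerate cases are defined rather than
rejected: a single-voxel slice takes the voxel footprint (long = larger
in-plane spacing, short = smaller), a one-voxel-wide line takes the smaller
in-plane spacing as its short axis. Whether the original tool measured in 2-D
or 3-D is not documented anywhere we could find; the in-plane convention was
chosen because the 1.7 mm and 5 mm criteria are short-axis conventions from
axial reading.

## The feature vector

Four ADC classes are computed per region: tumor ADC (`ADCt`), node ADC
(`ADCln`), and two relative classes. `rmADC` is the histogram of per-voxel
absolute differences from the tumor mean, `{|v − mean(tumor)|}`. `rADC` is
defined statistic-wise, `|stat(LN) − stat(tumor)|` for each of the 12
statistics: node and tumor contain different voxel counts, so no voxel
pairing exists, and the statistic-wise reading is the one under which a
quantity like "skewness of the relative ADC" is well defined. This is the
main interpretive decision in the package.

Each class yields 12 first-order statistics: mean, min, max, the
10/25/50/75/90th percentiles, skewness, kurtosis, SD and variation
(coefficient of variation). Moments use population (n) normalisation —
skewness m₃/m₂^1.5, kurtosis m₄/m₂² (not excess) — with a `bias_correct`
flag for the sample-adjusted forms. Percentiles interpolate linearly between
order statistics; the choice is documented because most node regions contain
fewer than 100 voxels, where percentile conventions differ materially.
Constant input defines SD, skewness, kurtosis and variation as 0.

Bladder normalisation (`nADC`) divides by the mean ADC of the bladder ROI
(urine as a stable reference; median available). Only the unit-carrying
statistics (mean, min, max, percentiles, SD) are divided; skewness, kurtosis
and variation are scale-free and pass through unchanged. This makes the 48
`nADC` features exactly the statistics of bladder-normalised voxel values,
and therefore exactly invariant under a global rescaling of all ADC inputs —
an invariance the tests check to 1e-10. Dividing the dimensionless statistics
too would destroy that invariance, which is why that (superficially simpler)
reading was rejected.

The full vector is 48 raw + 48 normalised + 6 anatomical (tumor volume; node
area, long axis, short axis, mean diameter, axis ratio) + 7 clinical
(histology, grade, tumor size, low-segment involvement, deep myometrial
invasion, MR-reported node status, CA-125) = 109 named entries with a stable
schema (`feature_dictionary()`).

## Decision rules and CART

All trees share one convention: an internal node tests `feature < cutoff`,
so printed cutoffs act as strict `<` on the low side and `≥` on the high
side (a node of exactly 5 mm is negative under the `> 5 mm` short-axis
model). The published figure giving the exact RadScore branch topology is not
recoverable from text, so the default topology — size gate, then tumor-ADC
gate, then the skewness disjunction — was chosen to be consistent with both
published false-negative case audits and with the clinical statement that
grade 1 disease under 20 mm excludes metastasis; any alternative topology can
be supplied as a JSON tree without code change. The grade dichotomy follows
the grade 3 vs 1–2 grouping used by the demographic tables (the abstract's
"1 vs 2 and 3" contradicts them and was set aside). RadSignature composes
the RadScore with the clinical gate by rule (re-fitting a tree on RadScore +
clinical variables is available through `fit_cart` but is not the default,
as composition is the only reading that makes the rule nest inside
RadScore).

`fit_cart` is an original CART implementation: greedy binary splitting
maximising weighted Gini decrease over midpoints between adjacent distinct
values (ties → first feature in schema order, then lower cutoff; leaf ties →
negative class), followed by weakest-link cost-complexity pruning on
weighted misclassification risk, keeping a subtree only if its risk
improvement per added leaf exceeds `cp` × root risk. Controls default to
`cp = 0.01`, `minsplit = 5`, `maxdepth = 4`. The class weights of the
"weighted" tree are nowhere stated; the default is inverse prevalence
(configurable), the standard remedy for 7% positive prevalence.
`repeated_cv` performs 10×10-fold stratified cross-validation over a cp
grid, re-pruning per-fold full trees, selecting the risk-minimising cp (ties
→ larger cp; 1-SE rule optional, off by default). The procedure is
deterministic given data and seed. rpart implements the same family of
estimators and serves as an independent cross-check in the tests, never as
the implementation.

## Synthetic data: what it emulates and what it does not

`generate_phantom` builds 3-D ellipsoids (background, tumor, bladder, node
lesions) on a regular grid, voxel membership by centre inclusion, ADC drawn
per structure from Gaussians on the 1e-3 mm²/s scale the clinical cutoffs
use (background ≈ 1.4, tumor ≈ 0.9, metastatic node ≈ 0.85, urine ≈ 3.0).
DWI intensity is an affine decreasing function of ADC plus Gaussian noise —
enough to exercise segmentation; no b-value physics, bias fields or
distortion are simulated. Default grid 64×64×16 at 0.5×0.5×3 mm, matching
pelvic DWI anisotropy.

`generate_cohort` draws a 236-patient / 472-region cohort: patient
positivity 9.7%, one positive region per positive patient plus a second with
probability 10/23, reproducing 33 positive regions per 23 positive patients
(region rate 7.0%). Covariates are drawn class-conditionally from the
published demographic counts, so the marginals (grade 3: 18.6%,
non-endometrioid: 7.2%, deep invasion: 23.3%, low segment: 58.5%, size ≥
20 mm: 59.3%) are recovered automatically; the tests check them against
binomial 99% intervals at n = 2000. Class-conditional ADC variances and
node-size distributions are published nowhere, so defaults were chosen once
to straddle the printed cutoffs (node short axis log-normal around 1.2 mm
benign / 3.0 mm metastatic; tumor ADC 1.15 vs 0.90; node ADC 1.30 vs 0.95)
and are flagged as synthetic conventions. CA-125 is log-normal with a
class-specific location: the published means carry SDs several times their
size, so only directionality is preserved. FIGO stage is derived as IB iff
deep myometrial invasion is present — a documented convention needed for
risk grouping. Consequently, passing tests demonstrate correct arithmetic
and recovery of the *assumed* structure; they say nothing about real-data
performance, which requires the original images.

### Cutoff identifiability in the recovery experiment

`generate_rule_labelled_regions` draws features uniformly and labels them by
a known tree rule, leaving an exclusion band of half-width 2% of the feature
range around every cutoff the rule uses (`gap_frac`). The band is what makes
"recovering the cutoff" well posed: every threshold inside the band labels
the data identically, so the cutoff is identifiable only up to the band, and
a greedy Gini tree converges to the band *edge* (just above the last
positive case) rather than its centre. Recovery error is therefore measured
as the distance from the recovered cutoff to the band; the tests require
each first split to land within one band half-width of the band over fixed
seeds, and the median over 20 seeds to stay below half the gap width. Two
further properties of greedy CART are worth knowing: with a disjunctive rule
(A or B) the greedy order of the two skewness splits can swap in a small
fraction of samples, displacing one cutoff beyond its band while training
accuracy stays ≥ 0.99; and with asymmetric class weights the preferred
boundary shifts a few sample spacings toward the lighter class. Neither is a
defect of the implementation — rpart behaves identically.

## Evaluation choices

The published tables do not name their CI method; exact Clopper–Pearson
intervals reproduce every printed bound pair to one decimal (e.g. 22/23 →
78.1–99.9%, 14/14 → 76.8–100.0%), which the acceptance suite verifies for
all 28 table rows, so that method is used, with one-sided exact bounds at
0/n and n/n and undefined metrics reported as `NA` rather than errors. The
McNemar test is the exact binomial version — two-sided p = min(1, 2 × smaller
tail) — which reproduces the printed p = 0.0313 and 0.0156 for 6:0 and 7:0
discordance patterns; the χ² approximation does not. The DeLong comparison
uses placement values with tie correction (ties count ½); its variance is
checked against a 10,000-replicate bootstrap of the AUC difference at
n = 30, using the median ratio over five replicate datasets to damp the
sampling noise of a single draw. Percentages are formatted by half-up
rounding to one decimal (`as_pct`), matching the tables where banker's
rounding does not (16.25 → 16.3). The bootstrap resamples regions by default
with a patient-cluster option, since the original resampling unit is
unstated; replicates without positive cases are skipped and counted. The
70/30 split is stratified at patient level with per-class training counts
`round(fraction × n_class)`, which lands exactly on 165/71 patients and 16/7
positives for 236 patients with 23 positives.

## Problem sizes and determinism

Test and acceptance runs use the study-scale sizes where the check is about
bookkeeping (236 patients, 472 regions) and n = 5000 regions × 20 seeds for
parameter recovery; oracle-equivalence suites run ≥ 100 randomised small
instances per operation. Every stochastic step is seeded: generators take an
explicit seed in their spec, `scripts/acceptance.R` derives all of its seeds
from `--seed`, and identical pipeline configurations produce byte-identical
metrics files.

## Known limitations

- The RadScore/RadSignature topology is a reconstruction constrained by the
  published case audits, not a copy of the original figure; alternative
  topologies load from JSON.
- First-order histogram features only; higher-order texture is deliberately
  out of scope (most node ROIs are under 100 voxels).
- Phantoms are ellipsoids with Gaussian tissue classes; no MR artifact
  simulation, no DICOM ingestion, and DWI/ADC volumes are assumed
  voxel-aligned (no registration).
- Real-cohort quantities that depend on the original images (dataset-level
  AUCs, the headline sensitivities) are not reproducible from synthetic data
  and are not claimed; the package validates arithmetic, printed-rule logic
  and recovery of known synthetic structure.
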