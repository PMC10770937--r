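---
title: "Spatial features of tissue-resident memory T-cell subsets and the TRM spatial immune signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial features of tissue-resident memory T-cell subsets and the TRM spatial immune signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmspatial)
```

## The scientific problem

CD103+CD8+ tissue-resident memory T (TRM) cells patrol epithelial
tissues and are thought to be the primary responders to checkpoint
immunotherapy, yet their reported prognostic effect in non-small cell
lung cancer is inconsistent. One plausible reason is heterogeneity:
TRM cells differ both in functional state — graded by their
co-expression of the immune checkpoints PD-1 and Tim-3 — and in where
they sit relative to cancer cells. Multiplex immunofluorescence (mIF)
resolves both at single-cell resolution: each segmented cell carries a
position, a tissue-compartment label (epithelium vs stroma), a tumor
region label (tumor center, TC, vs invasive margin, IM) and binary
marker calls.

`trmspatial` takes such per-cell tables and asks, per patient: how
abundant is each TRM subset, how deeply does it infiltrate the
epithelium, and how closely does it engage cancer cells — and then
whether a compact signature built from those spatial features predicts
disease-free survival (DFS) after surgery.

## Phenotypes

Composite phenotypes are pure functions of one cell's marker calls.
CK+ cells are cancer cells; cells co-staining CK and CD8 are treated
as segmentation artifacts and classified as cancer, which keeps the
cancer-cell set disjoint from every immune set entering a distance
computation. Among CK- cells, CD8+CD103+ cells are TRM, CD8+CD103-
cells TnonRM, and TRM splits into a partition of four functional
subsets by checkpoint co-expression:

| subset | PD-1 | Tim-3 | interpretation |
|--------|------|-------|----------------|
| TRM1 | - | - | quiescent |
| TRM2 | + | - | pre-dysfunctional, most cytotoxic |
| TRM3 | - | + | intermediate |
| TRM4 | + | + | terminally dysfunctional |

GZMB deliberately stays out of the subset definitions: the GZMB+
fraction of a subset is its cytotoxicity *readout*
(`gzmb_positive_fraction()`), not part of its identity.

## The four spatial features

For phenotype $A$ within one patient-region (distances in µm,
Euclidean, both compartments pooled):

* **Density** $\mathrm{Dens}(A) = n(A)/n(\text{total}) \times 1000$ —
  abundance per 1000 segmented cells. The denominator is all
  segmented cells of the patient-region, both compartments.
* **Infiltration score** $\mathrm{InS}(A) = n(A)^{epi}/n(A)^{stro}$ —
  epithelial vs stromal partitioning. A zero stromal count makes the
  ratio undefined; it propagates as missing (flagged
  "undefined-infinite" via `is_infinite_ins()`) and is median-imputed
  only inside the modelling stage, so the raw metric stays honest.
* **Mean nearest-neighbour distance**
  $\mathrm{mNND}(A{\sim}C) = \sum_i d_{\min}(A_i{\sim}C)/n(A)$ — the
  average distance from each $A$ cell to its nearest cancer cell;
  larger values mean weaker engagement.
* **Cancer-cell proximity score**
  $\mathrm{CCPS}(A) = \sum_i n(C_i \xrightarrow{r} A)/N(C)$ — the mean
  number of $A$ cells within radius $r$ of each cancer cell.

The proximity radius $r$ defaults to 20 µm — a cell-contact-scale
neighbourhood of one to two cell diameters, consistent with reading
CCPS as direct tumor-immune interaction — and is configurable and
recorded in every output. The distance computations are vectorized
and blocked to bound memory; they agree with a naive double loop to
within floating-point rounding (this equivalence is asserted over
random configurations in the test suite). No edge correction is
applied at core boundaries, and all cells of a region are pooled into
one pattern; if a patient contributed several physical cores per
region, per-core averaging would be a different (unimplemented)
choice.

`compute_feature_vectors()` evaluates the grid of 58 candidate
features: Dens for 11 phenotypes × 2 regions, and InS/mNND/CCPS for
{TRM, TnonRM, TRM1–TRM4} × 2 regions.

## The TRM spatial immune signature

`build_signature()` chains the construction:

1. **Split** — patients are randomized 7:3 into training and testing
   sets (`split_cohort()`; 274 patients give 192/82). The function
   reports training events per candidate variable and warns below the
   10-EPV heuristic.
2. **Importance ranking** — on the training set only, features are
   median-imputed, standardized and ranked by three learners, all
   fitted on the survival outcome rather than a binarized label:
   penalized Cox (LASSO, penalty by tenfold cross-validation,
   importance = |coefficient|), gradient boosting under the Cox
   partial-likelihood objective (importance = mean gain over
   bootstrap refits; 1000 refits by default — rankings stabilize well
   below that, so the validation runs in this package use 100–200),
   and a random survival forest (permutation importance). Ties break
   lexicographically so rankings are reproducible.
3. **Intersection** — the features common to all three top-10 lists
   (`intersect_top10()`), ordered by mean rank. Requiring consensus
   of three structurally different learners is a deliberately
   stringent guard against overfitting a single method's biases.
4. **Cut-points** — each selected feature is dichotomized at the
   threshold maximizing the two-group log-rank statistic over all
   observed values that leave at least 10% of patients on each side
   (`find_cutoff()`; smallest threshold on ties). This is the core
   operation of cut-point software such as X-tile. No multiplicity
   correction is applied inside the search, so p-values *at the
   chosen cut* are optimistic — the signature's honesty rests on
   test-set evaluation, not on those p-values.
5. **Weights and score** — each indicator $X_i$ gets the weight
   $\ln(\mathrm{HR}_i)$ from a univariate Cox fit on the training
   set, and patients are scored as
   $\mathrm{SIS} = \sum_i \ln(\mathrm{HR}_i)\, X_i$. The high/low SIS
   threshold comes from the same cut-point search applied to the
   training SIS values (the median would be a defensible simpler
   choice; the cut-point search was chosen for consistency with the
   per-feature dichotomization).

Dichotomizing before the univariate Cox fits (rather than fitting
continuous features) matches the construction order implied by
signatures of this form, whose published weights are group contrasts
(hazard ratios like 0.41 or 2.04). All statistics needed for scoring
— imputation medians, cut-offs, weights, SIS threshold — are frozen
from the training set; `score_patients()` never recomputes them, and
the test suite asserts that mutating scored data cannot change the
model.

## Survival evaluation

`km_logrank()` (Kaplan–Meier + two-sided log-rank), `cox_models()`
(univariate screens at α = 0.05, then backward elimination by
likelihood-ratio tests until all retained covariates have p < 0.05)
and `combined_model()` (SIS group + stage as a joint Cox linear
predictor) follow standard practice; α is two-sided 0.05 throughout
with no multiplicity correction. Median survival "not reached" is
reported as missing with a flag rather than a number.

`time_dependent_auc()` implements the cumulative-case /
dynamic-control AUC with inverse-probability-of-censoring weighting
(IPCW): at horizon $t$, cases are patients with an observed event by
$t$ (weight $1/\hat G(T_i^-)$), controls those event-free past $t$
(weight $1/\hat G(t)$), with $\hat G$ the Kaplan–Meier estimate of
the censoring distribution. This flavor was chosen because it is the
standard for fixed-horizon prognostic scores; with no censoring it
reduces exactly to the empirical AUC (asserted in tests). The default
horizons are 12, 36 and 60 months. By default the *continuous* SIS is
scored; pass the binary group instead if a group-level AUC is wanted.

## The synthetic cohort generator

No per-cell cohort of this design is publicly deposited, so the
package ships a generator (`synthetic_config()`, `generate_cohort()`)
whose defaults encode the cohort structure the analysis assumes, and
whose planted parameters make every stage testable by recovery:

* **Geometry** — two 600 µm square regions (TC, IM) per patient;
  epithelium is the union of 6 random disks (radius ≈ 90 ± 15 µm,
  ≈ 40% area fraction), the simplest geometry giving both
  compartments a well-defined mask, hence an exact InS ground truth.
  ≈ 1500 cells per region (negative binomial), 274 patients —
  a cohort generates in seconds on one CPU.
* **Phenotype frequencies** — ≈ 35% cancer cells confined to the
  epithelium; CD8+ ≈ 25% of non-cancer cells; TRM fractions of CD8+
  of 0.60 (TC) and 0.37 (IM); subset mixes per region with TRM1
  dominant and TRM2 rare; GZMB+ rates highest in TRM2 and lowest in
  TRM4. A patient-level latent factor tilts the CD103, PD-1, Tim-3
  and GZMB rates jointly on the logit scale, reproducing their
  positive patient-level correlation.
* **Spatial placement** — immune cells mix a compartment-uniform
  kernel (epithelium affinity graded TRM1/2 < TRM3/4) with a
  cancer-attracted Gaussian kernel (SD 15 µm; attraction probability
  graded 0.10 → 0.50 from TRM1 to TRM4), so subset mNND decreases and
  CCPS/InS increase from TRM1 to TRM4 by construction.
* **Survival** — DFS is exponential under a proportional-hazards
  model whose linear predictor combines planted effects on spatial
  features *computed from the realized point pattern* (standardized
  across the cohort; default: a protective CD103-density effect in TC
  with HR 0.41 and a harmful TRM4-infiltration effect in IM with HR
  2.04) and planted stage effects (HR 1.85 / 3.10 vs stage I).
  Planting on realized features, not latent parameters, means
  recovery targets are exactly what the pipeline measures. Censoring
  is independent uniform over a 24–96 month follow-up window (median
  60 months, a mature surgical cohort), and the baseline hazard is
  rescaled by root finding so the realized event fraction hits the
  39.4% target — keeping both the event rate and the five-year
  evaluation horizon well defined.
* **Panel 2** — per-patient CD31+ (microvessel) rates are drawn from
  a Gaussian copula against the TRM-abundance factor with
  configurable correlation (default −0.4), while Hif-1α rates are
  independent of TRM placement.

What the generator does *not* emulate: real nest morphology (nests
are disks, not branching glands), segmentation and marker-calling
errors, per-core heterogeneity within a region, spatial clustering of
immune cells among themselves, and any non-proportional-hazards
structure. Passing tests therefore demonstrate that the pipeline
recovers what it measures under its own assumptions — not that those
assumptions hold in any particular tissue.

## Validation at desk scale

The test suite validates each stage against independent references:
brute-force oracles for mNND/CCPS (100 random patterns, 1e-9 relative
tolerance), hand-computed product-limit and log-rank fixtures, exact
SIS arithmetic against the published weight structure, and
simulation-based recovery: the two planted features (|ln HR| = 0.8)
survive the triple top-10 intersection in ≥ 80% of 25 replicates
(n = 300 patients, 500 cells per region — cells scaled down from the
default because selection operates on patient-level features, where
n_patients, not cells per region, carries the information); a planted
HR of 2.4 is estimated within [1.8, 3.2] in ≥ 90% of 25 replicates at
n = 274; all-noise cohorts yield test-set log-rank rejections at
≤ 10%; and a random score's IPCW AUC stays in [0.45, 0.55] at
n = 1000. `scripts/acceptance.R` reruns these measurements from a
fresh seed and writes them as JSON.

## Numerical and degenerate-input choices

* Empty denominators are missing values, never zero: GZMB fraction of
  an empty subset, InS with zero stromal count, mNND/CCPS with no
  cancer cells, features of an absent region.
* Cut-point search requires ≥ 10% of patients per side; a constant
  feature (no admissible cut) is an error at the operation level and
  a dropped feature (with warning) inside `fit_signature()`.
* A constant feature gets importance 0 in every ranking; a univariate
  Cox fit that fails or returns |ln HR| > 10 drops its feature.
* Coordinates are written at 0.01 µm precision, which round-trips
  exactly; cohort assembly is order-independent.
* Spearman correlations need ≥ 3 complete pairs and non-constant
  margins; otherwise the coefficient is missing.

## Limitations

The cut-point search inherits the optimism of all maximally selected
statistics; only test-set quantities should be quoted. The IPCW AUC
assumes censoring independent of the score. The generator's defaults
are one plausible parameterization of an operable-NSCLC cohort, not a
fitted model of any dataset; conclusions about real tissue require
real per-cell tables, which the IO layer accepts directly.
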