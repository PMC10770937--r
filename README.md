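# trmspatial

Spatial phenotyping of CD103+CD8+ tissue-resident memory T (TRM) cells
in multiplex immunofluorescence (mIF) data, and a TRM-based spatial
immune signature (TRM-SIS) for disease-free survival in resected
non-small cell lung cancer.

TRM cells are heterogeneous in both functional state and position.
`trmspatial` is for researchers who have per-cell tables from mIF
image analysis (one row per segmented cell: patient, tumor region,
tissue compartment, x/y in µm, binary marker calls) and want to
quantify that heterogeneity per patient and test whether it predicts
outcome.

## What it computes

**Phenotypes.** Cancer cells (CK+), cytotoxic T cells (CD8+CK−), TRM
(CD8+CD103+), TnonRM (CD8+CD103−), and the partition of TRM into four
functional subsets by immune-checkpoint co-expression: TRM1
(PD-1−Tim-3−), TRM2 (PD-1+Tim-3−), TRM3 (PD-1−Tim-3+), TRM4
(PD-1+Tim-3+). The GZMB+ fraction of a subset is its cytotoxicity
readout.

**Four spatial features** per phenotype *A*, patient and region
(tumor center TC / invasive margin IM):

- density, Dens(A) = n(A)/n(total) × 1000 (cells per 1000 cells);
- infiltration score, InS(A) = n(A)ᵉᵖⁱ / n(A)ˢᵗʳᵒ;
- mean nearest-neighbour distance to cancer cells,
  mNND(A∼C) = Σᵢ d_min(Aᵢ∼C)/n(A) (µm);
- cancer-cell proximity score, CCPS(A) = Σᵢ n(Cᵢ →ʳ A)/N(C), the mean
  number of A cells within radius r (default 20 µm) of each cancer
  cell.

**The signature.** `build_signature()` splits patients 7:3, ranks the
58 candidate features on the training set by penalized Cox (LASSO),
gradient-boosted Cox and random survival forest, intersects the three
top-10 lists, dichotomizes each surviving feature at its maximally
selected log-rank cut-point, and weights the indicators by their
univariate Cox log hazard ratios:

    SIS = Σᵢ ln(HRᵢ) · Xᵢ

Evaluation tools: Kaplan–Meier/log-rank, uni/multivariate Cox with
backward elimination, IPCW time-dependent ROC AUC at 12/36/60 months,
and a SIS + stage combined model. A seeded synthetic-cohort generator
(`generate_cohort()`) with planted spatial and survival effects makes
the whole pipeline testable by parameter recovery.

## Worked example

```r
library(trmspatial)

cfg <- synthetic_config(n_patients = 120, cells_per_region_mean = 800, seed = 11)
sim <- generate_cohort(cfg)
sim$cohort
#> <trm_cohort> 120 patients, 193445 cells (panel1)
#>   cells per region: TC=98252, IM=95193

round(sim$features[1:3, c("Dens.TRM.TC", "InS.TRM4.IM", "mNND.TRM.TC", "CCPS.TRM.TC")], 2)
#>   Dens.TRM.TC InS.TRM4.IM mNND.TRM.TC CCPS.TRM.TC
#> 1       81.83          NA       74.41        0.64
#> 2       98.27           5       56.25        0.48
#> 3       86.47          NA       41.84        0.47
```

Patient 1 has 81.8 TRM per 1000 cells in the tumor center, sitting on
average 74 µm from the nearest cancer cell, with 0.64 TRM within 20 µm
of an average cancer cell; the `NA` marks an undefined
epithelium/stroma ratio (no stromal TRM4 in that region), carried as
missing rather than zero. Building and evaluating the signature (this
cohort plants a harmful TRM4-infiltration effect, HR 2.04, and a
protective CD103-density effect, HR 0.41):

```r
bs <- build_signature(sim$features, sim$cohort$clinical, seed = 11, n_boot = 200)
bs$model
#> <trm_sis> 3 features, SIS cut-off -2.336
#>            feature   cutoff    HR  weight
#> 1      InS.TRM4.IM  4.00000 6.187  1.8225
#> 2 Dens.GZMB_CD8.TC 26.75585 0.097 -2.3360
#> 3     Dens.TRM3.TC  8.04829 0.184 -1.6939

te <- bs$scores$set == "test"
clin <- sim$cohort$clinical
km_logrank(bs$scores$risk_group[te], clin$dfs_months[te], clin$dfs_event[te])$p_value
#> [1] 0.02953935
```

The triple intersection recovered the harmful planted feature
directly (`InS.TRM4.IM`) and the protective CD103-density effect
through two tightly correlated proxies (GZMB+CD8+ and TRM3 densities
track CD103 via the generator's shared latent factor — at n = 120 the
learners cannot always separate a feature from its proxies). The
high/low SIS split still separates test-set survival (log-rank
p = 0.03). Training-set hazard ratios are optimistic by construction
(maximally selected cut-points); only test-set quantities should be
quoted. At n = 300 the planted features themselves are recovered in
≥ 80% of replicates — that measurement is what `scripts/acceptance.R`
reports as `selection_recovery_rate`.

Real data enter through `read_cell_table()`, `read_clinical_table()`
and `assemble_cohort()`; see the vignette
(`vignettes/trm-spatial-signature.Rmd`) for the model, parameter and
design details.

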