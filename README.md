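# smbplsr

Sparse multi-block partial least squares regression (sMBPLSR) for
multi-omics data fusion, built for feeding-intervention studies that
profile the same animals on several platforms at once: untargeted LC-MS
metabolomics of plasma, urine and feces, targeted short-chain fatty acid
(SCFA) panels, and 16S taxa relative abundances. The package classifies
samples into diet groups or time points across all blocks jointly, selects
the features that drive the separation, and quantifies how features from
different blocks correlate.

## The method

Each block `X_b` (samples x features) is Pareto-scaled (centered, divided
by the square root of the feature SD) and normalized by its Frobenius norm
so blocks of any size and unit enter on the same footing. PLS2 is fitted by
NIPALS to the concatenated superblock against the class indicator matrix
`Y`; per component, the loading weight vector `w` is soft-thresholded to a
chosen *degree of sparsity* `g` (the fraction of entries forced to zero)
and renormalized, so variable selection happens during fitting:

    w = X'u / ||X'u||,  w <- soft_threshold(w, g),  t = Xw,
    q = Y't / t't,      u = Yq / q'q,               (iterate)
    p = X't / t't,      X <- X - tp',  Y <- Y - tq'

Block scores `t_b = X_b w_b` sum to the global score exactly, and super
weights `||w_b||^2` (summing to 1 per component) give each block's share.
The degree of sparsity is optimized per component and the number of latent
variables `A_opt` chosen by a one-standard-error rule, both under
leave-one-subject-out cross-validation (all samples of one animal form a
test fold; every scaling statistic is estimated on the training fold only).
Selected biomarkers — the features with nonzero regression-coefficient
rows — are confirmed univariately by one-way ANOVA on log intensities, and
correlation-loading / rank-2 correlation analytics describe the selected
variables in the plane of the first two latent variables.

Supporting tools cover the rest of the workflow: feature-table I/O with QC
and blank injections, QC-based signal-drift correction, blank and m/z /
retention-time filters, block alignment by sample correspondence, consensus
PCA for unsupervised overview, SCFA aggregate arithmetic and diet
energy-contribution calculations, plus a synthetic multi-block study
generator with planted ground truth for validating the whole pipeline.

## Worked example

Simulate a study at the default design (2 diets x 15 subjects x 3 weeks,
three metabolomics blocks of 200 features with 20 planted diet markers
each), preprocess, cross-validate, and check marker recovery:

```r
library(smbplsr)

sim <- simulate_study(sim_config(), seed = 2026)
tabs <- lapply(sim$blocks, function(t)
  blank_filter(suppressWarnings(qc_drift_normalize(t))))
mb <- align_blocks(tabs)
#> align_blocks: dropped 10 sample(s) from block 'plasma'  (per-block missingness)

cv <- cross_validate(mb, "class_label", ncomp_max = 2)
cv
#> Leave-one-subject-out CV (classification): 29 folds
#>   A_opt = 1; degree-of-sparsity path: 0.5
#>   SR_CV = 100.0% (MCR = 0.000)
#>   confusion matrix (true x predicted):
#>     predicted
#> true HR LR
#>   HR 37  0
#>   LR  0 37

model <- smbplsr(mb, "class_label", ncomp = cv$ncomp_opt,
                 sparsity = cv$g_path[seq_len(cv$ncomp_opt)])
round(model$super_weights, 3)
#>          LV1
#> plasma 0.296
#> urine  0.274
#> feces  0.430

bm <- select_biomarkers(model)
head(bm[, 1:3], 3)
#>    feature_id block coef_max_abs
#> 1 feces_F0004 feces     4.134300
#> 2 feces_F0009 feces     2.644816
#> 3 feces_F0072 feces     2.189688

recovery_metrics(bm, sim$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 0.2105263
```

Reading the output: `SR_CV` is the cross-validated success rate (fraction
of held-out samples assigned to the right diet), `A_opt` the selected
number of latent variables, and the degree-of-sparsity path the per-
component fraction of weights forced to zero. Super weights show the fecal
block carrying the largest share of the discriminative signal here. All 60
planted markers are recovered (`recall = 1`); the moderate precision
reflects the mild sparsity degree the error curve selected — correlated
cluster-mates of true markers enter alongside them.

Diet-composition arithmetic works standalone:

```r
diet_energy_contribution(diet_spec(424, 119, 177, 188))
#> carbohydrate          fat      protein        fiber
#>         41.7         37.9         11.7          8.7
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/smbplsr-cli.R` (subcommands `simulate`, `fit-cv`,
`biomarkers`, `corrloadings`, `dietcalc`).

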