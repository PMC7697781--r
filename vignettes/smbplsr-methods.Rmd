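---
title: "Sparse multi-block PLS for multi-omics data fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multi-block PLS for multi-omics data fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-term feeding interventions are often profiled on several platforms at
once: untargeted LC-MS metabolomics of plasma, urine and feces (each in
positive and negative electrospray ionization), a targeted short-chain
fatty acid (SCFA) panel, and 16S-derived taxa relative abundances. Each
platform yields a samples-by-features table ("block") with its own units,
feature count and missing samples. The scientific questions are shared:
which diet (or sampling week) does a sample belong to, which features drive
the separation, and how do features from different blocks correlate with
each other and with the design?

`smbplsr` answers these with sparse multi-block partial least squares
regression (sMBPLSR): a PLS2 model fitted to the column-wise concatenation
of normalized blocks, with soft-thresholded weight vectors that perform
variable selection during fitting, assessed by leave-one-subject-out
cross-validation.

# The model

## Preprocessing chain

Each block $X_b$ ($n \times p_b$) passes through, in order:

1. **QC drift correction** (`qc_drift_normalize`, optional): per feature, a
   trend (linear by default, loess with span 0.75 as an alternative) is
   fitted to the pooled-QC intensities against injection order; every
   injection is divided by the fitted trend at its own order and the feature
   is rescaled so its QC median is exactly preserved. Features with fewer
   than two usable QC values, or a non-positive fitted trend, pass unchanged
   with a warning. Note that preserving the raw-run QC median means the
   correction removes the drift *gradient* but not the run's overall level;
   comparisons across runs should be made relative to the QC median.
2. **Blank filtering** (`blank_filter`): a feature is removed when its mean
   intensity in blank injections reaches `ratio_threshold` (default 1) times
   its mean in study samples. The default says: anything as intense in a
   solvent blank as in a sample is contamination or carry-over.
3. **Mass / retention-time windows** (`mz_rt_filter`): features with
   $m/z$ strictly above `mz_max` (e.g. 700 Da for a QTOF run) or retention
   time outside the chromatographic window are dropped; the boundary itself
   is kept, and features lacking the metadata pass unchanged.
4. **Sample correspondence** (`align_blocks`): QC and blank injections are
   dropped, the blocks are restricted to the intersection of their sample
   ids (a sample missing from one block is removed from all), and samples
   are ordered lexicographically by subject then time point. The multi-block
   model requires an identical sample sequence in every block;
   the lexicographic order is a determinism choice, nothing more.
5. **Pareto scaling** (`pareto_scale`): each column is centered and divided
   by the *square root* of its sample standard deviation. Compared with
   autoscaling this damps, rather than removes, the dominance of
   high-intensity features; a scaled column has variance equal to the
   original standard deviation. Zero-variance columns are centered only.
6. **Frobenius normalization** (`frobenius_normalize`): each block is
   divided by $\|X_b\|_F = \sqrt{\sum_{ij} x_{ij}^2}$ so blocks of very
   different size and unit enter the model on the same footing. No
   additional scaling by the number of variables is applied.

Steps 5–6 happen inside the fitting functions and their statistics are
frozen in a `ScalingState`; new samples (and cross-validation test folds)
are always transformed with the training statistics, never their own.

The Pareto-then-Frobenius order is a design choice: scaling features first
and then equalizing whole blocks keeps the block weighting interpretable as
"every block contributes unit total variance-like mass", whatever its
feature count.

## Sparse NIPALS with block bookkeeping

Let $X = [X_1 | \cdots | X_B]$ be the preprocessed superblock and $Y$ the
response: a 0/1 indicator matrix of class memberships (columns in sorted
class order) for classification, or a numeric matrix for regression, both
column-centered. Per component $a = 1, \dots, A$:

1. Initialize $u$ as the $Y$ column of maximal variance.
2. Iterate until the relative change of $t$ falls below $10^{-10}$ (cap 500
   iterations, with a warning and the last iterate on failure):
   $w = X^\top u / \|X^\top u\|$; $w \leftarrow s_g(w)$ (soft threshold,
   below); $t = X w$; $q = Y^\top t / t^\top t$; $u = Y q / q^\top q$.
3. $p = X^\top t / t^\top t$; deflate $X \leftarrow X - t p^\top$,
   $Y \leftarrow Y - t q^\top$ (standard PLS2 deflation of both matrices by
   the super score).

The soft-threshold operator $s_g$ with degree of sparsity $g \in [0, 1)$
keeps $k = \max(1, \mathrm{round}((1-g)\,p))$ entries: with $\lambda$ the
$(k{+}1)$-th largest $|w_j|$, $w_j' = \mathrm{sign}(w_j)\max(|w_j| -
\lambda, 0)$, renormalized to unit length. Entries tied exactly at
$\lambda$ shrink to zero, so fewer than $k$ may survive; if a tie removes
everything, the first index among the largest magnitudes is retained and
the event logged. Sparsity is imposed on the *concatenated* super-weight
vector with one degree per component — the data decide how selection
distributes over blocks.

Block bookkeeping falls out of the concatenation: the block score
$t_{b,a} = X_b w_{b,a}$ (so $t_a = \sum_b t_{b,a}$ exactly) and the super
weight $\omega_{b,a} = \|w_{b,a}\|^2$ (so $\sum_b \omega_{b,a} = 1$). The
literature offers multi-block variants with block-wise deflation or a
second-level regression of the super score on block scores; the
concatenated form is chosen here because Frobenius normalization already
puts blocks on one footing and because it directly yields the global
scores, block scores and super weights that the analyses report. Deflation
by the super score keeps score vectors exactly orthogonal regardless of
sparsity.

Regression coefficients are $B = W (P^\top W)^{-1} Q^\top$ on the
preprocessed scale; prediction applies the frozen scaling state to new
blocks, computes $\hat Y = X_{new} B$ plus the stored $Y$ centering, and in
classification takes the argmax over class columns (exact ties go to the
first class in sorted order, logged).

Consensus PCA (`cpca`) provides an unsupervised overview in the same shape:
an SVD of the preprocessed superblock, with block scores $X_b v_{b,a}$ and
super weights $\|v_{b,a}\|^2$.

## Model selection

Cross-validation is leave-one-subject-out: all samples of one subject (all
time points) form a test fold, so a model is never judged on an animal it
has seen. All preprocessing statistics are estimated per training fold and
applied frozen to the held-out subject — the test samples influence nothing.

The degree of sparsity is optimized greedily per component: with
$g_1, \dots, g_{a-1}$ fixed, each candidate $g$ in the grid (default
$\{0, 0.5, 0.8, 0.9, 0.95, 0.99\}$; the choice spans dense to 1%-retained
models on a roughly logarithmic scale of retained fraction) is scored by
the pooled cross-validated misclassification rate (MCR) of the
$a$-component model, and the minimizer is fixed. Ties go to the smallest
(least sparse) degree — when the data cannot distinguish, we prefer to
discard less. An exhaustive search over $g$-paths would be exponential; the
greedy search matches the one-degree-per-component structure.

The number of latent variables $A_{opt}$ is the smallest $A$ whose error
does not exceed $\min_A \mathrm{MCR}(A)$ plus one standard error (fold-wise
standard deviation at the argmin over $\sqrt{n_{folds}}$). The headline
$\mathrm{SR}_{CV} = 1 - \mathrm{MCR}$ uses predictions pooled over folds;
fold-wise errors are kept for the standard error. A formal paired test
(McNemar) between candidate models is a reasonable alternative
operationalization of "not significantly higher"; the one-SE rule is used
because it needs no extra assumptions and is standard practice for
error-curve selection.

Two small opposing biases of this protocol are worth knowing about. Holding
a subject out leaves the training classes slightly imbalanced, which tilts
the argmax rule against the held-out subject's class (a conservative,
below-chance push on null data); and reporting the CV error at the
error-minimizing sparsity degree is slightly optimistic. Both shrink with
the number of subjects and largely offset at the default design; the
package's calibration tests measure the net effect on label-shuffled data.

## Biomarker statistics

A feature participates in a sparse model exactly when its row of $B$ is
nonzero; `select_biomarkers` reports those features per block, ordered by
largest absolute coefficient (a dense model triggers a warning — selection
is meaningless there). Univariate confirmation (`anova_log`) is classical
one-way ANOVA on natural-log intensities (zeros replaced by half the
column's smallest positive value), with $p \le 0.05$ flagged. The grouping
factor is the classification target, pooling over the other design factors;
a stratified analysis adjusting for time within diet (or vice versa) is out
of scope, and pooling makes the test conservative when the other factor
adds variance.

Correlation loadings place each variable at its Pearson correlations
$(r_1, r_2)$ with the first two score vectors; the unit circle (100%
explained by the plane) and the $\sqrt{0.5}$ circle (50%) are the reference
radii. The rank-2 correlation analysis replaces each selected variable by
its orthogonal projection onto $\mathrm{span}(t_1, t_2)$ and computes
pairwise Pearson correlations of the projections with two-sided p-values
from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom. The
projection restricts attention to the two summarized dimensions but does
not reduce the sample count, so $n - 2$ is the natural default; a
conservative $n - 3$ (one fewer for the rank-2 restriction) is available
via `conservative_df = TRUE`. These correlations are invariant to any
invertible reparameterization of the score plane.

# The synthetic-data generator

`simulate_study` draws complete studies with the structure the analysis
assumes, standing in for deposited instrument data. The default design is
the study's: 2 diet groups × 15 subjects × 3 time points (90 samples per
block before missingness). Per metabolomics block (defaults in
parentheses): log-normal intensities with feature-level means spread around
a baseline log-mean (10) and log-SD (0.6); features correlated in
block-diagonal clusters (size 10, $\rho = 0.5$) emulating adduct/isotope
families; diet markers (20) shifted by $\pm\Delta$ log-SD
($\Delta = 1.5$) in one diet; time markers (10) with a monotone trend
spanning $\Delta$ log-SD across the three weeks; QC injections (8) at the
pooled profile; blank-only features (10); a multiplicative linear intensity
drift over injection order (slope 0.3, i.e. +30% across the run); and
samples missing independently per block (rate 0.05), exercising the
sample-correspondence step. Feature count defaults to 200 per block — far
below a real untargeted table, but large enough to dominate the sample
count and exercise selection; tests and the acceptance script use this
scale so the whole suite runs on a desktop in minutes. The SCFA panel
plants diet multipliers (acetic 1.3, propionic 1.4, n-butyric 1.5,
iso-acids 0.7 in the resistant-starch diet — the qualitative pattern
expected when fermentable starch reaches the colon) on realistic fecal
baselines with log-normal noise. Taxa are compositional via a
logistic-normal construction (softmax of Gaussian log-abundances, $\sigma =
1$) with five diet-shifted taxa; a Dirichlet alternative was considered and
rejected because logistic-normal allows correlated log-abundances, closer
to real 16S tables.

Ground truth (planted marker ids and signs) accompanies every draw, and
`recovery_metrics` scores a selection against it (recall, precision, false
discovery proportion).

What the generator does **not** emulate: retention-time structure and
peak-shape artifacts, adduct mass relationships (clusters are correlation-
only), heteroscedastic technical noise, subject-level random effects
(samples of one subject are conditionally independent given the design),
batch boundaries, and censored/missing individual cells. Passing tests
therefore demonstrate that the pipeline recovers the planted low-rank
class structure under realistic dimensionality, correlation, drift and
missingness — not that it handles every pathology of real LC-MS data.

# Numerical choices and degenerate inputs

* NIPALS convergence: relative score change $< 10^{-10}$, cap 500
  iterations; non-convergence is a warning, not an error.
* Degenerate responses (no variance left in $Y$), vanishing weight vectors
  and singular $P^\top W$ raise errors naming the component.
* Soft-threshold ties and prediction ties resolve to the first index and
  are always logged.
* Zero-variance columns are centered only; zero-norm blocks are an error.
* Missing intensities are explicit `NA` at I/O time, never imputed
  silently; the modelling functions refuse `NA` and say so.
* `round()` (banker's rounding) defines $k$ in the soft threshold.
* Energy percentages are computed exactly from the FAO factors
  (carbohydrate and protein 17, fat 37, fiber 8 kJ/g) and rounded to one
  decimal at the end; with the study's compositions the carbohydrate share
  comes out 0.1 below some published roundings, and the stated formula is
  deliberately preferred to reverse-engineering a denominator.
* In fecal SCFA sums, "butyric acid" means n-butyric only; iso-forms count
  toward the branched-chain total.

# Known limitations

* The concatenated-superblock variant with super-score deflation is one of
  several multi-block PLS formulations; block-wise deflation can give
  different block scores for later components.
* Univariate ANOVA pools over non-target design factors and ignores the
  repeated-measures correlation within subject; it is a screening
  confirmation, not a substitute for a mixed model.
* The argmax classification rule has a small bias against the held-out
  class under leave-one-subject-out CV with near-balanced designs (see
  above); with few subjects, interpret null-adjacent success rates
  accordingly.
* Figures are plain base-graphics side artifacts; nothing downstream parses
  them.
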