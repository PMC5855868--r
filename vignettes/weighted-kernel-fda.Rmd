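---
title: "Weighted-kernel Fisher discriminant analysis for chemosensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-kernel Fisher discriminant analysis for chemosensor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkfda)
```

## The problem

An electronic nose pairs an array of partially selective gas sensors with a
pattern-recognition pipeline.  Each exposure yields one response curve per
sensor; a scalar summary per sensor (here the response maximum, or the
minimum for conductance-decrease sensors) gives a feature vector per
observation.  Metal-oxide sensors respond nonlinearly to analyte
concentration, so class structure in these feature tables is typically not
linearly separable, and linear reducers (PCA, Fisher discriminant analysis)
leave information on the table.  Unsupervised reducers have a second
weakness: sensor arrays carry strong class-irrelevant covariation
(temperature, humidity, baseline wander), which dominates the leading
variance directions.

`wkfda` implements feature extraction by kernel Fisher discriminant
analysis (KFDA) with a *weighted composite* kernel, the composite's mixing
weights and base-kernel parameters tuned by quantum-behaved particle swarm
optimization (QPSO), plus the standard baselines and the two evaluation
protocols used for single-batch and multi-batch (drifting) sensor data.

## Model

### Kernel Fisher discriminant analysis

With observations $x_1,\dots,x_N$ in $C$ classes and an implicit feature
map $\phi$, FDA in feature space maximizes
$\lambda = w^\top S_B w / w^\top S_W w$.  Writing $w = \phi(X)\alpha$ and
assuming feature-space centering, the problem reduces entirely to the
centered Gram matrix $\tilde K$ ($\tilde K = HKH$, $H = I - J/N$):

$$(\tilde K B \tilde K)\,\alpha = \lambda\,(\tilde K \tilde K)\,\alpha,$$

where $B$ is block diagonal with blocks $\tfrac{1}{N_i}\mathbf 1_{N_i
\times N_i}$ for class-contiguous samples (`build_block_b()`; samples are
reordered internally and results mapped back).  Training projections are
$Y = \tilde K A$ and a new point $z$ projects through its centered
cross-kernel vector, $g = A^\top \tilde k_z$.  At most $C-1$ informative
discriminants exist; the default output dimension is $\min(3, C-1)$, the
conventional choice when comparing three-dimensional score plots across
methods.

Numerical choices: $\tilde K \tilde K$ is rank-deficient, so the
right-hand side is ridged with $\mu = 10^{-8}\,\mathrm{tr}(\tilde K\tilde
K)/N$ and the pencil solved by Cholesky reduction to a symmetric
eigenproblem.  Coefficients are normalized to $\alpha^\top \tilde K
\alpha = 1$ (unit-norm discriminants in feature space), eigenvector signs
are fixed by making the largest-magnitude entry positive, and the reported
eigenvalues are the Rayleigh quotients recomputed from the unregularized
matrices, so they satisfy the defining identity to solver precision.  The
same ridge-and-reduce strategy, with $\mu = 10^{-8}\,\mathrm{tr}/p$, is
used for explicit-space FDA (where $S_W$ is singular whenever $N < p$) and
for LPP.

### Weighted composite kernels

Nonnegative combinations of Mercer kernels are Mercer kernels, so
$k = \sum_{m=1}^{n} p_m k_m$ with $p_m \ge 0$ is a valid kernel for any
bank of gaussian or polynomial bases.  Weights are clipped to $[0,\infty)$
and normalized to $\sum p_m = 1$ on construction: the Fisher quotient is
invariant to positive rescaling of $K$, so the overall scale is a spurious
search dimension.  Sigmoid kernels are accepted although they are not
positive semidefinite for all slopes/offsets; `check_psd()` reports the
minimum eigenvalue rather than rejecting, matching their common empirical
use.  PSD verification uses the finite criterion (minimum eigenvalue
$\ge -10^{-8}\max(1, \lambda_{\max})$), the double-precision eigensolver
noise floor.

### The QPSO search

The headline method tunes the weights $p_m$ and the base-kernel
parameters.  QPSO is used in its canonical formulation: per particle, an
attractor $p = \phi\,\mathrm{pbest} + (1-\phi)\,\mathrm{gbest}$ and the
jump $x' = p \pm \beta\,|m - x|\ln(1/u)$ around the personal-best mean
$m$, with $\beta$ annealed linearly from 1.0 to 0.5 and box constraints
enforced by clipping.  Defaults (swarm 20, 100 iterations, patience 20)
follow common QPSO practice.  The search space is the $n$ weights in
$[0,1]$ plus, when parameter optimization is on, one parameter per base on
a transformed scale: $\log_2 \sigma^2 \in [-4, 4]$ for gaussian banks,
offset $c_1 \in [0,3]$ with degrees fixed at $1..n$ for polynomial banks,
$\log_{10}\beta_0 \in [-3, 1]$ with $\beta_1 = -1$ for sigmoid banks.
When parameters are not searched, banks sit on fixed grids
(`default_kernel_bank()`): $\sigma^2 \in 2^{-3}..2^{3}$ geometrically,
degrees $1..n$, $\beta_0 \in 10^{-2}..10^{0}$.

The fitness of a candidate kernel is one minus the stratified $k$-fold
cross-validated accuracy of the pipeline *KFDA projection $\to$ RBF-SVM*
on the training partition only — the standard wrapper objective in
multiple-kernel learning; no test data is ever touched during the search.
Fold assignments are drawn once per fit, so the objective is deterministic
within a search and the whole fit is reproducible under a seed.  Because a
cross-validated objective is noisy at e-nose sample sizes (tens of
observations), two refinements are available: repeated cross-validation
(`cv_repeats`) averages the objective over independent fold assignments
at proportional cost, and the swarm is warm-started at the equally
weighted default grid bank and (gaussian banks) at the plain-KFDA
median-distance kernel, so the search always contains its own sensible
initialization.  The desk-scale comparison suite uses a single fold
assignment with five folds, which keeps a full five-method, ten-seed
comparison within minutes on one core.  Candidate evaluations that fail (degenerate all-zero
weights, eigen-solver breakdown in a fold) score the worst fitness and the
swarm moves on.

## Synthetic study conditions

Neither motivating dataset is public, so the generators emulate their
*structure*, and all empirical claims in this package are claims about
these synthetic conditions, not about the original measurements.

**Wound-like design** (`simulate_wound_dataset()`): 4 classes x 20
observations x 15 sensors, features = response maxima, matching the
published 80 x 15 shape.  Response curves follow a rise-plateau-decay
envelope with a saturating log concentration response and small
per-timepoint gaussian noise (SD 0.05).  Class geometry is chosen so the
set is not linearly separable: classes 1-2 have distinct sinusoidal gain
profiles with isotropic spread (SD 0.25), while classes 3-4 share one mean
profile and differ only in the radius of a spherical shell around it
(radii 0.35 and 1.4 with 10% log-normal jitter) — a concentric pair that
only a nonlinear decision surface can resolve.  Two nuisance mechanisms
emulate real arrays: a per-observation log-normal intensity factor
(SD 0.05, uncontrolled headspace concentration) and three additive
interference factors with fixed random loadings (SD 0.6 each,
correlated baseline/environmental variation).  The interference variance
was sized so that, as in published e-nose comparisons, unsupervised
reducers (PCA, LPP) are dominated by class-irrelevant variance and fall
clearly below the supervised methods, while the concentric pair keeps
FDA below kernel FDA.  Under these conditions the package reproduces the
qualitative published ordering QWKFDA >= KFDA > FDA and
KFDA > max(PCA, LPP) in at least 7 of 10 experiment seeds.

**Drift design** (`simulate_drift_dataset()`): 4 gases x 10 evenly spaced
concentration levels x 5 batches of 128 observations x 8
conductance-decrease sensors (features = response minima), matching the
640 x 8 shape.  Batches 2..5 receive per-sensor multiplicative gain
(`1 + N(0, 0.04)`) and additive offset (`N(0, 0.04)`) perturbations
relative to the unperturbed reference batch 1; the final batch gets five
times both SDs, emulating one severely drifted device.  Gas gain profiles
are deliberately close (sinusoid contrast 0.3 against a 12% per-sample
gain jitter) so that batch-1-trained classifiers transfer at 96-100% to
the mildly drifted batches while the high-drift batch drops visibly —
the qualitative signature of published multi-batch gas benchmarks, where
one device drifts far below its siblings.

What the generators do *not* emulate: real sensor chemistry and
cross-sensitivities, humidity/temperature covariates, temporal aging
within a batch, and the actual class-response profiles of the original
instruments (which are unpublished; the synthetic profiles are openly
stand-ins).  Passing tests therefore demonstrate correctness of the
algorithms and the plausibility of the qualitative method ordering under
controlled nonlinearity and drift — not performance on the original data.

## Evaluation protocols

* `repeated_holdout_evaluate()`: stratified 50/50 hold-out repeated 10
  times (both defaults configurable); the extractor is fitted on the
  training partition only, an RBF-SVM (`e1071`, cost 10, gamma = 1/d,
  features standardized with training statistics) is trained on the
  extracted features, and per-split accuracies are reported with their
  mean and sample (n-1) standard deviation.
* `batch_transfer_evaluate()`: fit once on a designated training batch,
  one accuracy per remaining batch plus their arithmetic mean.
* Confusion matrices use rows = predicted class; accuracy is
  orientation-invariant.  Displayed percentages are rounded half-up to
  two decimals (`round_half_up()`); machine-readable outputs keep full
  precision.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data
at desk scale: the 80 x 15 wound-like instance with 10 hold-out repeats
per experiment seed and 10 experiment seeds; QPSO benchmark suites of 20
seeded runs (5-D sphere, swarm 30, 200 iterations); 20-50 randomized
instances for the oracle-equivalence and Mercer-closure properties; and a
desk-scale QWKFDA search (3 gaussian bases, swarm 10, 15 iterations,
5-fold CV) inside the method-comparison harness.  These
sizes were chosen as the smallest at which the qualitative claims are
stable across seeds.

## Known limitations and open choices

* The dense Gram-matrix eigenproblem is $O(N^3)$; no low-rank or
  out-of-core path is provided (out of scope).
* Whether test-point projections should be centered with training
  statistics is ambiguous in parts of the discriminant literature; this
  package centers cross-kernel vectors consistently with the training
  Gram matrix, so projecting the training set through the out-of-sample
  path reproduces the training scores exactly.
* LPP neighborhood size (5) and heat bandwidth (mean squared pairwise
  distance) are field-standard defaults; supervised LPP variants are out
  of scope.
* The QPSO objective could optionally extend to classifier
  hyperparameters; the search vector here covers kernel weights and
  parameters only, with the classifier fixed, keeping the comparison
  against plain KFDA interpretable.
* With very small per-class counts the stratified CV folds inside the
  fitness can hold a single sample of a class; `cv_folds` should not
  exceed the smallest class size.

## A minimal session

```{r example, eval = FALSE}
data <- simulate_wound_dataset(seed = 1)
cmp <- compare_extraction_methods(data, repeats = 10, seed = 101)
round(cmp$mean_accuracy, 2)

fit <- fit_qwkfda(data$X, data$labels,
                  qwkfda_config("gaussian", n_bases = 3,
                                qpso = list(swarm_size = 10,
                                            max_iters = 15)),
                  seed = 7)
scores <- predict(fit, data$X)
```
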