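---
title: "Benchmarking binary classifiers on metabolomics feature tables: models, optimisation and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking binary classifiers on metabolomics feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabench)
```

## The problem

Clinical metabolomics studies routinely reduce to a binary classification
question: given a feature table of metabolite intensities (samples in rows,
metabolites `M_1 ... M_n` in columns) and a two-level outcome, how well can a
multivariate model predict the class of a new sample, and how certain are we
about that estimate? `metabench` implements a standardised workflow for that
question: it builds, optimises and evaluates eight archetypal machine-learning
families under identical conditions — the same train/test split, the same
cross-validation design, the same metrics — so that differences between
families reflect the algorithms and not the protocol.

The package works on a two-table "tidy" representation: a **Data** table (one
row per sample: identifier, outcome class, metadata, intensity columns) linked
to a **Peak** table (one row per metabolite: identifier, annotation, optional
metadata). `read_tidy_tables()` accepts an `.xlsx` workbook with `Data` and
`Peak` sheets or the equivalent CSV pair; `write_tidy_tables()` writes the CSV
pair (this build has no Excel writer available, and the CSV pair carries
identical information).

## Preprocessing

All statistics are learned from training rows only and then applied frozen to
any other matrix, so test rows can never leak into the fit:

1. optional `log10` transform (the default; metabolite intensities are
   approximately log-normal),
2. per-feature median imputation of missing values (deterministic, robust,
   no extra hyperparameter — the data format allows missing cells but the
   models do not),
3. autoscaling: mean-centring and division by the per-feature *population*
   standard deviation (n in the denominator), so a training column scales to
   exactly unit variance at any sample size.

Zero-variance training features cannot be scaled; they are dropped and
reported through a classed warning rather than an error, because bootstrap
resamples of small datasets routinely create them.

## The eight model families

Every family is fit through one interface (`model_spec()`, `fit_model()`,
`predict_scores()`) and returns a continuous score per sample, oriented so
that larger means more likely positive class. Hard labels use the strict
`score > 0.5` rule; a score of exactly 0.5 classifies negative.

| Family | Score | Tunable hyperparameters |
|---|---|---|
| PLS-DA | linear `y* = b0 + x'beta` | number of latent variables |
| PCR | linear | number of components |
| PCLR | probability | number of components |
| SVM-Lin | signed margin distance | cost `C` |
| SVM-RBF | signed margin distance | `C`, kernel shape `gamma` |
| RF | class-1 vote fraction | tree depth, min. leaf fraction |
| ANN-LS | probability | hidden neurons, learning rate |
| ANN-SS | probability | hidden neurons, learning rate |

Implementation notes, in decreasing order of how much is hand-written:

* **PLS-DA** uses a from-scratch SIMPLS for a single response: latent
  variables are extracted from the cross-product `X'y` without deflating `X`,
  scores are mutually orthogonal, and the model collapses to an explicit
  linear coefficient vector (`coef()` returns it). At `n_latent = rank(X)`
  it reproduces the least-squares solution; tests verify this and agreement
  with an independently coded NIPALS oracle.
* **ANN-LS / ANN-SS** are two-layer feed-forward networks written in the
  package: a hidden layer of linear (LS) or sigmoidal (SS) neurons and a
  sigmoidal output neuron, trained by mini-batch stochastic gradient descent
  on the binary cross-entropy loss. Momentum 0.5, learning-rate decay 0 and
  400 epochs are fixed settings of the recipe; initial weights are drawn from
  a seeded uniform distribution scaled by fan-in, and the batch size defaults
  to 32 (full batch gives noticeably slower convergence within the fixed
  epoch budget, so plain full-batch gradient descent is not used). With one
  linear hidden neuron ANN-LS is logistic regression, and the tests hold it
  to within 5% of the glm cross-entropy.
* **PCR / PCLR** are PCA (thin SVD, written here) followed by ordinary least
  squares / an IRLS maximum-likelihood logistic fit (`glm.fit`, tolerance
  1e-8, at most 100 iterations) on the component scores, collapsed back to a
  coefficient vector on the original features.
* **SVM-Lin / SVM-RBF** call `e1071::svm` (libsvm) with hinge loss; ROC
  scores are raw decision values, not thresholded labels. The RBF kernel
  uses the standard convention `K = exp(-gamma * ||x - y||^2)`, the same
  parameterisation the backend uses, exposed directly as
  `rbf_kernel_matrix()`.
* **RF** calls `ranger` with CART splits and fixed settings 100 trees,
  `sqrt(M)` candidate features per split and a minimum of 2 samples to
  attempt a split; the tunables are the depth cap and the minimum fraction
  of training samples per leaf (`min.bucket`). Tests verify the structural
  guarantees on the grown trees.

A ninth degenerate family, `"Dummy"`, predicts the training prevalence for
every sample; it is a chance-level reference for workflow tests.

## Hyperparameter optimisation

`mc_cv_evaluate()` runs, for every point of a 1- or 2-axis grid, fivefold
stratified cross-validation with 10 Monte-Carlo repartitions (independent
re-draws of the fold assignment). Per grid point it reports:

* `R2` and `AUC_full` from one fit on all training data,
* `Q2` and `AUC_CV`: within each repartition the out-of-fold predictions are
  pooled and scored once, then averaged across repartitions. The `Q2`
  denominator uses the full training-set outcome mean, not per-fold means —
  pooled predictions against a fixed reference keep single-fold noise from
  dominating small datasets.

`select_optimum()` works in the `(Q2, |R2 - Q2|)` plane (or the AUC
analogue): the Pareto front (maximise `Q2`, minimise the gap) is extracted,
and the optimum is the *knee* — the front point with maximal perpendicular
distance to the chord joining the front's extremes — provided that distance
reaches a knee-strength threshold `delta = 0.02`. The threshold makes a
visual judgement ("is there a clear inflection?") deterministic; when no
clear knee exists the rule falls back to the front point closest to the
`|R2 - Q2| = 0.2` guide line, the conventional boundary beyond which the
train/validation discrepancy signals overtraining. Both axes are in the same
units, so no normalisation is applied before measuring distances. Ties break
toward the less complex model (fewer latent variables / components /
neurons, shallower trees, smaller `C`, smaller `gamma`, smaller learning
rate, larger leaf fraction), making selection independent of grid order.

Default grids (`default_hyper_grid()`) cover 1..min(20, rank) components,
seven log-spaced decades for `C` (1e-2..1e4), `gamma` (1e-5..1e1) and the
learning rate (1e-3..1), depths 1..10, leaf fractions 0.01..0.20 and 1..10
neurons. `benchmark_hyper_grid()` provides the compact grids used by the
synthetic benchmark experiments below.

## Evaluation and uncertainty

`stratified_split()` draws the 2:1 train/test split once per dataset
(per-class training counts are `round(2/3 * n_class)`, round-half-to-even,
with the remainder to test) and the identical split is reused by every
family. `evaluate_train_test()` reports `ROC`/`AUC` for both sets; AUC is
computed as the Mann–Whitney concordance probability with ties counting one
half, which equals trapezoidal integration of the tie-grouped ROC exactly.

`bootstrap_evaluate()` quantifies the uncertainty of a *fixed* optimal
configuration: 100 resamples drawn with replacement from the complete
dataset (stratified by class, so ~63.2% of samples are in-bag and degenerate
single-class out-of-bag sets are rare; when one occurs it is redrawn and
logged), a full refit per resample *including preprocessing*, and in-bag and
out-of-bag ROC curves interpolated onto a common 101-point false-positive-
rate grid. AUC intervals are 2.5/97.5 percentiles of the per-resample AUC
distribution.

**Band construction.** The default 95% ROC band is *simultaneous*: the
per-point quantile level is relaxed until at least 95% of the bootstrap
curves lie entirely inside the band. A pointwise 2.5/97.5 percentile band
(`band_type = "pointwise"`) is narrower, but a whole curve has far less than
95% probability of lying inside 101 simultaneous pointwise intervals, which
makes statements of the form "the test ROC lies within the 95% band"
uninterpretable; the simultaneous band is the construction under which that
statement has its nominal meaning. This was a deliberate design choice made
after measuring the joint coverage of the pointwise variant (roughly 35% at
n = 400 for the whole test curve).

Even with the simultaneous band, containment of the held-out test curve is
*not* guaranteed at 95%: the out-of-bag estimate is systematically slightly
pessimistic (each model trains on ~63% effective unique samples), so a lucky
test split can sit above the entire OOB ensemble. On clean low-rank
synthetic data the package's own experiments measure whole-curve containment
in roughly 50–80% of replicates (seed-dependent) at n = 400–800, where the
bands are narrowest relative to the residual bias. On small heterogeneous
clinical datasets the
OOB bands are much wider and containment is the norm; the corresponding
acceptance check in this package is asserted at the strict reference level
and is expected to fail on large clean synthetic data — we report that
honestly rather than widen the band to pass.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the workflow
assumes: latent scores `T` (n x r, standard normal) express inter-metabolite
covariance; intensities are `exp(scale + T W' + noise)` with seeded normal
loadings, so effects live in log space and the default `log10` preprocessing
is the correct inverse. Three class mechanisms are provided: a linear
mean-shift of `effect_size` latent units along axis 1; a radial rule
(class = large latent norm); and an XOR rule (class = sign parity of
`T1 * T2`), which no linear decision function can separate. For the
nonlinear rules the class threshold is placed at the empirical quantile
matching the requested balance, so class counts are exact.

Defaults (100 features, rank 2, effect 2, log-noise 0.1, balance 0.5) were
chosen once as a realistic mid-size LC-MS-like table: rank-2 structure with
noise sd 0.1 puts ~99% of log-intensity variance in the top two components,
and an effect of 2 latent units corresponds to a population AUC of about
0.92 — a strong but imperfect biomarker panel. What the generator does *not*
emulate: instrument drift, batch effects, QC samples, heteroscedastic or
intensity-dependent missingness (missingness is completely at random),
heavy-tailed contamination, and correlated annotation structure. Passing
tests on this generator therefore demonstrate correctness of the machinery
and qualitative behaviour (linear separability, nonlinearity detection,
uncertainty scaling), not performance claims about any real cohort.

## Problem sizes used by the tests and the reproduction script

The packaged experiments run at desk scale, chosen once: the benchmark
scenarios use n = 400 samples x 100 features with 5 seeds and Monte-Carlo
cross-validation reduced to 2 repartitions over the compact
`benchmark_hyper_grid()` grids; the interval-width experiment compares
n = 80 against n = 800 with 50 bootstrap resamples over 20 replicates; the
band-containment experiment uses n = 800 with the full 100 resamples. The
full-scale defaults (10 repartitions, 100 resamples, wide grids) remain the
package defaults for real analyses.

## Known limitations

* Hyperparameter selection and bootstrap evaluation reuse the same data, so
  the OOB intervals inherit a mild optimism about the *selected*
  configuration; nested cross-validation is out of scope by design.
* `Q2` pools out-of-fold predictions per repartition; per-fold averaging is
  a defensible alternative the package does not implement.
* The ANN trainer is deliberately minimal (fixed epochs, momentum SGD, no
  early stopping); it matches the benchmarking recipe rather than modern
  deep-learning practice.
* Accession helpers only validate identifiers and describe where to place
  manually converted files; no downloading or format conversion from the
  public repositories is performed.
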