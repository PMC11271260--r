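---
title: "Benchmarking dimensionality reduction and data fusion for multimodal diagnosis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking dimensionality reduction and data fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusebench)
```

## The problem

Clinical diagnosis prediction increasingly draws on several data
modalities at once — for Alzheimer's disease, typically a battery of
clinical/neuropsychological features alongside structural MRI
volumetrics.  Two design questions dominate such pipelines:

1. **Where to fuse.**  Concatenate raw feature blocks and classify
   (*simple* fusion), concatenate and then reduce dimensionality
   (*early* fusion), or reduce each modality separately and concatenate
   the reduced representations (*intermediate* fusion).  Decision-level
   (late) fusion is deliberately out of scope here.
2. **How to reduce.**  fusebench implements four reducers under one
   fit/transform contract: principal component analysis (PCA), a
   denoising autoencoder (AE), LASSO feature selection, and a
   *supervised encoder* (SE) — a feed-forward classifier whose last
   hidden layer is a narrow bottleneck whose activations become the
   learned low-dimensional representation.

The package provides the building blocks to compare all combinations
on a common footing: a synthetic multimodal cohort generator with
known latent structure, preprocessing filters for visit-level tables,
end-to-end pipeline objects, a repeated random-split evaluation
protocol, voting ensembles, and permutation feature importance.

## The generative model behind the synthetic cohorts

Real multimodal cohorts of this kind are access-restricted, so the
package ships a generator whose defaults emulate the *shape* of a
merged clinical + MRI cohort (1,419 subjects; feature blocks of 90 and
157; roughly 63/19/17% class masses) without attempting to mimic real
item semantics or real covariance:

* a one-dimensional latent disease severity \(z_i \sim N(0,1)\) per
  subject;
* diagnosis by thresholding \(u_i = (z_i + s\,\eta_i)/\sqrt{1+s^2}\)
  (\(\eta_i \sim N(0,1)\), label-noise sd \(s\)) against two cut
  points.  Because \(u_i\) is standard normal for every \(s\), class
  masses are exactly the normal-CDF masses of the cut points, and
  \(s = 0\) makes labels a deterministic function of \(z\);
* per modality \(m\), features
  \(X_m = z w_m^\top + F_m B_m + \varepsilon_m\): the latent loads with
  magnitude `signal_weights[m]` on the first `n_informative[m]`
  columns; `nuisance_factors[m]` shared within-block factors induce
  multicollinearity (independent across modalities, so per-modality
  denoising genuinely helps intermediate fusion); residual noise has sd
  `noise_sd`; optional missing-completely-at-random entries at
  `missing_rate`;
* one integer seed drives independent substreams for the latent draw,
  label noise, nuisance loadings, residual noise, and missingness —
  changing `missing_rate` never perturbs the latent draw.

Because each modality's informative columns live in its own block, the
informative sets are disjoint across modalities and both blocks are
noisy views of the same severity axis: fusing them strictly increases
the information about \(z\), which is the regime in which intermediate
fusion should beat either single modality.

`bayes_reference_accuracy()` gives the ceiling for any classifier: in
this linear-Gaussian model the posterior mean of \(z\) given all
features is a linear score with signal-to-noise ratio
\(\mathrm{SNR}=\sum_m w_m^\top \Sigma_m^{-1} w_m\),
\(\Sigma_m = B_m^\top B_m + \sigma^2 I\), so Bayes accuracy reduces to
a one-dimensional Monte-Carlo integral.  The reference conditions on
the nuisance loadings realized from the cohort seed and ignores
missingness (a complete-data upper bound).  Tests cross-check it
against a brute-force posterior integration on a \(z\)-grid from
simulated raw features.

What passing tests on these cohorts do **not** show: robustness to the
heavy-tailed, ordinal, block-correlated structure of real clinical
instruments, to informative missingness, or to site effects.  The
generator is a testbed for the *pipeline logic*, not a simulator of
real cohorts.

## Preprocessing

The filters mirror common visit-level cleaning rules, each read
literally and fixed by tests at its boundary:

* features with **over** 10% missing entries are dropped (keep
  \(\le 0.10\));
* records with any remaining missing value are dropped (no
  imputation);
* multi-visit subjects keep their earliest (baseline) visit;
* two modalities are merged when a subject has visits within 18
  months, interpreted as 548 days (365.25 x 1.5, rounded) since no
  day-level definition is standard; ties on the gap prefer the earlier
  visit;
* the age filter is strict (`age > 65` keeps subjects over 65).

The composed order — baseline, feature filter, record drop, age
filter, merge — never increases row or column counts at any stage, and
`preprocess_pair()` emits a per-stage count report.

## Dimensionality reduction

All reducers share one contract: z-scoring moments are estimated on
the training split, stored, and re-applied (never refit) at transform
time; constant training columns get a unit divisor.  Output dimension
is fixed at fit time.

* **PCA** (`n_components` default 8, a typical scree knee for data of
  this kind): eigenstructure of the standardized training matrix, with
  a deterministic sign convention (largest-magnitude loading element
  positive).  `choose_components_knee()` picks the component count by
  the maximum-distance-to-chord rule on the cumulative
  explained-variance curve.  The chord is anchored at the origin (zero
  components explain zero variance); anchoring at the first curve
  point would misclassify a spectrum with one dominant component.
  Flat spectra return 1 by convention.
* **LASSO**: minimizes \(\tfrac{1}{2n}\lVert y - Xw\rVert_2^2 +
  \lambda\lVert w\rVert_1\) via glmnet on the standardized block.  A
  multi-value grid is tuned by 5-fold cross-validation on the training
  split (folds seeded from the spec).  For the 3-class task the target
  is coded ordinally HC = 0, MCI = 1, AD = 2, respecting disease
  ordering; only the selected set, not the coefficients, is passed
  downstream, limiting the coding's influence.  \(\lambda = 0\) is
  fitted by exact least squares (the coordinate-descent path is
  unreliable at zero penalty), which also makes it an exact identity
  reducer — useful for the fusion-equivalence tests.  The transform
  returns the selected columns of the *raw* input, preserving feature
  semantics for importance reports.
* **Denoising AE** (bottleneck 4): a five-layer symmetric network
  (encoder hidden layer, linear bottleneck code, decoder hidden layer)
  trained to reconstruct the clean standardized input from an input
  corrupted with fresh Gaussian noise (sd 0.1 by default, on z-scored
  features).  Unsupervised: labels never enter the fit.
* **Supervised encoder** (bottleneck 10): a feed-forward classifier
  with two ReLU hidden layers (64, 32 by default — widths are
  configurable since no canonical choice exists) feeding a linear
  bottleneck code and a softmax head.  After training, the head is
  discarded and the bottleneck activations are the representation.
  The code layer is kept linear in both AE and SE so the extracted
  representation is an unconstrained real-valued embedding.

Networks are trained by a small dense-network engine in the package
(mini-batch Adam, learning rate 0.01, batch 32, He initialization,
epoch budget with early stopping on a 10% validation carve-out once
\(n \ge 50\), best-validation weights restored).  All randomness —
initialization, batch order, corruption, carve-out — derives from the
spec seed, so fits are bit-reproducible.  Fitted reducers serialize to
a type-tagged JSON file with doubles written at 17 significant digits,
so a reloaded reducer transforms bit-identically (plain JSON number
printing loses the last bits of a double).

## Pipelines and classifiers

`pipeline_spec()` binds topology, reducer(s), classifier and task.
The binary task (HC vs any impairment) uses L2-regularized logistic
regression (glmnet ridge, fixed penalty 0.01); the multiclass task
uses a 500-tree random forest or a (64, 32) ReLU + softmax network.
Hyperparameters the design leaves open are collected in
`classifier_config()`.

Two decisions the design space left open:

* reduced blocks are re-standardized jointly before classification, so
  a modality with larger reduced scale cannot dominate;
* concatenation order is the declared modality order, recorded so
  importance reports can attribute columns to modalities.

A single-modality pipeline is implemented as the singleton case of
intermediate fusion (one code path), and identity reducers collapse
early and intermediate fusion onto simple fusion exactly — both facts
are asserted as tests.

## Evaluation protocol

`split_plan()` defaults to 50 random 75/25 train/test splits.  Splits
are stratified by class by default (a three-class cohort in the low
thousands can otherwise lose a class from a training split; if
stratification is turned off, a degenerate split is redrawn with a
warning).  Repeat \(r\) uses a substream of the plan seed, so every
pipeline evaluated under a plan sees the *same* partitions —
comparisons are paired, and ensembles vote among members fitted on the
identical split.

The 95% confidence interval is the normal approximation on the split
means, mean \(\pm 1.96\,\mathrm{sd}/\sqrt{R}\), clipped to \([0,1]\);
two results differ significantly when their intervals do not overlap.
Interval coverage at the nominal rate and the \(1/\sqrt{R}\) width
scaling are both exercised by simulation in the test suite.

Voting ensembles take the per-subject modal label; ties are broken by
training-set class prevalence, then label order.  One binary and one
multiclass ensemble are formed per pipeline family with at least two
members (simple fusion has a single binary model, hence no binary
ensemble).  `rank_models()` orders results by mean accuracy, then
narrower interval, then name.

Permutation importance shuffles one raw feature at a time within the
test rows, *before* standardization and reduction, so importance
attaches to original named features grouped by modality; a feature the
fitted model never consumes (e.g. not LASSO-selected) scores exactly
zero.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen
so the whole suite completes in minutes while every property retains a
clear margin: grid-level checks use a 600-subject cohort with 20 + 30
features over 10 repeats (reduced epoch/tree settings via the exposed
configs); the encoder-recovery check uses n = 2000, p = 50 with 10
informative features and 10 nuisance factors; the fusion-headline
check uses n = 1000 over 30 repeats.  A nuisance-free design is
deliberately avoided for the encoder-recovery check: a randomly
initialized network already preserves much of an *unstructured* linear
signal, whereas cancelling shared nuisance factors requires the
supervision that only the trained encoder has — that contrast is the
property being tested.

Other conventions: PCA rejects `n_components` above the numerical rank
of the training matrix; explained-variance ratios are exposed for
scree inspection; degenerate knee chords return 1; glmnet's two-column
minimum is met by padding one-dimensional classifier inputs with a
constant zero column; all derived seeds stay below \(2^{31}\).

## Limitations

* The MLP engine is deliberately minimal (dense layers, Adam, early
  stopping); it is adequate for feature widths in the hundreds, not
  for image-level input.
* Late fusion and other reducers (ICA, LDA) are out of scope.
* The evaluation protocol treats split accuracies as independent
  draws; the normal-approximation interval on split means is the
  package's primary comparison device, with no further multiple
  comparison correction — matching the benchmarking practice it
  implements.
* Synthetic cohorts validate pipeline logic, not clinical realism; no
  claim about real-data accuracy follows from them.
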