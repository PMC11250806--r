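---
title: "Methods: multi-cohort methylation analysis and classifier benchmarking"
author: "methbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort methylation analysis and classifier benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`methbench` implements a complete analysis chain for multi-cohort blood DNA
methylation case/control studies of the kind used in depression biomarker
research: several cohort batches measured on Illumina-style arrays, each with
its own technical character, merged into one pooled dataset and analysed for
differential methylation, then mined for classifiers. Because the real
cohorts of such studies are only partly public, the package ships a
first-class simulator that reproduces the *statistical structure* the
analysis assumes, together with the ground truth needed to test every stage.

Methylation at a CpG is carried either as a beta-value $\beta \in [0,1]$
(the methylated fraction) or as the M-value $M = \log_2\!\big(\beta/(1-\beta)\big)$.
M-values are approximately Gaussian and are the default modelling scale;
beta-values are used where a bounded scale is required (hypervariable-probe
screening, cell-type deconvolution, cross-entropy reconstruction in the
autoencoders). Saturated beta-values are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the logit;
the clipping bound is exposed because the choice is a convention, not a fact
about the data.

# The simulator

`generate_study()` draws, per batch $b$ and sample $i$:

$$M_{ij} = \mathrm{logit}_2\!\Big(\textstyle\sum_k w_{ik} R_{kj}\Big)
  + \delta\,\mathbb{1}[\text{case}_i]\,\mathbb{1}[j \in S]
  + \gamma_b + \epsilon_{ij}, \qquad
  \epsilon_{ij} \sim N(0,\; \sigma^2 \lambda_b)$$

where $R$ is a celltype-by-probe reference beta panel, $w_i$ a Dirichlet
cell mixture, $S$ the planted signal-probe set with effect $\delta$ in
M-units, $\gamma_b$ a per-batch mean shift and $\lambda_b$ a per-batch
variance multiplier. Defaults emulate the published eight-cohort design:
8 batches, 1942 samples with a pooled case fraction near 0.58 but
heterogeneous per-batch imbalance, and a desk-scale universe of 5000 probes.
Choices the underlying study does not pin down, made once here:

* **Gaussian noise on the M scale.** Per-cohort noise models are not
  published; Gaussianity on M matches the linear-modelling assumption of the
  downstream moderated-t analysis and is surfaced in `sim_config()`.
* **Case counts** are `floor(fraction * n + 0.5)` (half-up, not banker's
  rounding), so a documented deterministic count results.
* **Cell-composition confounding is off by default** (identical Dirichlet
  concentrations for cases and controls, a granulocyte-dominant whole-blood
  composition); setting the two concentration vectors apart turns the
  adjustment stage's target phenomenon on.
* **Age and sex are null covariates** by default: they exist in every sample
  sheet so covariate handling is exercised, but carry no effect, keeping
  effect-recovery oracles unbiased.
* **Probe coordinates** are consecutive 1-based positions on synthetic
  autosomes chr1–chr22; sex chromosomes never appear in simulated universes,
  mirroring the standard probe filter.
* **Batch confounding** (`batch_confound`) couples each batch's mean shift
  to its case fraction, $\gamma_b \mathrel{+}= c\,(f_b - \bar f)$. This is the
  generator for the leakage experiment; the coupling form is the simplest one
  that produces the "case fraction correlates with batch" scenario, and it is
  off ($c = 0$) by default.

# Preprocessing and harmonization

`quantile_normalize()` forces every sample's distribution onto the
cross-sample mean of order statistics (ties receive the mean of the quantile
values they span — the common reference-implementation dialect). On disk,
matrices are probes-by-samples (GEO series-matrix orientation) with 1-based
Illumina-convention coordinates; in memory everything is samples-by-probes.

`combat_adjust()` implements the parametric empirical-Bayes location/scale
batch model: per-probe standardization by a batch + covariate least-squares
fit, batchwise location/scale estimates, normal and inverse-gamma priors by
method of moments, and iterated posterior updates to a relative tolerance of
$10^{-4}$. Parametric priors (rather than the nonparametric variant) were
chosen for their closed-form moment matching and testable convergence; the
fitted object exposes every hyperparameter
($\bar\gamma_b, \bar\tau^2_b, \lambda_b, \theta_b$) and the shrunken
per-batch effects. Disease status is **not** protected by default — the
harmonize-then-model workflow this package mirrors runs ComBat with the batch
variable only — but a `covariates` argument protects any design columns that
must survive (the effect-preservation tests use it). A single batch is an
exact no-op.

"Hypervariable" probes are those whose cross-sample **beta range**
(max − min) exceeds 0.2. Range, rather than IQR or a group contrast, is the
interpretation adopted for "beta value difference"; it is the strictest
reading and is monotone in the threshold, which the tests exploit. PCA
diagnostics run on centered, unscaled beta values of that submatrix and
report one-way ANOVA $R^2$ of PC1/PC2 on a label.

`estimate_cell_proportions()` solves the reference-based (Houseman-style)
constrained projection $\min_w \lVert b - R^\top w\rVert^2$ s.t.
$w \ge 0, \sum w = 1$ over the panel's discriminating probes, via
non-negative least squares followed by sum-to-one normalization. The
equality constraint (not $\sum w \le 1$) reflects a complete blood panel and
gives a testable invariant. The residual+mean adjustment regresses each
probe on an intercept plus $K-1$ proportion columns (last cell type is the
reference, avoiding the simplex collinearity) and returns residual + probe
mean — exactly mean-preserving and idempotent. Adjustment runs on whichever
scale the dataset is on; both scales are supported because the source
workflow does not state its choice.

# Differential methylation and meta-analysis

Per-probe OLS uses one QR decomposition for the whole matrix; the "log2 fold
change" is the status coefficient on the analysis scale (on M-values this is
the case–control $\Delta M$, the conventional use of the term for array
probes). Moderation follows the standard empirical-Bayes closed forms:
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, prior df $d_0$ from trigamma
inversion of the excess dispersion of $e$, prior variance
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$, shrunken variance
$s^2_{\text{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and
$t = \hat\beta / (u\, s_{\text{post}})$ on $d_0 + d$ df. One numerical
choice deserves note: when the observed $\log s^2$ carry *no* excess
dispersion, $d_0 = \infty$ and the prior variance is taken as the geometric
mean of the observed $s^2$, so that exactly-equal residual variances shrink
to themselves and the moderated t reduces to the ordinary t exactly — the
degenerate case is otherwise a matter of convention. No robust or
mean-variance-trend variants are provided.

The directional agreement index is the fraction of cohorts whose
case-minus-control **median** difference matches a reference sign; zero
differences count as disagreement. The reference is the pooled-analysis
logFC sign by default (the anchor is not stated in the source workflow; a
cross-cohort majority-sign alternative is available by flag).

Meta-analysis uses the Sidik–Jonkman two-step heterogeneity estimator
exactly as published: crude dispersion $\tau_0^2 = \sum(y_i-\bar y)^2/k$
with the unweighted mean, weights $(v_i/\tau_0^2 + 1)^{-1}$, and
$\hat\tau^2 = \sum w_i (y_i - \hat\mu_w)^2/(k-1)$. Identical effects give
$\tau_0^2 = 0$; the estimator's source is silent there and the package
returns $\hat\tau^2 = 0$. Pooling is inverse-variance with Wald (normal)
inference — the cited implementation's default, no Knapp–Hartung — Cochran's
Q uses fixed-effect weights, and $I^2$ uses the Higgins–Thompson typical
within-study variance. Probes enter the meta-analysis when nominally
significant in at least one cohort and present in at least two; $k$ is
recorded per probe.

# Feature selection, classifiers, evaluation

Variance-fraction selectors retain $\lceil f \cdot p\rceil$ probes — the only
rounding rule consistent with all three published counts (15239/3048/305
from 304,765). All ranking ties break by probe-universe order. The
L1-logistic selector walks the lasso path and takes the least-penalized
point with at least $k$ nonzero coefficients; the L1 linear-SVC selector is
a proximal-gradient (ISTA) solver for the squared-hinge + L1 objective with
the published 5000-iteration cap; both pad to $k$ with the next-largest
magnitudes when sparsity yields fewer. The extra-trees selector normalizes
impurity importances to sum to one and requires a seed.

Every classifier family — the four logistic variants, decision tree, random
forest, linear and RBF SVMs, AdaBoost (discrete SAMME over depth-1 stumps,
50 rounds), the simple DNN, and the two joint autoencoder-classifiers —
exposes one `train_classifier()` / `score_samples()` contract returning case
scores in $[0,1]$ (margin families are squashed through a sigmoid for
thresholding; AUC is rank-based and unaffected). Classifiers see CpG
features only; age and sex participate in feature selection but never enter
the models.

The deep models follow the published architecture: encoder $N$–128–64 into a
32-unit bottleneck, decoder 64–128–$N$, a small classifier head on the
bottleneck, squared-error reconstruction for M-values and binary
cross-entropy for beta-values, Adam, batch size 128, and total losses
$w\,L_{rec} + (1-w)\,L_{clf}$ (joint AE, $w = 0.5$ by default since the
weight is left open as a hyperparameter) and
$L_{rec} + KL + c\,L_{clf}$ (joint VAE, $c = 1$). The full-scale defaults
are 2000 / 2250 / 1000 epochs at learning rate $10^{-4}$. Desk-scale runs
(the test suite and the acceptance script) train 200-epoch models at
learning rate $3\times10^{-3}$: a fifth of the epochs cannot traverse the
loss surface at the full-scale step size, so the reduced-scale default
raises it; this is a property of the reduced budget, and the full-scale
configuration remains the documented default. Head width (16), dropout
(off) and weight penalties (off) are package defaults — the published
figure-level settings are not in the text. Batch normalization is not
implemented; at these widths it buys little and costs exactness of the
backprop oracle tests.

Evaluation follows the published protocol: 10 repetitions of stratified
threefold cross-validation (stratification is on by default; the source is
silent, and an unstratified mode exists), fold-level metric averaging (not
pooled-prediction AUC), accuracy at a 0.5 threshold, and cohort-batch-based
hold-out allocation in the published 5-train / 3-test proportions with a
hard error on any batch overlap. The leakage audit is structural: every
selector records the exact sample ids it saw, and `evaluate_unbiased()`
refuses any fold whose validation ids intersect them. Hold-out evaluation
can average over seeded training repeats for the stochastic families.

# What the tests do and do not show

The simulator reproduces batch location/scale heterogeneity, class
imbalance, cell-mixture structure, and planted effects — but not probe-type
chemistry, detection-p missingness, SNP artefacts, correlated CpG blocks, or
population stratification. Green tests therefore certify the *methods*
(calibration, recovery, bias phenomena) under the stated generative
assumptions, not performance on any real cohort; the published real-data
AUCs are explicitly out of reproduction scope.

Problem sizes in the test suite and acceptance script are the package's
own desk-scale choices: the selection-bias experiment uses one 600-sample,
5000-probe null study per seed (three seeds in the tests), where the
whole-data top-200 panel inflates cross-validated AUC to ≈ 0.8 while
within-fold selection stays at chance; the leakage contrast uses
8 × 100 samples × 2000 probes; ComBat's shift-removal check uses two
batches of 500 samples so that the 0.1 standardized-mean-difference bound is
measured against a sampling noise floor of ≈ 0.05; the autoencoder check
uses 400 training samples on 200 probes. Scaling any of these up changes
runtimes, not conclusions.

Known limitations: no nonparametric ComBat, no reference-batch or
ComBat-seq variants, no surrogate-variable analysis, no DL/REML $\tau^2$
estimators, no recursive feature elimination, no calibration analysis, and
no GPU-scale hyperparameter search. The L1-SVC proximal solver fixes the
penalty at the objective's canonical $C = 1$; it is a selector, not a tuned
classifier.
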