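---
title: "Methods: cross-dataset generalization benchmarking for drug response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset generalization benchmarking for drug response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(drpbench)
```

This vignette documents the models, procedures, and design choices behind
`drpbench`: how dose–response measurements become AUC labels, how benchmark
bundles and splits are built, what the pipeline and workflow contracts
guarantee, how the generalization metrics are defined, and what the
synthetic data generator does and does not emulate.

## Dose–response curves and the AUC label

Viability of a cell line at drug concentration $c$ (molar) is modelled with
the standard three-parameter Hill-slope curve,

$$v(c) = E_\infty + \frac{1 - E_\infty}{1 + (c/\mathrm{EC}_{50})^h},$$

a descending sigmoid on log-dose. The upper asymptote is fixed at 1 because
viability is normalized to untreated controls; $E_\infty \in [0, 1]$ is the
residual viability at saturating dose, $\mathrm{EC}_{50} > 0$ the
half-effect concentration, and $h > 0$ the Hill slope. At $c =
\mathrm{EC}_{50}$ the curve passes through $(1 + E_\infty)/2$, and it is
monotonically non-increasing in dose for all admissible parameters.

**Fitting.** `fit_hill_curve()` minimizes squared viability residuals on the
log$_{10}$-dose axis with Levenberg–Marquardt least squares (`minpack.lm`)
under box bounds $\mathrm{EC}_{50} \in [10^{-12}, 10^{-2}]$ M, $h \in [0.05,
10]$, $E_\infty \in [0, 1]$. Because the sigmoid's SSE surface has local
minima when the transition falls near the edge of the measured dose range,
the optimizer is restarted from a $3 \times 3 \times 3$ grid — EC$_{50}$ at
the 25/50/75% dose quantiles, $h \in \{0.5, 1, 2\}$, $E_\infty \in \{0,
0.25, 0.5\}$ — and the lowest-SSE solution wins. A start that already
achieves numerically zero SSE short-circuits the remaining starts. Fit
quality is the ordinary $R^2$ of observed vs fitted viabilities (total sum
of squares about the observed mean; negative values are possible and
meaningful). Constant-viability input is reported as a non-converged
`degenerate` fit rather than an error so batch runs always complete; fewer
than 4 points raises at the single-curve level but is caught and recorded by
the batch driver `fit_response_data()`.

**AUC.** The response label is the area under the *fitted* curve over
$[10^{-10}, 10^{-4}]$ M on the log$_{10}$-dose axis, divided by the
six-decade range width so the value lies in $[0, 1]$ (viability is clipped
to $[0, 1]$ first; for admissible parameters the clip is a no-op). The
integral has a closed form,

$$\int_a^b \frac{dx}{1 + 10^{h (x - m)}} = (b - a) - \frac{\log_{10}\!\big(1 + 10^{h(b-m)}\big) - \log_{10}\!\big(1 + 10^{h(a-m)}\big)}{h},$$

with $m = \log_{10} \mathrm{EC}_{50}$, evaluated overflow-safely; tests
verify agreement with a $10^5$-point trapezoid quadrature to $10^{-4}$.
Lower AUC means stronger growth inhibition. Pairs whose fit $R^2$ is
strictly below 0.3 are excluded from the benchmark (`build_response_table`;
a fit at exactly 0.30 is kept).

**Why the fitted-curve AUC and not a raw-point trapezoid?** The label should
be a property of the underlying pharmacology, not of the particular dose
grid; integrating the fitted curve decouples the label from grid density and
noise, and is the only reading consistent with deriving the label *from* the
fit.

## Bundles, splits, featurization

A benchmark bundle joins a response table (`cell_id`, `drug_id`, `auc`), an
omics matrix (cells × features), and one or more drug feature matrices
through shared identifiers; samples lacking features are dropped with a
logged count, and an empty join is fatal. Splits are random k-fold
partitions: for split $n$ of 10, the test set is fold $n$, the validation
set the next fold cyclically, and the training set the remaining eight folds
— (0.8, 0.1, 0.1) proportions. The cyclic validation-fold rule is a design
choice (any disjoint carve-out would satisfy the proportions); it guarantees
that across the 10 splits every fold serves exactly once as test and once as
validation. At least 3 folds are required, since test and validation each
consume one fold. On disk, splits are plain-text files of 0-based row
indices (a `#` header documents the base); in memory the package uses R's
native 1-based indices, converted only at the I/O boundary.

Drug featurization goes through the OpenBabel backend (`ChemmineOB`):
canonical SMILES as the deterministic join key (raw SMILES kept as
metadata), circular ECFP4 fingerprints (radius 2) folded by OR from the
backend's native 4096 bits to a fixed 512-bit width, and the backend's 2D
descriptor set. SMILES carry no 3D conformer, so no 3D descriptors enter the
matrix; descriptor columns with more than 50% invalid entries are dropped
and remaining invalid values are median-imputed. Unparsable SMILES exclude
the drug with a warning rather than aborting the batch.

## The pipeline contract

Every model runs as three separable stages — preprocess, train, infer —
that communicate only via files, so a workflow scheduler can treat them as
black boxes. Configuration is resolved across three tiers (command line >
config file > defaults) with per-key provenance recorded and the resolved
configuration serialized into the run directory; unknown keys fail with a
nearest-name suggestion.

Preprocessing standardizes continuous feature blocks (omics, descriptors)
per feature using statistics computed from *training rows only*, applied
unchanged to validation and test data; binary fingerprints are left
unscaled. In cross-dataset mode the test set is the full target response
table, featurized with the source-trained scaler — so target feature values
legitimately vary across training splits while target labels do not.

Training uses validation-based early stopping: training halts once the
validation loss (MSE) has failed to improve for `patience` consecutive
evaluations (default 10, one evaluation per boosting round / epoch chunk),
and the checkpoint with the lowest validation loss ever seen is the one
persisted — never a later, worse one. Predictions are deliberately *not*
clipped to $[0, 1]$: clipping would mask the diagnostic negative-$R^2$
behaviour that cross-dataset evaluation relies on. Three baselines ship in
the registry: `gbt` (gradient-boosted trees on omics ‖ descriptors, xgboost
with native early stopping), `ridge` (L2 linear model, glmnet, regularization
strength selected on the validation set), and `mlp` (small feed-forward
network trained in warm-restart chunks through the generic
`early_stopping_loop()`). The loss function and patience are defaults of
this package, configurable per run.

Run outputs follow a bijective naming convention,
`runs/{model}/{source}/split_{n}/` with per-target
`test_{target}_{predictions.csv,scores.json}`, so a run directory can be
parsed back into a score store without auxiliary bookkeeping.

## The cross-dataset workflow and metrics

With $d$ datasets and $N$ splits, each model is trained once per (source,
split) — $d N$ instances — and each instance is evaluated on its own
held-out test split and on every other dataset's full response table,
$d N d$ evaluations, reusing instances across targets. The executor is a
contract, not a library: any scheduler honoring the
preprocess→train→infer dependency order must produce identical results,
which holds because every pipeline derives its seed deterministically from
the master seed and its (model, source, split) identity. A serial executor
and a process-pool executor (forked workers) are bundled; tasks are
idempotent and runs resumable by output presence, with `force` to override.
Cross-dataset evaluation deliberately does *not* exclude target samples
whose cell or drug also occurs in the source; overlap is analyzed
explicitly through the coverage matrices instead.

Scores are $R^2 = 1 - SS_{res}/SS_{tot}$: 1 for perfect prediction, 0 for a
naive mean predictor, negative when transfer is worse than that. The metric
family is

$$g[s,t] = \tfrac{1}{N}\sum_n g[s,t,n], \qquad
  g_a[s] = \tfrac{1}{d-1}\sum_{t \neq s} g[s,t],$$
$$g_n[s,t] = \frac{g[s,t]}{g[s,s]}, \qquad
  g_{na}[s] = \tfrac{1}{d-1}\sum_{t \neq s} g_n[s,t].$$

Numerical conventions chosen here: the per-entry spread across splits is the
sample standard deviation (denominator $N - 1$; defined as 0 when $N = 1$);
$g_n$ is undefined (masked, excluded from $g_{na}$, flagged per row) when
$g[s,s] \le 0$, since a ratio over a non-positive baseline is meaningless —
and even for small positive baselines the normalized values should be read
with care. Coverage is $C_D(s,t) = |D_s \cap D_t| / |D_t|$ (and analogously
for cells): the fraction of the *target's* entities the source has seen,
asymmetric by construction. The coverage–performance association uses
Spearman's $\rho$ with average ranks over the $d(d-1)$ off-diagonal cells.
Pairwise model comparisons use two-sided Wilcoxon signed-rank tests paired
on off-diagonal (source, target) cells with split-averaged scores by
default; pairing on (source, target, split) and a `p.adjust` correction are
configurable, with no correction applied by default. Reported gaps
$\Delta = a - b$ are exact differences; rounding to 4 decimals happens only
at presentation time.

## The synthetic data generator

`simulate_world()` draws latent cell embeddings $u_c$ and drug embeddings
$v_d$ (spherical Gaussians scaled so $\mathrm{var}(u_c \cdot v_d) \approx
1$) plus cell and drug biases, and defines the clean response surface

$$f(c,d) = \mathrm{logistic}\big(1.2\, u_c \cdot v_d + b_c + b_d\big) \in [0,1].$$

A low-rank bilinear surface with biases is the simplest structure that lets
tree and linear baselines learn *partially* while leaving headroom, which is
the regime the benchmark is about. Each study observes

$$\mathrm{auc} = \mathrm{clip}\big(a_s f + b_s + \varepsilon, 0, 1\big),
  \quad a_s = 1 + \mathcal{N}(0, \sigma_{shift}), \;
  b_s = \mathcal{N}(0, \sigma_{shift}/2), \;
  \varepsilon \sim \mathcal{N}\big(0, \sigma_{noise}(0.5 + f)\big),$$

a per-study affine distortion plus mildly heteroscedastic noise — a minimal
stand-in for differing viability assay chemistries across screens. Defaults:
$\sigma_{noise} = 0.05$ (the scale of replicate variation in viability
screens), $\sigma_{shift} = 0.15$ (moderate distortion; 0 disables it, and
larger values, e.g. 0.3, model strongly divergent assays). Study rosters
control entity overlap exactly: each study takes a deterministic prefix of a
shared reference pool (fraction = its overlap parameter) plus a
study-private disjoint block, so pairwise drug/cell coverage is known by
construction. Omics features are the true $u_c$ padded with 30 pure-noise
columns; drug descriptors are $v_d$ padded with noise; pseudo-fingerprints
are binarized random projections of $v_d$. The biases $b_c, b_d$ are *not*
exposed as features: a model can only capture them by memorizing entities
seen in training, which is precisely what makes entity coverage matter for
transfer — mirroring the leakage structure of random pair splits on real
screens.

The default desk-scale roster has five studies of decreasing size (250×70
down to 120×15 cells×drugs, 60% of each grid measured, ≈22k samples total),
echoing the size heterogeneity of public screens; the full 5×10 ridge
workflow on it runs in well under a minute on one CPU, and the test suite's
qualitative checks use four-study worlds (150×30) with 3 splits.

What the generator does **not** emulate: real expression covariance or
pathway structure, chemically valid molecules (pseudo-features; real-SMILES
featurization is tested separately on a handful of hand-written molecules),
dose-range truncation effects, or systematic cell-panel composition biases.
Passing the end-to-end checks therefore demonstrates that the machinery is
correct and that the metrics respond to assay shift and overlap as designed
— not that any baseline would attain a particular accuracy on real screens.

## Known limitations

* The Hill parameterization, optimizer, and log-axis AUC integration are
  this package's choices among standard conventions; other packages'
  AUC values are comparable only under the same conventions.
* $g_n$ is reported masked rather than extrapolated when $g[s,s] \le 0$;
  aggregate $g_{na}$ values over partially masked rows are flagged, not
  silently rescaled.
* The Wilcoxon pairing unit (split-averaged cells) treats the $d(d-1)$
  cells as exchangeable pairs; cells sharing a source are not independent,
  so the tests are descriptive rather than strictly calibrated.
* Random pair splits leak cell and drug identities between train and test
  within a study; blind-split strategies (cell-blind, drug-blind) are out of
  scope here but the split files make them easy to add externally.
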