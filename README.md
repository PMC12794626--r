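# drpbench

Cross-dataset generalization benchmarking for drug response prediction (DRP).

DRP models regress a continuous treatment-response readout — here the
normalized area under the dose–response curve (AUC) — on cancer-sample
features (omics) and drug features (fingerprints, descriptors). Models that
look excellent under cross-validation *within* one drug screening study
often collapse when asked to predict responses measured by a *different*
study, because screens differ in assay chemistry, dose ranges, and compound
panels. `drpbench` packages the machinery needed to measure that collapse
systematically:

* **Dose–response curves.** Each (cell line, drug) pair's viability
  measurements are fitted to a three-parameter Hill-slope curve
  `v(c) = E_inf + (1 − E_inf) / (1 + (c / EC50)^h)`, pairs with fit
  R² < 0.3 are excluded, and the response label is the fitted-curve AUC over
  the dose range [10⁻¹⁰ M, 10⁻⁴ M] on the log₁₀-dose axis, normalized to
  [0, 1] (lower AUC = stronger growth inhibition).
* **Benchmark bundles.** A response table, an omics matrix, and drug feature
  matrices joined by shared cell/drug identifiers, plus N = 10 reproducible
  train/validation/test splits in (0.8, 0.1, 0.1) proportions stored as
  plain-text row-index files.
* **A standardized pipeline contract.** Separate preprocess, train, and
  infer stages with tiered parameter resolution (command line > config file
  > defaults), train-only feature scaling, validation-based early stopping
  that always keeps the best checkpoint, and consistently named outputs.
  Baseline regressors (gradient-boosted trees, ridge, a small MLP) ship
  behind a registry; any model conforming to the contract can be plugged in.
* **The d × d workflow.** For each source dataset `s`, one model instance is
  trained per split (d·N trainings per model) and evaluated on its held-out
  test split (within-dataset, `s = t`) and on every other dataset's full
  response table (cross-dataset, `s ≠ t`) — d·N·d evaluations, no
  retraining per target.
* **Generalization metrics.** With `g[s,t]` the split-averaged R²:

  - `G`: the d × d matrix of `g[s,t]` (mean ± std across splits);
  - `Ga`: `g_a[s] = (1/(d−1)) Σ_{t≠s} g[s,t]`, absolute cross-dataset
    performance per source;
  - `Gn`: `g_n[s,t] = g[s,t] / g[s,s]`, performance retained relative to the
    within-dataset baseline (masked when `g[s,s] ≤ 0`);
  - `Gna`: off-diagonal row means of `Gn`;
  - source-to-target coverage `C_D(s,t) = |D_s ∩ D_t| / |D_t|` (drugs) and
    `C_C(s,t)` (cells), their Spearman correlation with `g(s,t)`, metric
    gaps Δ between models, and pairwise Wilcoxon signed-rank tests.
* **A synthetic multi-study generator** with a known low-rank response
  surface, controllable drug/cell overlap, and per-study assay distortions,
  so the entire workflow is exercisable end-to-end without any external
  download.

## Worked example

Four synthetic studies of 150 cells × 30 drugs sharing 60% of their drugs,
with strong study-specific assay distortions; a gradient-boosted-tree
baseline; 3 splits per source:

```r
library(drpbench)

specs <- lapply(1:4, function(i) study_spec(paste0("s", i), n_cells = 150, n_drugs = 30))
world <- simulate_world(synth_world_config(
  n_cells_total = 500, n_drugs_total = 150, study_specs = specs,
  assay_shift_sd = 0.3, seed = 7))
bundles <- emit_all_studies(world, n_splits = 3)

plan  <- plan_experiment(names(bundles), models = "gbt", n_splits = 3)
store <- execute_plan(plan, bundles, out_dir = file.path(tempdir(), "runs"), seed = 7)

G <- build_g(store, "gbt")
round(G$mean, 3)
#>        s1     s2     s3     s4
#> s1  0.346  0.106  0.225  0.114
#> s2  0.188  0.369 -0.050 -0.253
#> s3  0.211 -0.207  0.397  0.303
#> s4 -0.017 -0.750  0.254  0.396

round(aggregate_ga(G), 3)
#>     s1     s2     s3     s4
#>  0.148 -0.038  0.102 -0.171

round(as.numeric(aggregate_gna(normalize_gn(G))), 3)
#> [1]  0.428 -0.104  0.258 -0.433
```

Reading the output: the diagonal of `G` (0.35–0.40) is the within-dataset
R² — the model explains over a third of the response variance on held-out
splits of its own study. Every off-diagonal entry is lower, several are
negative (worse than predicting the target's mean response): the assay
distortions break transfer, exactly the pattern this framework is built to
expose. `Ga` ranks sources by absolute transfer; `Gna` shows the fraction of
within-dataset skill retained — source `s1` keeps ~43% of its baseline
performance on foreign studies, source `s4` loses more than it had.

A command-line interface wrapping the same functions is installed with the
package (`system.file("cli", "drpbench.R", package = "drpbench")`), with
subcommands `curves-fit`, `build-splits`, `featurize`, `make-world`,
`cross-dataset`, and `aggregate`.

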