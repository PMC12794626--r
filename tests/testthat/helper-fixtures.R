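# Shared fixtures: compact synthetic worlds and independent metric oracles.

tiny_world <- function(seed = 7, n_studies = 2, n_cells = 60, n_drugs = 20,
                       assay_shift_sd = 0.15, drug_overlap = 0.6,
                       cell_overlap = 0.8, noise_sd = 0.05) {
  specs <- lapply(seq_len(n_studies), function(i) {
    ov_d <- if (length(drug_overlap) > 1) drug_overlap[i] else drug_overlap
    study_spec(paste0("s", i), n_cells, n_drugs, drug_overlap = ov_d,
               cell_overlap = cell_overlap)
  })
  simulate_world(synth_world_config(
    n_cells_total = n_studies * n_cells + n_cells,
    n_drugs_total = n_studies * n_drugs + n_drugs,
    study_specs = specs, assay_shift_sd = assay_shift_sd,
    noise_sd = noise_sd, seed = seed))
}

# A deliberately linear learnable regression fixture in preprocess_stage
# output form (y = w . x + small noise).
linear_sets <- function(seed = 1, n = 600, p = 12, noise_sd = 0.05) {
  set.seed(seed)
  mk <- function(n) {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("omics.f", seq_len(p))))
    w <- seq_len(p) / p
    y <- as.numeric(x %*% w) + rnorm(n, sd = noise_sd)
    list(x = x, y = y,
         ids = data.frame(cell_id = paste0("c", seq_len(n)),
                          drug_id = paste0("d", seq_len(n))))
  }
  list(train = mk(n), val = mk(n %/% 3), test = mk(n %/% 3),
       feature_names = paste0("omics.f", seq_len(p)))
}

# Independent loop-based oracles for the metric algebra.
oracle_g <- function(scores, datasets, splits) {
  d <- length(datasets)
  mean_m <- std_m <- matrix(NA_real_, d, d, dimnames = list(datasets, datasets))
  for (s in seq_len(d)) for (t in seq_len(d)) {
    v <- numeric(0)
    for (n in splits) {
      v <- c(v, scores[[paste(datasets[s], datasets[t], n)]])
    }
    mean_m[s, t] <- sum(v) / length(v)
    std_m[s, t] <- if (length(v) > 1) sqrt(sum((v - mean(v))^2) / (length(v) - 1)) else 0
  }
  list(mean = mean_m, std = std_m)
}

oracle_ga <- function(mean_m) {
  d <- nrow(mean_m)
  out <- numeric(d)
  for (s in seq_len(d)) {
    acc <- 0
    for (t in seq_len(d)) if (t != s) acc <- acc + mean_m[s, t]
    out[s] <- acc / (d - 1)
  }
  out
}

oracle_gn <- function(mean_m) {
  d <- nrow(mean_m)
  out <- matrix(NA_real_, d, d)
  for (s in seq_len(d)) for (t in seq_len(d)) {
    if (mean_m[s, s] > 0) out[s, t] <- mean_m[s, t] / mean_m[s, s]
  }
  out
}

oracle_gna <- function(gn_m) {
  d <- nrow(gn_m)
  out <- numeric(d)
  for (s in seq_len(d)) {
    v <- gn_m[s, -s]
    out[s] <- if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)])
  }
  out
}

# Random complete score store for oracle-equivalence checks.
random_store <- function(d, n_splits, model = "m", seed = 1) {
  set.seed(seed)
  datasets <- paste0("ds", seq_len(d))
  grid <- expand.grid(source = datasets, target = datasets,
                      split = seq_len(n_splits), stringsAsFactors = FALSE)
  grid$model <- model
  grid$r_squared <- runif(nrow(grid), -1, 1)
  grid$stage <- ifelse(grid$source == grid$target, "within", "cross")
  structure(grid[, c("model", "source", "target", "split", "r_squared", "stage")],
            class = c("score_store", "data.frame"))
}

# Dense trapezoid quadrature oracle for the normalized AUC.
quadrature_auc <- function(params, config, n_points = 1e5) {
  x <- seq(log10(config$dose_lo), log10(config$dose_hi), length.out = n_points)
  v <- pmin(pmax(hill_viability(params, 10^x), 0), 1)
  sum(diff(x) * (v[-1] + v[-n_points]) / 2) / (x[n_points] - x[1])
}

make_fit <- function(cell, drug, r2, converged = TRUE, auc = 0.5) {
  list(cell_id = cell, drug_id = drug,
       fit = drpbench:::curve_fit_result(
         params = if (converged) hill_params(1e-7, 1, 0.1) else NULL,
         r_squared = if (converged) r2 else NA_real_,
         converged = converged,
         reason = if (converged) NA_character_ else "degenerate",
         auc = if (converged) auc else NA_real_))
}
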