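# Generalization metric family: R^2 scores, the d x d cross-dataset matrix G
# (mean +/- std over splits), its off-diagonal aggregation Ga, the
# within-dataset-normalized matrix Gn and its aggregation Gna, coverage
# matrices, coverage-performance correlation, and paired model comparisons.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of `y_true`. The value is 1 for perfect predictions, 0 for a predictor
#' equivalent to the naive mean of the observed responses, and negative for
#' predictors worse than that mean.
#'
#' @param y_true Observed values (length >= 2, nonzero variance).
#' @param y_pred Predicted values.
#' @return The R-squared value (may be negative, never above 1).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    drp_error("'y_true' and 'y_pred' must have equal length", "drp_domain_error")
  }
  if (length(y_true) < 2L) {
    drp_error("need at least 2 observations", "drp_domain_error")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    drp_error("R^2 undefined: 'y_true' has zero variance", "drp_undefined_score")
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Build the cross-dataset performance matrix G
#'
#' Each entry `g[s, t]` is the mean, over the N data splits, of the R-squared
#' score of the model trained on source dataset `s` and evaluated on target
#' dataset `t` (the held-out test split when `s == t`, the full target table
#' otherwise). The per-entry standard deviation across splits is reported
#' alongside (sample standard deviation, denominator N - 1; defined as 0 when
#' N = 1).
#'
#' @param store A score store data frame with columns `model`, `source`,
#'   `target`, `split`, `r_squared` (see [collect_scores()]).
#' @param model Registry name of the model to extract.
#' @param datasets Optional dataset ordering; defaults to sorted unique names.
#' @return An object of class `g_matrix` with fields `mean`, `std`
#'   (d x d matrices), `datasets`, `n_splits`.
#' @export
build_g <- function(store, model, datasets = NULL) {
  df <- store[store$model == model, , drop = FALSE]
  if (nrow(df) == 0L) {
    drp_error(sprintf("no scores for model '%s'", model), "drp_incomplete_store")
  }
  datasets <- datasets %||% sort(unique(c(df$source, df$target)))
  splits <- sort(unique(df$split))
  n <- length(splits)
  want <- expand.grid(source = datasets, target = datasets, split = splits,
                      stringsAsFactors = FALSE)
  have <- paste(df$source, df$target, df$split)
  missing <- !(paste(want$source, want$target, want$split) %in% have)
  if (any(missing)) {
    ex <- utils::head(want[missing, ], 5)
    drp_error(sprintf(
      "score store incomplete for model '%s': %d missing (s, t, n) cells, e.g. %s",
      model, sum(missing),
      paste(sprintf("(%s,%s,%d)", ex$source, ex$target, ex$split), collapse = " ")),
      "drp_incomplete_store")
  }
  d <- length(datasets)
  mean_m <- std_m <- matrix(NA_real_, d, d, dimnames = list(datasets, datasets))
  for (s in datasets) {
    for (t in datasets) {
      g <- df$r_squared[df$source == s & df$target == t]
      mean_m[s, t] <- mean(g)
      std_m[s, t] <- if (n > 1L) stats::sd(g) else 0
    }
  }
  structure(list(mean = mean_m, std = std_m, datasets = datasets,
                 n_splits = n), class = "g_matrix")
}

#' @export
print.g_matrix <- function(x, ...) {
  cat(sprintf("<g_matrix> %d datasets, %d splits\n", length(x$datasets),
              x$n_splits))
  print(round(x$mean, 4))
  invisible(x)
}

#' Aggregated cross-dataset performance Ga
#'
#' For each source dataset `s`, the mean of `g[s, t]` over the `d - 1` target
#' datasets `t != s` — a single absolute-generalization summary per source,
#' unaffected by within-dataset performance.
#'
#' @param G A [build_g()] result.
#' @return Named numeric vector `g_a[s]` of length d.
#' @export
aggregate_ga <- function(G) {
  stopifnot(inherits(G, "g_matrix"))
  d <- length(G$datasets)
  if (d < 2L) drp_error("Ga undefined for a single dataset", "drp_undefined_metric")
  vapply(seq_len(d), function(s) mean(G$mean[s, -s]), 0) |>
    stats::setNames(G$datasets)
}

#' Normalized cross-dataset performance matrix Gn
#'
#' Scales each entry `g[s, t]` by the within-dataset performance `g[s, s]`,
#' giving the fraction of within-dataset performance retained on the target.
#' Rows whose within-dataset score is not strictly positive are masked (the
#' ratio is meaningless for a non-positive baseline) with a warning; note
#' also that high normalized values can be misleading when the within-dataset
#' baseline is low.
#'
#' @param G A [build_g()] result.
#' @return An object of class `gn_matrix` with fields `values` (d x d matrix,
#'   `NA` where masked), `defined` (logical mask), `datasets`.
#' @export
normalize_gn <- function(G) {
  stopifnot(inherits(G, "g_matrix"))
  d <- length(G$datasets)
  vals <- G$mean / diag(G$mean)   # row s divided by g[s, s] (column recycling)
  defined <- matrix(rep(diag(G$mean) > 0, d), d, d)
  dimnames(defined) <- dimnames(vals)
  if (any(!defined)) {
    warning(sprintf("Gn undefined for source row(s) with g[s,s] <= 0: %s",
                    paste(G$datasets[diag(G$mean) <= 0], collapse = ", ")))
    vals[!defined] <- NA_real_
  }
  structure(list(values = vals, defined = defined, datasets = G$datasets),
            class = "gn_matrix")
}

#' Aggregated normalized cross-dataset performance Gna
#'
#' Off-diagonal row means of the normalized matrix, over defined entries
#' only. Rows containing masked entries are flagged; a fully masked row
#' yields `NA`.
#'
#' @param Gn A [normalize_gn()] result.
#' @return Named numeric vector `g_na[s]` with a logical `flagged` attribute
#'   marking rows with any masked entry.
#' @export
aggregate_gna <- function(Gn) {
  stopifnot(inherits(Gn, "gn_matrix"))
  d <- length(Gn$datasets)
  if (d < 2L) drp_error("Gna undefined for a single dataset", "drp_undefined_metric")
  out <- vapply(seq_len(d), function(s) {
    v <- Gn$values[s, -s]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  names(out) <- Gn$datasets
  flagged <- vapply(seq_len(d), function(s) anyNA(Gn$values[s, -s]), TRUE)
  names(flagged) <- Gn$datasets
  attr(out, "flagged") <- flagged
  out
}

#' Gap between two metric values
#'
#' Reports the exact difference `a - b` alongside both operands, as used when
#' contrasting two models' Ga/Gna (or G/Gn entries) on the same source.
#'
#' @param a,b Metric values (scalars).
#' @return List with fields `a`, `b`, `delta` (`a - b`).
#' @export
metric_gap <- function(a, b) {
  if (is.na(a) || is.na(b)) {
    return(list(a = a, b = b, delta = NA_real_))
  }
  list(a = a, b = b, delta = a - b)
}

#' Source-to-target entity coverage
#'
#' For entity sets per dataset (unique drugs or unique cell lines), computes
#' `cov[s, t] = |S_s intersect S_t| / |S_t|`: the fraction of the *target*
#' dataset's entities also present in the source. The matrix is asymmetric
#' whenever set sizes differ.
#'
#' @param sets Named list of character vectors, one entity set per dataset.
#' @param kind Label, `"drug"` or `"cell"`.
#' @return An object of class `coverage_matrix` with fields `values`
#'   (d x d, `NA` where the target set is empty), `kind`, `datasets`.
#' @export
coverage <- function(sets, kind = c("drug", "cell")) {
  kind <- match.arg(kind)
  stopifnot(is.list(sets), !is.null(names(sets)))
  datasets <- names(sets)
  d <- length(datasets)
  m <- matrix(NA_real_, d, d, dimnames = list(datasets, datasets))
  for (s in seq_len(d)) {
    for (t in seq_len(d)) {
      nt <- length(unique(sets[[t]]))
      m[s, t] <- if (nt == 0) NA_real_ else
        length(intersect(sets[[s]], sets[[t]])) / nt
    }
  }
  if (anyNA(m)) warning("coverage undefined for empty target set(s)")
  structure(list(values = m, kind = kind, datasets = datasets),
            class = "coverage_matrix")
}

#' Entity sets of a list of bundles
#'
#' @param bundles Named list of [assemble_bundle()] objects (or response
#'   tables).
#' @param kind `"drug"` or `"cell"`.
#' @return Named list of unique entity id vectors, for [coverage()].
#' @export
bundle_entity_sets <- function(bundles, kind = c("drug", "cell")) {
  kind <- match.arg(kind)
  col <- if (kind == "drug") "drug_id" else "cell_id"
  lapply(bundles, function(b) {
    resp <- if (inherits(b, "benchmark_bundle")) b$response else b
    unique(resp[[col]])
  })
}

#' Spearman correlation between coverage and cross-dataset performance
#'
#' Rank correlation (average ranks for ties) between the `d (d - 1)`
#' off-diagonal coverage entries and the corresponding off-diagonal `g[s, t]`
#' scores.
#'
#' @param G A [build_g()] result.
#' @param C A [coverage()] result over the same datasets in the same order.
#' @return List with `rho`, `n_pairs`, and `kind`.
#' @export
coverage_correlation <- function(G, C) {
  stopifnot(inherits(G, "g_matrix"), inherits(C, "coverage_matrix"),
            identical(G$datasets, C$datasets))
  d <- length(G$datasets)
  if (d < 3L) {
    drp_error("need at least 3 datasets (6 off-diagonal pairs)",
              "drp_undefined_metric")
  }
  off <- !diag(d)
  g <- G$mean[off]
  cv <- C$values[off]
  if (stats::sd(g) == 0 || stats::sd(cv, na.rm = TRUE) == 0) {
    warning("correlation undefined for constant vector")
    return(list(rho = NA_real_, n_pairs = sum(off), kind = C$kind))
  }
  list(rho = stats::cor(cv, g, method = "spearman", use = "complete.obs"),
       n_pairs = sum(off), kind = C$kind)
}

#' Pairwise model comparisons on cross-dataset scores
#'
#' Two-sided Wilcoxon signed-rank tests between every pair of models. The
#' default pairing unit is the `d (d - 1)` off-diagonal (source, target)
#' cells using split-averaged scores; `unit = "pair-split"` pairs on
#' individual (source, target, split) scores instead. No multiple-testing
#' correction is applied by default (`correction = "none"`); any
#' [stats::p.adjust()] method may be requested.
#'
#' @param store Score store data frame (see [collect_scores()]).
#' @param models Character vector of at least two registry names.
#' @param unit Pairing unit, `"pair"` (default) or `"pair-split"`.
#' @param correction Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"`.
#' @return An object of class `comparison_report`: list with `p_values`
#'   (symmetric matrix, `NA` where the test is undefined), `unit`,
#'   `correction`, and `n_units`.
#' @export
pairwise_model_tests <- function(store, models, unit = c("pair", "pair-split"),
                                 correction = "none") {
  unit <- match.arg(unit)
  if (length(models) < 2L) {
    drp_error("need at least two models to compare", "drp_config_error")
  }
  cross <- store[store$source != store$target, , drop = FALSE]
  score_vec <- function(model) {
    df <- cross[cross$model == model, , drop = FALSE]
    if (unit == "pair") {
      key <- paste(df$source, df$target)
      tapply(df$r_squared, key, mean)
    } else {
      key <- paste(df$source, df$target, df$split)
      stats::setNames(df$r_squared, key)[order(key)]
    }
  }
  vecs <- lapply(stats::setNames(models, models), score_vec)
  keys <- Reduce(intersect, lapply(vecs, names))
  if (length(keys) < 2L) {
    drp_error("fewer than 2 shared cross-dataset units across models",
              "drp_incomplete_store")
  }
  k <- length(models)
  p <- matrix(NA_real_, k, k, dimnames = list(models, models))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      dif <- vecs[[i]][keys] - vecs[[j]][keys]
      if (all(dif == 0)) {
        warning(sprintf("test undefined for %s vs %s: all differences zero",
                        models[i], models[j]))
        next
      }
      p[i, j] <- p[j, i] <- suppressWarnings(
        stats::wilcox.test(vecs[[i]][keys], vecs[[j]][keys],
                           paired = TRUE)$p.value)
    }
  }
  upper <- p[upper.tri(p)]
  p[upper.tri(p)] <- stats::p.adjust(upper, method = correction)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(p_values = p, unit = unit, correction = correction,
                 n_units = length(keys)), class = "comparison_report")
}

fmt_matrix_csv <- function(m, path) {
  df <- data.frame(dataset = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write metric reports to a directory
#'
#' Writes `G_mean.csv`, `G_std.csv`, `Ga.csv`, `Gn.csv`, `Gna.csv`, coverage
#' CSVs, a combined `metrics.json`, and (optionally) heatmap PNGs whose cells
#' show `mean +/- std`. Masked normalized entries are rendered as `NA` and a
#' footnote file lists them.
#'
#' @param G A [build_g()] result.
#' @param out_dir Output directory, created if needed.
#' @param coverage_drug,coverage_cell Optional [coverage()] results.
#' @param comparisons Optional [pairwise_model_tests()] result.
#' @param heatmaps Render PNG heatmaps (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(G, out_dir, coverage_drug = NULL,
                           coverage_cell = NULL, comparisons = NULL,
                           heatmaps = TRUE) {
  stopifnot(inherits(G, "g_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Gn <- suppressWarnings(normalize_gn(G))
  paths <- character(0)
  wr <- function(m, name) {
    p <- file.path(out_dir, name)
    fmt_matrix_csv(round(m, 6), p)
    paths <<- c(paths, p)
  }
  wr(G$mean, "G_mean.csv")
  wr(G$std, "G_std.csv")
  wr(Gn$values, "Gn.csv")
  ga <- if (length(G$datasets) > 1) aggregate_ga(G) else NULL
  gna <- if (length(G$datasets) > 1) aggregate_gna(Gn) else NULL
  if (!is.null(ga)) {
    utils::write.csv(data.frame(dataset = names(ga), ga = round(ga, 6),
                                gna = round(as.numeric(gna), 6)),
                     file.path(out_dir, "Ga.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(dataset = names(gna),
                                gna = round(as.numeric(gna), 6)),
                     file.path(out_dir, "Gna.csv"), row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, file.path(out_dir, c("Ga.csv", "Gna.csv")))
  }
  if (!is.null(coverage_drug)) wr(coverage_drug$values, "coverage_drug.csv")
  if (!is.null(coverage_cell)) wr(coverage_cell$values, "coverage_cell.csv")
  combined <- list(datasets = G$datasets, n_splits = G$n_splits,
                   G_mean = G$mean, G_std = G$std, Gn = Gn$values,
                   Ga = as.list(ga), Gna = as.list(gna))
  if (!is.null(comparisons)) {
    combined$comparisons <- list(p_values = comparisons$p_values,
                                 unit = comparisons$unit,
                                 correction = comparisons$correction)
    jsonlite::write_json(combined$comparisons,
                         file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, file.path(out_dir, "comparisons.json"))
  }
  jsonlite::write_json(combined, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, file.path(out_dir, "metrics.json"))
  if (any(!Gn$defined)) {
    writeLines(c("Masked normalized entries (within-dataset g[s,s] <= 0);",
                 "rendered as NA in Gn.csv and excluded from Gna:",
                 paste0("  source row: ",
                        G$datasets[diag(G$mean) <= 0])),
               file.path(out_dir, "Gn_footnote.txt"))
    paths <- c(paths, file.path(out_dir, "Gn_footnote.txt"))
  }
  if (heatmaps) {
    lab <- matrix(sprintf("%.3f ± %.3f", G$mean, G$std),
                  nrow = nrow(G$mean))
    for (nm in c("G", "Gn")) {
      m <- if (nm == "G") G$mean else Gn$values
      labels <- if (nm == "G") lab else
        matrix(ifelse(is.na(Gn$values), "NA", sprintf("%.3f", Gn$values)),
               nrow = nrow(m))
      p <- file.path(out_dir, paste0(nm, "_heatmap.png"))
      m_plot <- m
      m_plot[is.na(m_plot)] <- 0
      rng <- range(m_plot)
      if (diff(rng) == 0) rng <- rng + c(-1e-6, 1e-6)  # constant matrix guard
      grDevices::png(p, width = 720, height = 640)
      pheatmap::pheatmap(m_plot, cluster_rows = FALSE, cluster_cols = FALSE,
                         display_numbers = labels, main = nm,
                         breaks = seq(rng[1], rng[2], length.out = 101))
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
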