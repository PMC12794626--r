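# Dose-response curve fitting and AUC derivation.
#
# Viability is modelled with the three-parameter Hill-slope curve
#   v(c) = e_inf + (1 - e_inf) / (1 + (c / ec50)^h),
# i.e. a descending sigmoid on log-dose with the untreated asymptote fixed at 1,
# lower asymptote e_inf in [0, 1], half-effect dose ec50 (M) and Hill slope h.

#' Three-parameter Hill-slope parameters
#'
#' @param ec50 Half-maximal effective dose in molar units (> 0).
#' @param slope Hill slope (> 0); larger values give steeper transitions.
#' @param e_inf Asymptotic viability at infinite dose, in `[0, 1]`.
#' @return An object of class `hill_params`.
#' @examples
#' p <- hill_params(ec50 = 1e-7, slope = 1.5, e_inf = 0.1)
#' hill_viability(p, 1e-7)
#' @export
hill_params <- function(ec50, slope, e_inf) {
  stopifnot(length(ec50) == 1L, length(slope) == 1L, length(e_inf) == 1L)
  if (!is.finite(ec50) || ec50 <= 0) {
    drp_error("'ec50' must be a positive molar dose", "drp_domain_error")
  }
  if (!is.finite(slope) || slope <= 0) {
    drp_error("'slope' must be positive", "drp_domain_error")
  }
  if (!is.finite(e_inf) || e_inf < 0 || e_inf > 1) {
    drp_error("'e_inf' must lie in [0, 1]", "drp_domain_error")
  }
  structure(list(ec50 = ec50, slope = slope, e_inf = e_inf),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> ec50 = %.4g M, slope = %.3g, e_inf = %.3g\n",
              x$ec50, x$slope, x$e_inf))
  invisible(x)
}

#' Curve-fitting and AUC configuration
#'
#' @param dose_lo,dose_hi Integration bounds for the normalized AUC, in molar
#'   units. Defaults cover the six-decade range `[1e-10, 1e-4]` M.
#' @param r2_min Minimum fit R-squared for a cell-drug pair to be retained
#'   (pairs with R-squared strictly below the threshold are excluded).
#' @return An object of class `curve_config`.
#' @export
curve_config <- function(dose_lo = 1e-10, dose_hi = 1e-4, r2_min = 0.3) {
  if (!is.finite(dose_lo) || !is.finite(dose_hi) || dose_lo <= 0 ||
      dose_lo >= dose_hi) {
    drp_error("need 0 < dose_lo < dose_hi", "drp_config_error")
  }
  if (r2_min < 0 || r2_min > 1) {
    drp_error("'r2_min' must lie in [0, 1]", "drp_config_error")
  }
  structure(list(dose_lo = dose_lo, dose_hi = dose_hi, r2_min = r2_min),
            class = "curve_config")
}

#' Hill-slope viability at given doses
#'
#' Evaluates `v(c) = e_inf + (1 - e_inf) / (1 + (c/ec50)^slope)`, which is
#' monotonically non-increasing in dose, equals `(1 + e_inf)/2` at `c = ec50`,
#' and tends to 1 as dose tends to 0 and to `e_inf` as dose grows.
#'
#' @param params A [hill_params()] object.
#' @param dose Vector of strictly positive molar doses.
#' @return Viability fractions in `[e_inf, 1]`.
#' @export
hill_viability <- function(params, dose) {
  stopifnot(inherits(params, "hill_params"))
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    drp_error("doses must be finite and strictly positive", "drp_domain_error")
  }
  # evaluate on the log scale to avoid overflow at extreme dose/ec50 ratios
  z <- params$slope * (log10(dose) - log10(params$ec50))
  params$e_inf + (1 - params$e_inf) / (1 + 10^pmin(z, 300))
}

# log10(1 + 10^z), overflow-safe
log1p10 <- function(z) ifelse(z > 30, z, log10(1 + 10^z))

#' Normalized area under the fitted dose-response curve
#'
#' Integrates the fitted viability curve over log10-dose between
#' `config$dose_lo` and `config$dose_hi` (viability clipped to `[0, 1]`) and
#' divides by the width of the log10 range, giving an AUC in `[0, 1]`. Lower
#' values indicate stronger growth inhibition; a flat no-effect curve
#' (`e_inf = 1`) has AUC exactly 1. The integral has a closed form for the
#' Hill-slope model, which is used here.
#'
#' @param params A [hill_params()] object.
#' @param config A [curve_config()] object.
#' @return AUC in `[0, 1]`.
#' @export
normalized_auc <- function(params, config = curve_config()) {
  stopifnot(inherits(params, "hill_params"), inherits(config, "curve_config"))
  a <- log10(config$dose_lo)
  b <- log10(config$dose_hi)
  m <- log10(params$ec50)
  h <- params$slope
  # closed form of (1 / (b - a)) * int_a^b 1 / (1 + 10^(h (x - m))) dx
  frac <- (b - a) - (log1p10(h * (b - m)) - log1p10(h * (a - m))) / h
  auc <- (params$e_inf * (b - a) + (1 - params$e_inf) * frac) / (b - a)
  min(max(auc, 0), 1)
}

#' A dose-response curve for one cell-drug pair
#'
#' @param cell_id,drug_id Identifiers of the pair.
#' @param dose Molar doses (strictly positive, distinct).
#' @param viability Measured viability fractions (finite; raw values may
#'   slightly exceed 1).
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(cell_id, drug_id, dose, viability) {
  if (length(dose) != length(viability)) {
    drp_error("'dose' and 'viability' must have equal length", "drp_domain_error")
  }
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    drp_error("doses must be finite and strictly positive", "drp_domain_error")
  }
  if (any(duplicated(dose))) {
    drp_error("doses must be distinct", "drp_domain_error")
  }
  if (any(!is.finite(viability))) {
    drp_error("viabilities must be finite", "drp_domain_error")
  }
  structure(list(cell_id = as.character(cell_id),
                 drug_id = as.character(drug_id),
                 dose = as.numeric(dose), viability = as.numeric(viability)),
            class = "dose_response_curve")
}

curve_fit_result <- function(params = NULL, r_squared = NA_real_,
                             converged = FALSE, reason = NA_character_,
                             auc = NA_real_) {
  structure(list(params = params, r_squared = r_squared,
                 converged = converged, reason = reason, auc = auc),
            class = "curve_fit_result")
}

#' Fit a three-parameter Hill-slope curve to one cell-drug pair
#'
#' Nonlinear least squares on log10-dose (Levenberg-Marquardt with box
#' bounds), minimizing squared viability residuals. To be robust to local
#' minima, the optimizer is started from a 3x3x3 grid: ec50 at the 25/50/75%
#' dose quantiles, slope in `{0.5, 1, 2}`, `e_inf` in `{0, 0.25, 0.5}`; the
#' start with the lowest sum of squared errors wins. Bounds:
#' ec50 in `[1e-12, 1e-2]` M, slope in `[0.05, 10]`, `e_inf` in `[0, 1]`.
#'
#' Degenerate data (constant viability) yields `converged = FALSE` with a
#' `"degenerate"` reason rather than an error; fewer than 4 points raises an
#' insufficient-data error (batch drivers catch it, see
#' [fit_response_data()]).
#'
#' @param curve A [dose_response_curve()].
#' @param config A [curve_config()]; used for the AUC of the fitted curve and
#'   carried into downstream filtering.
#' @return A `curve_fit_result` with fields `params`, `r_squared`,
#'   `converged`, `reason`, and `auc` (normalized AUC, only when converged).
#' @export
fit_hill_curve <- function(curve, config = curve_config()) {
  stopifnot(inherits(curve, "dose_response_curve"),
            inherits(config, "curve_config"))
  n <- length(curve$dose)
  if (n < 4L) {
    drp_error(sprintf("need at least 4 dose points to fit, got %d", n),
              "drp_insufficient_data")
  }
  v <- curve$viability
  x <- log10(curve$dose)
  sst <- sum((v - mean(v))^2)
  if (sst == 0) {
    return(curve_fit_result(converged = FALSE, reason = "degenerate"))
  }

  lower <- c(log_ec50 = -12, slope = 0.05, e_inf = 0)
  upper <- c(log_ec50 = -2, slope = 10, e_inf = 1)
  starts <- expand.grid(
    log_ec50 = as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75))),
    slope = c(0.5, 1, 2),
    e_inf = c(0, 0.25, 0.5)
  )
  starts$log_ec50 <- pmin(pmax(starts$log_ec50, lower[1]), upper[1])

  best <- NULL
  best_sse <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ e_inf + (1 - e_inf) / (1 + 10^(slope * (x - log_ec50))),
        data = data.frame(v = v, x = x),
        start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
      # a numerically perfect fit cannot be improved; skip remaining starts
      if (sse < 1e-16 * max(sst, 1)) break
    }
  }
  if (is.null(best)) {
    return(curve_fit_result(converged = FALSE, reason = "optimizer_failure"))
  }
  est <- stats::coef(best)
  params <- hill_params(ec50 = 10^est[["log_ec50"]], slope = est[["slope"]],
                        e_inf = est[["e_inf"]])
  r2 <- 1 - best_sse / sst
  curve_fit_result(params = params, r_squared = r2, converged = TRUE,
                   reason = NA_character_,
                   auc = normalized_auc(params, config))
}

#' @export
print.curve_fit_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<curve_fit_result> converged, R^2 = %.4f, AUC = %.4f\n",
                x$r_squared, x$auc))
    print(x$params)
  } else {
    cat(sprintf("<curve_fit_result> not converged (%s)\n", x$reason))
  }
  invisible(x)
}

#' Fit all cell-drug pairs in a raw dose-response table
#'
#' Splits a long-format table (one row per dose point) by cell-drug pair and
#' fits each pair with [fit_hill_curve()]. Pairs with fewer than 4 points or
#' failed/degenerate fits are recorded as non-converged so a batch run always
#' completes.
#'
#' @param data Data frame with columns `cell_id`, `drug_id`, `dose_M`,
#'   `viability`.
#' @param config A [curve_config()].
#' @return A list of entries `list(cell_id, drug_id, fit)`, one per pair, in
#'   first-appearance order.
#' @export
fit_response_data <- function(data, config = curve_config()) {
  req <- c("cell_id", "drug_id", "dose_M", "viability")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    drp_error(paste0("missing column(s): ", paste(miss, collapse = ", ")),
              "drp_schema_error")
  }
  key <- paste(data$cell_id, data$drug_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(data)), factor(key, levels = unique(key))),
                function(idx) {
    rows <- data[idx, ]
    fit <- tryCatch(
      fit_hill_curve(dose_response_curve(rows$cell_id[1], rows$drug_id[1],
                                         rows$dose_M, rows$viability), config),
      drp_insufficient_data = function(e) {
        curve_fit_result(converged = FALSE, reason = "insufficient_data")
      },
      drp_domain_error = function(e) {
        curve_fit_result(converged = FALSE, reason = "invalid_points")
      }
    )
    list(cell_id = as.character(rows$cell_id[1]),
         drug_id = as.character(rows$drug_id[1]), fit = fit)
  })
  names(out) <- NULL
  out
}

#' Filter fits into a benchmark response table
#'
#' Retains exactly the converged fits whose R-squared is at or above
#' `config$r2_min` (exclusion is strict `< r2_min`, so a boundary fit at the
#' threshold is kept) and emits one AUC response sample per retained pair.
#'
#' @param fits A list as returned by [fit_response_data()].
#' @param config A [curve_config()].
#' @param dataset_name Study label attached to the table.
#' @return A [response_table()] data frame with columns `cell_id`, `drug_id`,
#'   `auc`; attributes `n_input` and `n_retained` carry retention counts, and
#'   attribute `qc` holds a per-pair QC data frame (`r_squared`, `converged`,
#'   `retained`).
#' @export
build_response_table <- function(fits, config = curve_config(),
                                 dataset_name = "unnamed") {
  qc <- data.frame(
    cell_id = vapply(fits, `[[`, "", "cell_id"),
    drug_id = vapply(fits, `[[`, "", "drug_id"),
    r_squared = vapply(fits, function(f) f$fit$r_squared, 0),
    converged = vapply(fits, function(f) f$fit$converged, TRUE),
    stringsAsFactors = FALSE
  )
  qc$retained <- qc$converged & !is.na(qc$r_squared) &
    qc$r_squared >= config$r2_min
  keep <- which(qc$retained)
  tab <- data.frame(
    cell_id = qc$cell_id[keep],
    drug_id = qc$drug_id[keep],
    auc = vapply(fits[keep], function(f) f$fit$auc, 0),
    stringsAsFactors = FALSE
  )
  message(sprintf("retained %d of %d pairs (R^2 >= %.2f)",
                  length(keep), length(fits), config$r2_min))
  tab <- response_table(tab, dataset_name = dataset_name)
  attr(tab, "n_input") <- length(fits)
  attr(tab, "n_retained") <- length(keep)
  attr(tab, "qc") <- qc
  tab
}
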