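# Standardized three-stage model pipeline: tiered configuration resolution,
# preprocess / train / infer stage contracts, early stopping, and consistently
# named run-directory outputs.

#' Resolve a tiered stage configuration
#'
#' Merges three parameter tiers with the precedence command line > config
#' file > defaults, recording the provenance of every key. Defaults are
#' organized into three sections: `framework` (logging, paths, seed),
#' `application` (feature kinds, dataset/split names), and `model`
#' (model-specific hyperparameters); command-line and file values are flat
#' key-value pairs matched to their section by key name.
#'
#' @param cli_args Named list of command-line overrides (may be empty).
#' @param config_file Path to a YAML file, a named list, or `NULL`.
#' @param defaults Named list with elements `framework`, `application`,
#'   `model`, each a complete named list of defaults for the stage.
#' @return An object of class `stage_config`: the three resolved sections
#'   plus a `provenance` map (`"cli"`, `"config_file"` or `"default"` per
#'   key).
#' @export
resolve_config <- function(cli_args = list(), config_file = NULL,
                           defaults = default_stage_config()) {
  stopifnot(all(c("framework", "application", "model") %in% names(defaults)))
  file_args <- if (is.null(config_file)) {
    list()
  } else if (is.character(config_file)) {
    yaml::read_yaml(config_file) %||% list()
  } else {
    config_file
  }
  # flatten sectioned config files
  if (any(names(file_args) %in% c("framework", "application", "model"))) {
    file_args <- do.call(c, unname(lapply(file_args, function(x)
      if (is.list(x)) x else list(x))))
  }
  sections <- c("framework", "application", "model")
  valid <- unlist(lapply(defaults[sections], names))
  section_of <- rep(sections, times = vapply(defaults[sections], length, 0L))
  names(section_of) <- valid
  check_known <- function(args, origin) {
    unknown <- setdiff(names(args), valid)
    if (length(unknown)) {
      hint <- suggest_name(unknown[1], valid)
      drp_error(sprintf(
        "unknown %s parameter '%s'; did you mean '%s'? valid keys: %s",
        origin, unknown[1], hint, paste(valid, collapse = ", ")),
        "drp_config_error")
    }
  }
  check_known(file_args, "config-file")
  check_known(cli_args, "command-line")
  out <- defaults[sections]
  provenance <- stats::setNames(rep("default", length(valid)), valid)
  for (k in names(file_args)) {
    out[[section_of[[k]]]][[k]] <- file_args[[k]]
    provenance[[k]] <- "config_file"
  }
  for (k in names(cli_args)) {
    out[[section_of[[k]]]][[k]] <- cli_args[[k]]
    provenance[[k]] <- "cli"
  }
  structure(c(out, list(provenance = as.list(provenance))),
            class = "stage_config")
}

#' Default tiered configuration
#'
#' @param model_params Named list of model hyperparameters to seat in the
#'   `model` section.
#' @return Defaults list for [resolve_config()].
#' @export
default_stage_config <- function(model_params = list()) {
  list(
    framework = list(run_dir = "runs", log_level = "info", seed = 1L),
    application = list(source = NULL, target = NULL, split_index = 1L,
                       y_col = "auc"),
    model = utils::modifyList(
      list(patience = 10L, max_evals = 200L, learning_rate = 0.1),
      model_params)
  )
}

#' Serialize a resolved configuration to a run directory
#'
#' @param config A [resolve_config()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stage_config <- function(config, path) {
  stopifnot(inherits(config, "stage_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## ---- model registry ---------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Describe and register a model
#'
#' A model specification names the feature kinds the model consumes and
#' supplies `fit`/`predict` functions conforming to the stage contract:
#' `fit(x_train, y_train, x_val, y_val, params, seed)` returns a list with at
#' least `fit` (the trained object), `best_val_loss` (validation MSE of the
#' retained checkpoint) and `n_evals`; `predict(fit, x)` returns a numeric
#' vector. Predictions are deliberately not clipped to `[0, 1]`, so negative
#' R-squared values remain diagnostic.
#'
#' @param name Unique registry key.
#' @param cell_features Subset of `"omics"`.
#' @param drug_features Subset of `c("fingerprint", "descriptor")`.
#' @param supports_early_stopping Logical flag.
#' @param fit,predict Functions as described above.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, cell_features, drug_features,
                       supports_early_stopping, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            all(cell_features %in% "omics"),
            all(drug_features %in% c("fingerprint", "descriptor")),
            is.function(fit), is.function(predict))
  structure(list(name = name, cell_features = cell_features,
                 drug_features = drug_features,
                 supports_early_stopping = isTRUE(supports_early_stopping),
                 fit = fit, predict = predict),
            class = "model_spec")
}

#' @rdname model_spec
#' @param spec A `model_spec` to register (replaces any existing entry of the
#'   same name).
#' @export
register_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  assign(spec$name, spec, envir = .model_registry)
  invisible(spec$name)
}

#' @rdname model_spec
#' @export
list_models <- function() sort(ls(.model_registry))

#' @rdname model_spec
#' @export
get_model_spec <- function(name) {
  if (!exists(name, envir = .model_registry, inherits = FALSE)) {
    drp_error(sprintf("unknown model '%s'; registered models: %s", name,
                      paste(list_models(), collapse = ", ")),
              "drp_registry_error")
  }
  get(name, envir = .model_registry)
}

## ---- preprocessing ----------------------------------------------------------

feature_block <- function(bundle, kind, ids, id_kind) {
  m <- if (kind == "omics") bundle$omics else bundle$drug_features[[kind]]
  if (is.null(m)) {
    drp_error(sprintf("bundle '%s' lacks required feature kind '%s'",
                      bundle$name, kind), "drp_feature_error")
  }
  out <- m[ids, , drop = FALSE]
  colnames(out) <- paste(kind, colnames(m), sep = ".")
  out
}

make_design <- function(bundle, spec, rows) {
  resp <- bundle$response[rows, , drop = FALSE]
  blocks <- c(
    lapply(spec$cell_features, function(k)
      feature_block(bundle, k, resp$cell_id, "cell")),
    lapply(spec$drug_features, function(k)
      feature_block(bundle, k, resp$drug_id, "drug"))
  )
  x <- do.call(cbind, blocks)
  rownames(x) <- NULL
  scaled <- unlist(lapply(c(spec$cell_features, spec$drug_features),
                          function(k) {
    m <- if (k == "omics") bundle$omics else bundle$drug_features[[k]]
    rep(k != "fingerprint", ncol(m))
  }))
  list(x = x, y = resp$auc, ids = resp[, c("cell_id", "drug_id")],
       scaled_cols = which(scaled))
}

fit_scaler <- function(x, cols) {
  list(cols = cols,
       center = colMeans(x[, cols, drop = FALSE]),
       scale = pmax(apply(x[, cols, drop = FALSE], 2, stats::sd), 1e-8))
}

apply_scaler <- function(x, scaler) {
  x[, scaler$cols] <- sweep(sweep(x[, scaler$cols, drop = FALSE], 2,
                                  scaler$center), 2, scaler$scale, "/")
  x
}

#' Preprocess stage: benchmark bundle to model-ready sets
#'
#' Builds train/validation/test design matrices for a model from a bundle and
#' one split. In within-dataset mode the test set is the split's held-out
#' test rows; in cross-dataset mode (`target_bundle` given) the test set is
#' the *full* target response table. Continuous feature blocks (omics,
#' descriptors) are standardized per feature with statistics fitted on the
#' training rows only and applied unchanged to validation and test sets —
#' including the target dataset's features, whose scaled values therefore
#' depend on the training split. Binary fingerprints are left unscaled.
#'
#' @param bundle Source [assemble_bundle()].
#' @param split A `split_definition` valid for `bundle$response`.
#' @param spec A [model_spec()] (or registry name).
#' @param target_bundle Optional target bundle for cross-dataset evaluation.
#' @param supplementary_path Optional path to model-specific supplementary
#'   data; passed through unused by the bundled baselines.
#' @return List with `train`, `val`, `test` (each `x`, `y`, `ids`), the
#'   fitted `scaler`, `feature_names`, and `mode` (`"within"` or `"cross"`).
#' @export
preprocess_stage <- function(bundle, split, spec, target_bundle = NULL,
                             supplementary_path = NULL) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  stopifnot(inherits(bundle, "benchmark_bundle"),
            inherits(split, "split_definition"), inherits(spec, "model_spec"))
  n <- nrow(bundle$response)
  all_idx <- c(split$train_idx, split$val_idx, split$test_idx)
  if (any(all_idx < 1 | all_idx > n)) {
    bad <- all_idx[all_idx < 1 | all_idx > n][1]
    drp_error(sprintf("split index %d out of bounds for %d response rows",
                      bad - 1L, n), "drp_bounds_error")
  }
  train <- make_design(bundle, spec, split$train_idx)
  val <- make_design(bundle, spec, split$val_idx)
  test <- if (is.null(target_bundle)) {
    make_design(bundle, spec, split$test_idx)
  } else {
    make_design(target_bundle, spec, seq_len(nrow(target_bundle$response)))
  }
  scaler <- fit_scaler(train$x, train$scaled_cols)
  for (nm in c("train", "val", "test")) {
    set <- get(nm)
    set$x <- apply_scaler(set$x, scaler)
    assign(nm, set)
  }
  list(train = train, val = val, test = test, scaler = scaler,
       feature_names = colnames(train$x),
       mode = if (is.null(target_bundle)) "within" else "cross",
       supplementary_path = supplementary_path)
}

## ---- early stopping ---------------------------------------------------------

#' Generic early-stopping training loop
#'
#' Repeatedly advances an iterative learner and evaluates its validation
#' loss, stopping once the loss has failed to improve for `patience`
#' consecutive evaluations (or after `max_evals`). The state achieving the
#' lowest validation loss ever seen is the one returned — never a later,
#' worse one.
#'
#' @param init Initial learner state.
#' @param step Function `state -> state` advancing training by one
#'   evaluation period.
#' @param val_loss Function `state -> numeric` scoring the state on
#'   validation data.
#' @param patience Consecutive non-improving evaluations tolerated.
#' @param max_evals Hard cap on evaluations.
#' @return List with `best_state`, `best_loss`, `best_eval`, `n_evals`, and
#'   the full loss `history`.
#' @export
early_stopping_loop <- function(init, step, val_loss, patience = 10,
                                max_evals = 200) {
  state <- init
  best_state <- NULL
  best_loss <- Inf
  best_eval <- 0L
  history <- numeric(0)
  since_best <- 0L
  n <- 0L
  while (n < max_evals) {
    state <- step(state)
    n <- n + 1L
    loss <- val_loss(state)
    if (is.na(loss) || is.nan(loss)) {
      drp_error(sprintf("validation loss is NaN at evaluation %d", n),
                "drp_train_error")
    }
    history[n] <- loss
    if (loss < best_loss) {
      best_loss <- loss
      best_state <- state
      best_eval <- n
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  list(best_state = best_state, best_loss = best_loss, best_eval = best_eval,
       n_evals = n, history = history)
}

## ---- train / infer stages ---------------------------------------------------

#' Training stage
#'
#' Fits the model on the training set with validation-based early stopping
#' (for models that support it), retaining the checkpoint with the lowest
#' validation loss. Returns the model handle plus validation predictions and
#' scores. A non-finite validation loss aborts with diagnostics.
#'
#' @param sets A [preprocess_stage()] result (uses `$train` and `$val`).
#' @param spec A [model_spec()] or registry name.
#' @param config A [resolve_config()] result (uses the `model` section and
#'   the framework seed).
#' @return List with `handle` (list: `model`, `fit`, `feature_names`,
#'   `best_val_loss`, `n_evals`), `val_predictions` (data frame `cell_id`,
#'   `drug_id`, `y_true`, `y_pred`), and `val_scores`.
#' @export
train_stage <- function(sets, spec, config = resolve_config()) {
  if (is.character(spec)) spec <- get_model_spec(spec)
  if (nrow(sets$train$x) == 0L || nrow(sets$val$x) == 0L) {
    drp_error("empty training or validation set", "drp_train_error")
  }
  seed <- config$framework$seed %||% 1L
  fitted <- with_rng_seed(seed, {
    spec$fit(sets$train$x, sets$train$y, sets$val$x, sets$val$y,
             config$model, seed)
  })
  if (!is.finite(fitted$best_val_loss)) {
    drp_error(sprintf("model '%s': non-finite validation loss (%s)",
                      spec$name, fitted$best_val_loss), "drp_train_error")
  }
  y_pred <- as.numeric(spec$predict(fitted$fit, sets$val$x))
  val_predictions <- data.frame(sets$val$ids, y_true = sets$val$y,
                                y_pred = y_pred)
  val_scores <- list(r_squared = r_squared(sets$val$y, y_pred),
                     n_samples = length(y_pred), stage = "val")
  list(handle = list(model = spec$name, fit = fitted$fit,
                     feature_names = sets$feature_names,
                     best_val_loss = fitted$best_val_loss,
                     n_evals = fitted$n_evals %||% NA_integer_),
       val_predictions = val_predictions, val_scores = val_scores)
}

#' Inference stage
#'
#' Applies a trained model handle to a test set, producing one prediction
#' record per row and — when ground truth is present — performance scores.
#'
#' @param handle Handle from [train_stage()].
#' @param test_set A list with `x`, `ids`, and optionally `y` (as produced by
#'   [preprocess_stage()]`$test`).
#' @return List with `predictions` (data frame) and `scores` (or `NULL` when
#'   no ground truth is available).
#' @export
infer_stage <- function(handle, test_set) {
  if (is.null(test_set$x) || nrow(test_set$x) == 0L) {
    drp_error("empty test set", "drp_infer_error")
  }
  missing <- setdiff(handle$feature_names, colnames(test_set$x))
  if (length(missing)) {
    drp_error(paste0("test features missing: ",
                     paste(utils::head(missing, 5), collapse = ", ")),
              "drp_feature_error")
  }
  spec <- get_model_spec(handle$model)
  x <- test_set$x[, handle$feature_names, drop = FALSE]
  y_pred <- as.numeric(spec$predict(handle$fit, x))
  predictions <- data.frame(test_set$ids, y_pred = y_pred)
  scores <- NULL
  if (!is.null(test_set$y)) {
    predictions <- data.frame(test_set$ids, y_true = test_set$y,
                              y_pred = y_pred)
    scores <- list(r_squared = r_squared(test_set$y, y_pred),
                   n_samples = length(y_pred), stage = "test")
  }
  list(predictions = predictions, scores = scores)
}
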