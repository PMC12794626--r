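# Cross-dataset experiment orchestration: plan the d x d experiment, execute
# preprocess -> train -> infer pipelines (one trained instance per source and
# split, reused across all targets), and collect scores from the run directory.

#' Plan a cross-dataset experiment
#'
#' For each model and each source dataset, one training task per split; each
#' trained instance is evaluated on every target dataset (within-dataset on
#' its held-out test split, cross-dataset on the full target table). With d
#' datasets and N splits this yields `d * N` trainings and `d * N * d`
#' evaluations per model — no retraining per target.
#'
#' @param datasets Character vector of distinct dataset names.
#' @param models Character vector of registry model names.
#' @param n_splits Number of splits N per source dataset.
#' @return An object of class `experiment_plan` with data frames `trainings`
#'   (`model`, `source`, `split`) and `evaluations` (`model`, `source`,
#'   `split`, `target`), plus `datasets`, `models`, `n_splits`.
#' @export
plan_experiment <- function(datasets, models, n_splits = 10) {
  if (length(datasets) < 1L || length(models) < 1L) {
    drp_error("need at least one dataset and one model", "drp_config_error")
  }
  if (anyDuplicated(datasets)) {
    drp_error("duplicate dataset names", "drp_config_error")
  }
  for (m in models) get_model_spec(m)  # fail fast on unknown models
  trainings <- expand.grid(split = seq_len(n_splits), source = datasets,
                           model = models, stringsAsFactors = FALSE)
  trainings <- trainings[, c("model", "source", "split")]
  evaluations <- merge(trainings, data.frame(target = datasets),
                       by = NULL)
  evaluations <- evaluations[order(evaluations$model, evaluations$source,
                                   evaluations$split, evaluations$target), ]
  rownames(trainings) <- rownames(evaluations) <- NULL
  structure(list(trainings = trainings, evaluations = evaluations,
                 datasets = datasets, models = models,
                 n_splits = as.integer(n_splits)),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %d datasets x %d splits x %d models: %d trainings, %d evaluations\n",
              length(x$datasets), x$n_splits, length(x$models),
              nrow(x$trainings), nrow(x$evaluations)))
  invisible(x)
}

#' Run-directory naming convention
#'
#' Bijective mapping between pipeline identifiers and file paths:
#' `{out_dir}/{model}/{source}/split_{n}/` holds the resolved config, the
#' model checkpoint, `val_predictions.csv`, `val_scores.json`, and per-target
#' `test_{target}_predictions.csv` / `test_{target}_scores.json`. Model and
#' dataset names must not contain `/`.
#'
#' @param out_dir Run-directory root.
#' @param model,source,split,target Identifiers.
#' @return `run_dir_path` and `score_path` return paths;
#'   `parse_score_path` inverts `score_path`, returning a list with `model`,
#'   `source`, `split`, `target`, `stage`.
#' @export
run_dir_path <- function(out_dir, model, source, split) {
  file.path(out_dir, model, source, sprintf("split_%d", split))
}

#' @rdname run_dir_path
#' @export
score_path <- function(out_dir, model, source, split, target) {
  file.path(run_dir_path(out_dir, model, source, split),
            sprintf("test_%s_scores.json", target))
}

#' @rdname run_dir_path
#' @param path A path produced by `score_path`.
#' @export
parse_score_path <- function(path, out_dir = NULL) {
  rel <- if (is.null(out_dir)) path else {
    sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", out_dir), "/?"),
        "", path)
  }
  parts <- strsplit(rel, "/")[[1]]
  n <- length(parts)
  if (n < 4L) drp_error(paste0("unparsable score path: ", path), "drp_parse_error")
  target <- sub("^test_(.+)_scores\\.json$", "\\1", parts[n])
  split <- as.integer(sub("^split_", "", parts[n - 1L]))
  if (identical(target, parts[n]) || is.na(split)) {
    drp_error(paste0("unparsable score path: ", path), "drp_parse_error")
  }
  source <- parts[n - 2L]
  model <- parts[n - 3L]
  list(model = model, source = source, split = split, target = target,
       stage = if (source == target) "within" else "cross")
}

write_scores_json <- function(scores, path, ids) {
  jsonlite::write_json(c(scores, ids), path, auto_unbox = TRUE, digits = NA)
}

run_pipeline_task <- function(model, source, split_n, bundles, out_dir,
                              master_seed, force = FALSE) {
  bundle <- bundles[[source]]
  spec <- get_model_spec(model)
  split <- bundle$splits[[split_n]]
  rd <- run_dir_path(out_dir, model, source, split_n)
  targets <- names(bundles)
  done <- all(file.exists(vapply(
    targets, function(t) score_path(out_dir, model, source, split_n, t), "")))
  if (done && !force) return(invisible("skipped"))
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  task_seed <- derive_seed(master_seed,
                           paste(model, source, split_n, sep = "/"))
  config <- resolve_config(
    cli_args = list(seed = task_seed, run_dir = rd, source = source,
                    split_index = split_n),
    defaults = default_stage_config())
  write_stage_config(config, file.path(rd, "config.json"))

  ok <- tryCatch({
    sets <- preprocess_stage(bundle, split, spec)
    trained <- train_stage(sets, spec, config)
    saveRDS(trained$handle, file.path(rd, "model.rds"))
    utils::write.csv(trained$val_predictions,
                     file.path(rd, "val_predictions.csv"), row.names = FALSE)
    write_scores_json(trained$val_scores, file.path(rd, "val_scores.json"),
                      list(model = model, source = source, split = split_n))
    for (target in targets) {
      test_set <- if (target == source) sets$test else {
        preprocess_stage(bundle, split, spec,
                         target_bundle = bundles[[target]])$test
      }
      inf <- infer_stage(trained$handle, test_set)
      utils::write.csv(inf$predictions,
                       file.path(rd, sprintf("test_%s_predictions.csv", target)),
                       row.names = FALSE)
      write_scores_json(inf$scores,
                        score_path(out_dir, model, source, split_n, target),
                        list(model = model, source = source, split = split_n,
                             target = target))
    }
    TRUE
  }, error = function(e) {
    jsonlite::write_json(list(error = conditionMessage(e)),
                         file.path(rd, "failure.json"), auto_unbox = TRUE)
    FALSE
  })
  invisible(if (ok) "done" else "failed")
}

#' Execute an experiment plan
#'
#' Runs every (model, source, split) pipeline of the plan: preprocess, train
#' (checkpoint saved under the run directory), then inference on the source's
#' held-out test split and on every other dataset's full response table.
#' Tasks are idempotent — a pipeline whose score files already exist is
#' skipped unless `force = TRUE` — so interrupted runs are resumable. The
#' serial and pool executors produce identical results because every pipeline
#' derives its own seed from the master seed and its identifiers.
#'
#' @param plan An [plan_experiment()] result.
#' @param bundles Named list of [assemble_bundle()] objects covering
#'   `plan$datasets`; each bundle must carry at least `plan$n_splits` splits.
#' @param out_dir Run-directory root.
#' @param seed Master seed.
#' @param executor `"serial"` (default) or `"pool"`
#'   (multi-process via [parallel::mclapply()]).
#' @param force Re-run tasks whose outputs already exist.
#' @return A score store (see [collect_scores()]), checked for completeness
#'   against the plan.
#' @export
execute_plan <- function(plan, bundles, out_dir, seed = 1,
                         executor = c("serial", "pool"), force = FALSE) {
  executor <- match.arg(executor)
  stopifnot(inherits(plan, "experiment_plan"))
  missing_b <- setdiff(plan$datasets, names(bundles))
  if (length(missing_b)) {
    drp_error(paste0("no bundle for dataset(s): ",
                     paste(missing_b, collapse = ", ")), "drp_config_error")
  }
  for (ds in plan$datasets) {
    if (length(bundles[[ds]]$splits %||% list()) < plan$n_splits) {
      drp_error(sprintf("bundle '%s' has fewer than %d splits", ds,
                        plan$n_splits), "drp_config_error")
    }
  }
  bundles <- bundles[plan$datasets]
  tasks <- plan$trainings
  runner <- function(i) {
    run_pipeline_task(tasks$model[i], tasks$source[i], tasks$split[i],
                      bundles, out_dir, seed, force)
  }
  if (executor == "serial") {
    lapply(seq_len(nrow(tasks)), runner)
  } else {
    parallel::mclapply(seq_len(nrow(tasks)), runner,
                       mc.cores = max(1L, getOption("mc.cores", 2L)))
  }
  collect_scores(out_dir, plan = plan)
}

#' Collect scores from a run directory
#'
#' Parses the naming convention back into score records. Malformed score
#' files are reported with a warning and skipped; when a plan is supplied,
#' missing evaluation cells are reported too.
#'
#' @param out_dir Run-directory root.
#' @param plan Optional [plan_experiment()] to check completeness against.
#' @return A `score_store` data frame with columns `model`, `source`,
#'   `target`, `split`, `r_squared`, `stage`; attribute `n_missing` counts
#'   plan cells without a score file.
#' @export
collect_scores <- function(out_dir, plan = NULL) {
  files <- list.files(out_dir, pattern = "^test_.+_scores\\.json$",
                      recursive = TRUE, full.names = TRUE)
  records <- list()
  bad <- character(0)
  for (f in files) {
    rec <- tryCatch({
      meta <- parse_score_path(f, out_dir)
      js <- jsonlite::read_json(f)
      stopifnot(is.numeric(js$r_squared))
      data.frame(model = meta$model, source = meta$source,
                 target = meta$target, split = meta$split,
                 r_squared = js$r_squared, stage = meta$stage,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(rec)) bad <- c(bad, f) else records[[length(records) + 1L]] <- rec
  }
  if (length(bad)) {
    warning(sprintf("skipped %d malformed score file(s): %s", length(bad),
                    paste(utils::head(bad, 3), collapse = ", ")))
  }
  if (length(files) == 0L) warning("no score files found under ", out_dir)
  store <- if (length(records)) do.call(rbind, records) else {
    data.frame(model = character(0), source = character(0),
               target = character(0), split = integer(0),
               r_squared = numeric(0), stage = character(0))
  }
  n_missing <- 0L
  if (!is.null(plan)) {
    want <- paste(plan$evaluations$model, plan$evaluations$source,
                  plan$evaluations$split, plan$evaluations$target)
    have <- paste(store$model, store$source, store$split, store$target)
    n_missing <- sum(!(want %in% have))
    if (n_missing > 0L) {
      warning(sprintf("%d of %d planned evaluations missing from %s",
                      n_missing, length(want), out_dir))
    }
  }
  structure(store, class = c("score_store", "data.frame"),
            n_missing = n_missing)
}

#' Write / read a score store as CSV
#'
#' @param store A `score_store`.
#' @param path CSV path.
#' @return The path (write) or the score store (read).
#' @export
write_score_store <- function(store, path) {
  utils::write.csv(as.data.frame(store), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_score_store
#' @export
read_score_store <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("score_store", "data.frame"))
}
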