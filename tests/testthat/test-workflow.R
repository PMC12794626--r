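test_that("experiment plans count trainings and evaluations correctly", {
  p <- plan_experiment(paste0("ds", 1:5), "ridge", n_splits = 10)
  expect_equal(nrow(p$trainings), 50L)
  expect_equal(nrow(p$evaluations), 250L)
  p2 <- plan_experiment(c("a", "b"), "ridge", n_splits = 3)
  expect_equal(nrow(p2$trainings), 6L)
  expect_equal(nrow(p2$evaluations), 12L)
  p1 <- plan_experiment("solo", "ridge", n_splits = 2)
  expect_true(all(p1$evaluations$source == p1$evaluations$target))
  expect_error(plan_experiment(c("a", "a"), "ridge"),
               class = "drp_config_error")
  expect_error(plan_experiment("a", "not_a_model"),
               class = "drp_registry_error")
})

test_that("executing a plan produces a complete, correctly shaped store", {
  w <- tiny_world(seed = 23)
  bundles <- emit_all_studies(w, n_splits = 3)
  plan <- plan_experiment(names(bundles), "ridge", n_splits = 3)
  out <- withr::local_tempdir()
  store <- execute_plan(plan, bundles, out, seed = 23)
  expect_s3_class(store, "score_store")
  expect_equal(nrow(store), 2 * 2 * 3)      # d^2 x N with 1 model
  expect_equal(attr(store, "n_missing"), 0L)
  expect_setequal(unique(store$stage[store$source == store$target]), "within")
  expect_setequal(unique(store$stage[store$source != store$target]), "cross")
  # within-dataset evaluations score the held-out test split; cross-dataset
  # evaluations score the full target table
  n_test <- length(bundles$s1$splits[[1]]$test_idx)
  within_pred <- utils::read.csv(
    file.path(out, "ridge", "s1", "split_1", "test_s1_predictions.csv"))
  cross_pred <- utils::read.csv(
    file.path(out, "ridge", "s1", "split_1", "test_s2_predictions.csv"))
  expect_equal(nrow(within_pred), n_test)
  expect_equal(nrow(cross_pred), nrow(bundles$s2$response))
  # one checkpoint per (source, split): the instance is reused across targets
  ckpts <- list.files(out, pattern = "^model[.]rds$", recursive = TRUE)
  expect_length(ckpts, 6L)
})

test_that("runs are resumable and skipping leaves results unchanged", {
  w <- tiny_world(seed = 24, n_cells = 40, n_drugs = 12)
  bundles <- emit_all_studies(w, n_splits = 3)
  plan <- plan_experiment(names(bundles), "ridge", n_splits = 3)
  out <- withr::local_tempdir()
  store1 <- execute_plan(plan, bundles, out, seed = 24)
  snapshot <- file.mtime(file.path(out, "ridge", "s1", "split_1", "model.rds"))
  store2 <- execute_plan(plan, bundles, out, seed = 24)   # all tasks skipped
  expect_identical(
    file.mtime(file.path(out, "ridge", "s1", "split_1", "model.rds")),
    snapshot)
  o1 <- store1[order(store1$source, store1$target, store1$split), ]
  o2 <- store2[order(store2$source, store2$target, store2$split), ]
  expect_equal(o1$r_squared, o2$r_squared)
  # deleting one score file is reported, then repaired on re-execution
  victim <- file.path(out, "ridge", "s1", "split_2", "test_s2_scores.json")
  unlink(victim)
  expect_warning(collect_scores(out, plan = plan), regexp = "missing")
  unlink(file.path(out, "ridge", "s1", "split_2", "test_s1_scores.json"))
  store3 <- execute_plan(plan, bundles, out, seed = 24)
  expect_equal(attr(store3, "n_missing"), 0L)
})

test_that("serial and pool executors give identical scores", {
  w <- tiny_world(seed = 25, n_cells = 40, n_drugs = 12)
  bundles <- emit_all_studies(w, n_splits = 3)
  plan <- plan_experiment(names(bundles), "ridge", n_splits = 3)
  out_s <- withr::local_tempdir()
  out_p <- withr::local_tempdir()
  s1 <- execute_plan(plan, bundles, out_s, seed = 25, executor = "serial")
  s2 <- execute_plan(plan, bundles, out_p, seed = 25, executor = "pool")
  o1 <- s1[order(s1$source, s1$target, s1$split), ]
  o2 <- s2[order(s2$source, s2$target, s2$split), ]
  expect_equal(o1$r_squared, o2$r_squared, tolerance = 1e-12)
})

test_that("score collection reports malformed files and empty directories", {
  out <- withr::local_tempdir()
  expect_warning(store <- collect_scores(out), regexp = "no score files")
  expect_equal(nrow(store), 0L)
  dir.create(file.path(out, "m", "src", "split_1"), recursive = TRUE)
  writeLines("not json", file.path(out, "m", "src", "split_1",
                                   "test_tgt_scores.json"))
  expect_warning(store2 <- collect_scores(out), regexp = "malformed")
  expect_equal(nrow(store2), 0L)
})

test_that("score stores round-trip through CSV", {
  store <- random_store(d = 2, n_splits = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_store(store, path)
  back <- read_score_store(path)
  expect_equal(as.data.frame(back), as.data.frame(store), tolerance = 1e-12)
})
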