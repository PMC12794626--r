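test_that("response tables round-trip through CSV", {
  tab <- response_table(data.frame(
    cell_id = paste0("c", 1:10), drug_id = paste0("d", 1:10),
    auc = seq(0.05, 0.95, length.out = 10)), dataset_name = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_table(tab, path)
  back <- read_response_table(path, dataset_name = "demo")
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "dataset_name"), "demo")
})

test_that("response table validation names the offending column and row", {
  expect_error(response_table(data.frame(cell_id = "c", drug_id = "d")),
               regexp = "auc", class = "drp_schema_error")
  bad <- data.frame(cell_id = paste0("c", 1:3), drug_id = paste0("d", 1:3),
                    auc = c(0.2, 0.4, 1.2))
  expect_error(response_table(bad), regexp = "row 3",
               class = "drp_validation_error")
  dup <- data.frame(cell_id = c("c", "c"), drug_id = c("d", "d"),
                    auc = c(0.1, 0.2))
  expect_error(response_table(dup), class = "drp_validation_error")
})

test_that("split generation yields the documented proportions", {
  splits <- generate_splits(1000, 10, seed = 42)
  expect_length(splits, 10L)
  for (s in splits) {
    expect_length(s$train_idx, 800L)
    expect_length(s$val_idx, 100L)
    expect_length(s$test_idx, 100L)
  }
  tiny <- generate_splits(10, 10, seed = 1)
  expect_equal(lengths(tiny[[1]][c("train_idx", "val_idx", "test_idx")]),
               c(train_idx = 8L, val_idx = 1L, test_idx = 1L))
  expect_error(generate_splits(5, 10, seed = 1), class = "drp_config_error")
})

test_that("every split is a partition for a range of sample sizes", {
  for (n in 10:50) {
    for (s in generate_splits(n, 10, seed = n)) {
      all_idx <- c(s$train_idx, s$val_idx, s$test_idx)
      expect_equal(sort(all_idx), seq_len(n))
      expect_length(intersect(s$train_idx, s$val_idx), 0L)
      expect_length(intersect(s$train_idx, s$test_idx), 0L)
      expect_length(intersect(s$val_idx, s$test_idx), 0L)
    }
  }
})

test_that("seeded splits are byte-identical on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_splits(generate_splits(97, 10, seed = 7), d1)
  write_splits(generate_splits(97, 10, seed = 7), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed changes them
  d3 <- withr::local_tempdir()
  write_splits(generate_splits(97, 10, seed = 8), d3)
  expect_false(identical(readLines(file.path(d1, "split_1_train.txt")),
                         readLines(file.path(d3, "split_1_train.txt"))))
})

test_that("split files store 0-based indices and report parse errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_split_file(c(1L, 6L, 8L), path)
  lines <- readLines(path)
  expect_equal(lines[!grepl("^#", lines)], c("0", "5", "7"))
  expect_equal(read_split_file(path), c(1L, 6L, 8L))
  writeLines("x", path)
  expect_error(read_split_file(path), regexp = "line 1",
               class = "drp_parse_error")
})

test_that("splits read back equal the splits written", {
  d <- withr::local_tempdir()
  splits <- generate_splits(50, 5, seed = 3)
  write_splits(splits, d)
  back <- read_splits(d, n_folds = 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$train_idx, splits[[i]]$train_idx)
    expect_equal(back[[i]]$val_idx, splits[[i]]$val_idx)
    expect_equal(back[[i]]$test_idx, splits[[i]]$test_idx)
  }
})

test_that("bundle assembly join-filters unmatched samples", {
  resp <- response_table(data.frame(
    cell_id = c(paste0("c", 1:99), "ghost"),
    drug_id = rep(paste0("d", 1:10), 10), auc = runif(100)))
  omics <- matrix(rnorm(99 * 4), 99, 4,
                  dimnames = list(paste0("c", 1:99), paste0("g", 1:4)))
  desc <- matrix(rnorm(10 * 3), 10, 3,
                 dimnames = list(paste0("d", 1:10), paste0("x", 1:3)))
  b <- suppressMessages(assemble_bundle(resp, omics, list(descriptor = desc)))
  expect_equal(nrow(b$response), 99L)
  expect_equal(b$n_dropped, 1L)
  # fully matched input keeps everything
  resp2 <- response_table(as.data.frame(resp)[1:99, ])
  b2 <- assemble_bundle(resp2, omics, list(descriptor = desc))
  expect_equal(nrow(b2$response), 99L)
  expect_equal(b2$n_dropped, 0L)
  # zero shared cells is fatal
  omics_alien <- matrix(0, 2, 2, dimnames = list(c("z1", "z2"), c("g1", "g2")))
  expect_error(assemble_bundle(resp2, omics_alien, list(descriptor = desc)),
               class = "drp_join_error")
})

test_that("omics reader enforces schema and accepts CSV and TSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  write_feature_matrix(m, path, id_col = "cell_id")
  expect_equal(read_omics_table(path), m)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tg1", "c1\t0.5"), tsv)
  expect_equal(read_omics_table(tsv)["c1", "g1"], 0.5)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,g1", "c1,0.5"), bad)
  expect_error(read_omics_table(bad), class = "drp_schema_error")
})
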