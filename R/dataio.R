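# Benchmark-bundle data model and file I/O: response tables, omics matrices,
# drug tables, reproducible splits, and bundle assembly.

#' Construct and validate a drug response table
#'
#' One row per (cell, drug) pair with its normalized AUC in `[0, 1]`; row
#' order is meaningful because split files index into it.
#'
#' @param df Data frame with columns `cell_id`, `drug_id`, `auc`.
#' @param dataset_name Study label.
#' @return The validated data frame with class `response_table` and a
#'   `dataset_name` attribute.
#' @export
response_table <- function(df, dataset_name = "unnamed") {
  miss <- setdiff(c("cell_id", "drug_id", "auc"), names(df))
  if (length(miss)) {
    drp_error(paste0("response table missing column(s): ",
                     paste(miss, collapse = ", ")), "drp_schema_error")
  }
  bad <- which(!is.finite(df$auc) | df$auc < 0 | df$auc > 1)
  if (length(bad)) {
    drp_error(sprintf("auc outside [0, 1] at row %s",
                      paste(utils::head(bad, 5), collapse = ", ")),
              "drp_validation_error")
  }
  key <- paste(df$cell_id, df$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    drp_error("duplicate (cell_id, drug_id) pairs in response table",
              "drp_validation_error")
  }
  df <- df[, c("cell_id", "drug_id", "auc")]
  df$cell_id <- as.character(df$cell_id)
  df$drug_id <- as.character(df$drug_id)
  rownames(df) <- NULL
  structure(df, class = c("response_table", "data.frame"),
            dataset_name = dataset_name)
}

#' Read / write a response table CSV
#'
#' CSV with columns `cell_id`, `drug_id`, `auc`. Write-then-read preserves
#' rows and order.
#'
#' @param path File path.
#' @param dataset_name Study label attached on read (defaults to the file
#'   name without extension).
#' @return `read_response_table` returns a [response_table()];
#'   `write_response_table` returns `path` invisibly.
#' @export
read_response_table <- function(path, dataset_name = NULL) {
  if (!file.exists(path)) drp_error(paste0("no such file: ", path), "drp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  response_table(df, dataset_name %||%
                   sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_response_table
#' @param table A [response_table()].
#' @export
write_response_table <- function(table, path) {
  stopifnot(inherits(table, "response_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an omics feature table
#'
#' Wide numeric matrix, first column `cell_id`, remaining columns gene/probe
#' features. Both CSV and TSV are accepted (delimiter sniffed from the
#' header line).
#'
#' @param path File path.
#' @return Numeric matrix with `cell_id` rownames.
#' @export
read_omics_table <- function(path) {
  if (!file.exists(path)) drp_error(paste0("no such file: ", path), "drp_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "cell_id") {
    drp_error("omics table must have 'cell_id' as its first column",
              "drp_schema_error")
  }
  if (anyDuplicated(df$cell_id)) {
    drp_error("duplicate cell_id in omics table", "drp_validation_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$cell_id)
  m
}

#' Write an entity-by-feature matrix as CSV
#'
#' @param m Numeric matrix with entity rownames.
#' @param path Output path.
#' @param id_col Name of the identifier column (first column of the CSV).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, id_col = "cell_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug table (identifiers and SMILES)
#'
#' @param path CSV with columns `drug_id`, `smiles` (raw SMILES; a
#'   `smiles_canonical` column is honored if present).
#' @return Data frame with columns `drug_id`, `smiles` and, when present,
#'   `smiles_canonical`.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) drp_error(paste0("no such file: ", path), "drp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("drug_id", "smiles"), names(df))
  if (length(miss)) {
    drp_error(paste0("drug table missing column(s): ",
                     paste(miss, collapse = ", ")), "drp_schema_error")
  }
  if (anyDuplicated(df$drug_id)) {
    drp_error("duplicate drug_id in drug table", "drp_validation_error")
  }
  df$drug_id <- as.character(df$drug_id)
  df
}

#' Generate reproducible train/validation/test splits
#'
#' Random k-fold partition of `n_samples` row indices. For split `n`, the
#' test set is fold `n`, the validation set is the next fold cyclically, and
#' the training set is the remaining folds, giving size proportions of
#' approximately (0.8, 0.1, 0.1) with the default 10 folds. The same seed
#' always yields identical splits.
#'
#' @param n_samples Number of response rows to partition.
#' @param n_folds Number of folds (and of splits), default 10.
#' @param seed Integer seed.
#' @return List of `n_folds` `split_definition` objects, each with 1-based
#'   `train_idx`, `val_idx`, `test_idx` and `split_index`.
#' @export
generate_splits <- function(n_samples, n_folds = 10, seed = 1) {
  if (!is_count(n_samples) || !is_count(n_folds)) {
    drp_error("'n_samples' and 'n_folds' must be positive integers",
              "drp_config_error")
  }
  if (n_folds < 3) {
    drp_error("need at least 3 folds: test and validation each take one fold, and at least one fold must remain for training",
              "drp_config_error")
  }
  if (n_samples < n_folds) {
    drp_error(sprintf("n_samples (%d) < n_folds (%d)", n_samples, n_folds),
              "drp_config_error")
  }
  fold <- with_rng_seed(seed, {
    sample(rep(seq_len(n_folds), length.out = n_samples))
  })
  lapply(seq_len(n_folds), function(n) {
    val_fold <- (n %% n_folds) + 1L
    structure(list(
      split_index = n,
      train_idx = which(!fold %in% c(n, val_fold)),
      val_idx = which(fold == val_fold),
      test_idx = which(fold == n)
    ), class = "split_definition")
  })
}

#' Read / write split index files
#'
#' Splits are stored as plain text, one row index per line, 0-based on disk
#' (a leading `#` comment line documents the base). In memory the package
#' uses R's native 1-based indices; conversion happens here at the I/O
#' boundary.
#'
#' @param path File path.
#' @return `read_split_file` returns an integer vector of 1-based indices in
#'   file order; `write_split_file` returns `path` invisibly.
#' @export
read_split_file <- function(path) {
  if (!file.exists(path)) drp_error(paste0("no such file: ", path), "drp_io_error")
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(!is.finite(vals) | vals < 0 | vals != floor(vals))
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    drp_error(sprintf("split file %s: line %d is not a non-negative integer",
                      path, lineno), "drp_parse_error")
  }
  as.integer(vals) + 1L
}

#' @rdname read_split_file
#' @param idx Integer vector of 1-based row indices.
#' @export
write_split_file <- function(idx, path) {
  stopifnot(all(idx >= 1), all(idx == floor(idx)))
  writeLines(c("# 0-based row indices into the response table",
               format(as.integer(idx) - 1L, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Write a set of splits as `split_{n}_{train|val|test}.txt` files
#'
#' @param splits List from [generate_splits()].
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_splits <- function(splits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(splits, function(s) {
    vapply(c("train", "val", "test"), function(part) {
      p <- file.path(dir, sprintf("split_%d_%s.txt", s$split_index, part))
      write_split_file(s[[paste0(part, "_idx")]], p)
      p
    }, "")
  }))
  invisible(paths)
}

#' Read splits written by [write_splits()]
#'
#' @param dir Directory holding `split_{n}_{train|val|test}.txt` files.
#' @param n_folds Number of splits to read.
#' @return List of `split_definition` objects.
#' @export
read_splits <- function(dir, n_folds = 10) {
  lapply(seq_len(n_folds), function(n) {
    structure(list(
      split_index = n,
      train_idx = read_split_file(file.path(dir, sprintf("split_%d_train.txt", n))),
      val_idx = read_split_file(file.path(dir, sprintf("split_%d_val.txt", n))),
      test_idx = read_split_file(file.path(dir, sprintf("split_%d_test.txt", n)))
    ), class = "split_definition")
  })
}

#' Assemble a benchmark bundle from its components
#'
#' Joins the response table with omics and drug feature matrices through the
#' shared cell and drug identifiers. Response samples whose cell is absent
#' from the omics matrix or whose drug is absent from every drug feature
#' matrix are dropped with a logged count; an empty intersection is fatal.
#'
#' @param response A [response_table()].
#' @param omics Numeric matrix, rownames = cell ids.
#' @param drug_features Named list of numeric matrices (rownames = drug ids),
#'   e.g. `list(descriptor = ..., fingerprint = ...)`.
#' @param splits Optional list from [generate_splits()]; note that splits
#'   index the *filtered* response table, so generate them after assembly (or
#'   pass splits generated for an already fully-matched response table).
#' @param name Dataset label; defaults to the response table's.
#' @return An object of class `benchmark_bundle` with fields `name`,
#'   `response`, `omics`, `drug_features`, `splits`, `n_dropped`.
#' @export
assemble_bundle <- function(response, omics, drug_features, splits = NULL,
                            name = NULL) {
  stopifnot(inherits(response, "response_table"), is.matrix(omics),
            is.list(drug_features), length(drug_features) >= 1L)
  drug_ids <- Reduce(intersect, lapply(drug_features, rownames))
  ok <- response$cell_id %in% rownames(omics) & response$drug_id %in% drug_ids
  if (!any(ok)) {
    drp_error("no response sample has both omics and drug features",
              "drp_join_error")
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("dropped %d of %d response samples without features",
                    n_dropped, length(ok)))
  }
  resp <- response_table(as.data.frame(response)[ok, , drop = FALSE],
                         dataset_name = name %||% attr(response, "dataset_name"))
  structure(list(
    name = attr(resp, "dataset_name"),
    response = resp,
    omics = omics,
    drug_features = drug_features,
    splits = splits,
    n_dropped = n_dropped
  ), class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf("<benchmark_bundle> %s: %d samples, %d cells, %d drugs, features: %s\n",
              x$name, nrow(x$response), length(unique(x$response$cell_id)),
              length(unique(x$response$drug_id)),
              paste(names(x$drug_features), collapse = "+")))
  invisible(x)
}
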