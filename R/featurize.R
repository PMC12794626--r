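# Drug featurization through the OpenBabel cheminformatics backend
# (ChemmineOB): SMILES canonicalization, circular (Morgan/ECFP) fingerprints,
# and 2D molecular descriptors.

ob_parse_one <- function(smiles, f) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, f)),
    error = function(e) NULL
  )
  if (is.null(res) || length(res) == 0L) NULL else res[[1]]
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the backend's canonical form, so different
#' spellings of the same molecule map to one string. Canonical forms are
#' deterministic for a given backend version.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where a string could
#'   not be parsed.
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, "", USE.NAMES = FALSE)
}

# Fold a long binary fingerprint down to n_bits by OR-ing aligned blocks.
fold_fingerprint <- function(bits, n_bits) {
  if (length(bits) %% n_bits != 0L) {
    drp_error(sprintf("fingerprint width %d is not a multiple of n_bits = %d",
                      length(bits), n_bits), "drp_config_error")
  }
  as.integer(rowSums(matrix(bits, nrow = n_bits)) > 0)
}

#' Morgan (extended-connectivity) fingerprints
#'
#' Binary circular fingerprints computed on canonical SMILES via the
#' OpenBabel ECFP implementation (radius 2 corresponds to ECFP4), folded to a
#' fixed width of `n_bits`. Drugs whose SMILES cannot be parsed are excluded
#' with a warning and listed in the `errors` attribute.
#'
#' @param drugs Data frame with columns `drug_id`, `smiles` (see
#'   [read_drug_table()]).
#' @param n_bits Fingerprint width; must divide the backend's native width
#'   (4096). Default 512.
#' @param radius Circular neighborhood radius; default 2.
#' @return Binary matrix (drugs x `n_bits`) with `drug_id` rownames,
#'   attribute `kind = "fingerprint"`, and attribute `errors` naming excluded
#'   drugs.
#' @export
morgan_fingerprints <- function(drugs, n_bits = 512, radius = 2) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  if (!is_count(n_bits) || 4096 %% n_bits != 0L) {
    drp_error("'n_bits' must be a positive divisor of 4096", "drp_config_error")
  }
  fp_name <- paste0("ECFP", 2L * radius)
  can <- canonicalize_smiles(drugs$smiles)
  rows <- vector("list", nrow(drugs))
  failed <- character(0)
  for (i in seq_len(nrow(drugs))) {
    bits <- if (is.na(can[i])) NULL else {
      ob_parse_one(can[i], function(m) ChemmineOB::fingerprint_OB(list(m), fp_name))
    }
    if (is.null(bits)) {
      failed <- c(failed, drugs$drug_id[i])
    } else {
      rows[[i]] <- fold_fingerprint(as.integer(bits), n_bits)
    }
  }
  if (length(failed)) {
    warning(sprintf("excluded %d drug(s) with unparsable SMILES: %s",
                    length(failed), paste(failed, collapse = ", ")))
  }
  keep <- !vapply(rows, is.null, TRUE)
  m <- do.call(rbind, rows[keep])
  if (is.null(m)) m <- matrix(integer(0), nrow = 0, ncol = n_bits)
  rownames(m) <- drugs$drug_id[keep]
  colnames(m) <- paste0("fp_", seq_len(n_bits))
  structure(m, kind = "fingerprint", errors = failed)
}

#' 2D molecular descriptors
#'
#' Computes the OpenBabel descriptor set on canonical SMILES. Only 2D
#' descriptors are produced (SMILES carry no conformer, so no 3D descriptors
#' enter the matrix); non-numeric identifier fields from the backend are
#' dropped. Columns with more than `max_invalid_frac` invalid values are
#' removed; remaining invalid entries are imputed with the column median.
#'
#' @param drugs Data frame with columns `drug_id`, `smiles`.
#' @param max_invalid_frac Maximum tolerated fraction of invalid values per
#'   column before the column is dropped (default 0.5).
#' @return Numeric matrix (drugs x descriptors) with `drug_id` rownames,
#'   attribute `kind = "descriptor"`, and attribute `errors` naming excluded
#'   drugs. Descriptor names are preserved from the backend.
#' @export
descriptors_2d <- function(drugs, max_invalid_frac = 0.5) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  can <- canonicalize_smiles(drugs$smiles)
  rows <- vector("list", nrow(drugs))
  failed <- character(0)
  for (i in seq_len(nrow(drugs))) {
    p <- if (is.na(can[i])) NULL else ob_parse_one(can[i], ChemmineOB::prop_OB)
    if (is.null(p)) {
      failed <- c(failed, drugs$drug_id[i])
    } else {
      rows[[i]] <- p[1, vapply(p, is.numeric, TRUE), drop = FALSE]
    }
  }
  if (length(failed)) {
    warning(sprintf("excluded %d drug(s) with unparsable SMILES: %s",
                    length(failed), paste(failed, collapse = ", ")))
  }
  keep <- !vapply(rows, is.null, TRUE)
  df <- do.call(rbind, rows[keep])
  m <- as.matrix(df)
  rownames(m) <- drugs$drug_id[keep]
  if (nrow(m) > 0) m <- impute_columns(m, max_invalid_frac)
  structure(m, kind = "descriptor", errors = failed)
}

# Invalid-value policy: drop columns whose invalid fraction exceeds the
# threshold, median-impute the remaining invalid entries.
impute_columns <- function(m, max_invalid_frac = 0.5) {
  invalid_frac <- colMeans(!is.finite(m))
  m <- m[, invalid_frac <= max_invalid_frac, drop = FALSE]
  for (j in seq_len(ncol(m))) {
    bad <- !is.finite(m[, j])
    if (any(bad)) m[bad, j] <- stats::median(m[!bad, j])
  }
  m
}
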