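# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

drp_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "drp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions do not disturb the
#' session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible task seed from a master seed
#'
#' Maps a master seed plus an arbitrary character key (for example
#' `"gbt/study1/split3"`) to a deterministic 31-bit integer, so independent
#' pipeline tasks get distinct but reproducible random streams regardless of
#' execution order.
#'
#' @param master_seed Integer master seed.
#' @param key Character scalar identifying the task.
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- as.double(master_seed) %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Nearest-name suggestion for unknown keys/arguments.
suggest_name <- function(bad, valid) {
  if (length(valid) == 0L) return(character(0))
  d <- utils::adist(bad, valid, ignore.case = TRUE)
  valid[which.min(d)]
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}
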