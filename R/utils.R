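# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## single scalar checks used by constructors
assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}

## Column presence check for file readers; reports the file for context.
assertColumns <- function(df, cols, path) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  invisible(df)
}
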