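# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mv <- function(...) stop(sprintf(...), call. = FALSE)

#' Standardize a numeric vector to mean 0, sd 1
#'
#' @param x numeric vector (NAs preserved).
#' @return numeric vector with mean 0 and sd 1 over non-missing entries.
#' @keywords internal
#' @noRd
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop_mv("cannot standardize a zero-variance vector")
  (x - mean(x, na.rm = TRUE)) / s
}

# Deterministic sub-stream seed: one global seed plus a named component, so
# adding a component does not perturb the draws of the others. Kept < 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) + 1000003 * (h %% 2027)) %%
               .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_numeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x)) stop_mv("'%s' must be numeric", name)
  if (positive && any(x <= 0, na.rm = TRUE)) stop_mv("'%s' must be > 0", name)
  invisible(x)
}
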