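# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

# Derive a per-stream child seed from a root seed, keeping it inside the
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483647L
}

# Normal draw truncated to [lower, upper] via inverse-CDF sampling.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}
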