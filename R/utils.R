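# Internal helpers: reproducible seeding and small numerics.

#' Derive a stage-specific RNG seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Per-stage (and per-replicate) seeds are derived deterministically by mixing
#' the master seed with a stage label and an optional counter, so multi-stage
#' pipelines are reproducible and independent stages draw from decorrelated
#' streams.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. `"rarefy"` or `"bootstrap"`.
#' @param index non-negative integer counter for per-replicate splits.
#' @return a positive integer seed strictly below 2^31 - 1.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  u <- utf8ToInt(as.character(label))
  h <- sum(u * seq_along(u)) %% 1000003
  s <- (abs(as.numeric(seed)) * 48271 + h * 1009 + as.numeric(index) * 9973) %%
    2147483646
  as.integer(s) + 1L
}

# Evaluate `code` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# log(mean(exp(x))) computed stably.
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
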