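# Internal helpers: seed management and small assertions.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

#' Derive a stream-specific sub-seed from a master seed
#'
#' All randomness in the simulators flows from one master seed; independent
#' streams (gene sets, cohort noise, drug tables, ...) get deterministic
#' sub-seeds so each sub-table is reproducible on its own.  Linear
#' congruential mixing keeps the result a valid 32-bit R seed.
#'
#' @param seed master integer seed.
#' @param stream small integer identifying the stream.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(stream) * 1299721) %% 2147483647)
}

stop_validation <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise sample SD of a numeric matrix (denominator n - 1).
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}
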