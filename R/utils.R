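# Internal helpers shared across modules.

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one integer master seed; each
#' consumer (proteome generation, pair sampling, data splits, weight
#' initialization, repeat r of a hold-out loop) draws its own sub-seed so that
#' adding a stage never perturbs the streams of the others. The derivation is
#' a fixed affine-modular map kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer usable with [set.seed()].
#' @keywords internal
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 1e6 * 2099 + as.double(stream) * 8191 + 1) %%
               2147483647)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
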