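# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and a stream label
#'
#' Each generated artifact (chemistry, each count table, rarefaction, ...)
#' draws from its own stream so that regenerating one artifact does not
#' shift the draws of another. The derivation is a fixed integer hash of the
#' label mixed with the master seed; it is deterministic and stays within
#' the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `code` after seeding the RNG (promise forces after set.seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Assert a numeric scalar >= 0
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_f("'%s' must be a single non-negative finite number", name)
  invisible(x)
}
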