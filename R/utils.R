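# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Child seeds
#' for a given participant, phase, or purpose are derived deterministically by
#' folding the master seed and a sequence of string/integer tags into a 31-bit
#' integer, so that any single simulation component can be replayed in
#' isolation.
#'
#' @param master Integer master seed.
#' @param ... Character or integer tags identifying the stream (e.g.
#'   participant id, phase name, `"patterns"`).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "p01", "conditioning", "patterns")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483629 # largest prime < 2^31; keeps products < 2^53 with mult = 31
  s <- as.double(abs(master)) %% m
  for (tag in list(...)) {
    codes <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|")) else as.integer(tag)
    for (k in codes) s <- (s * 31 + (as.double(k) %% m)) %% m
  }
  as.integer(s)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(paste0(...), call. = FALSE)
stop_integrity <- function(...) stop(paste0(...), call. = FALSE)
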