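#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed.  Each
#' random stage (registry, per-case volumes, stain draws, cohort split,
#' cross-validation folds) receives its own stream index, and the stream
#' seed is a deterministic hash of `(master, stream)`.  The result always
#' fits in a 32-bit signed integer so it can be passed to [set.seed()].
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, length(stream) == 1L,
            is.finite(master), is.finite(stream))
  m <- as.numeric(master) %% 1048576
  s <- as.numeric(stream) %% 1048576
  as.integer((m * 1997 + s * 7919 + 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
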