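#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All randomised operations in the
# package route through this so that a global seed never leaks between
# stages.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  seed <- as.double(seed) %% 2147483647  # keep any derived seed in int range
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

#' Derive a reproducible stream of sub-seeds from a master seed
#'
#' Deterministic seed fan-out used throughout the pipeline: the master seed
#' plus a stream label select an RNG state from which `n` sub-seeds are
#' drawn.  Two arms of the benchmark that must share partitions (the QSAR
#' and conformal arms share their first 80/20 split) use the *same* stream;
#' independent randomness (calibration splits, forest seeds) uses distinct
#' streams.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @param stream small non-negative integer labelling the stream.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(n >= 1L)
  base <- (as.double(seed) + 1000003 * as.double(stream)) %% 2147483647
  with_seed(as.integer(base), sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Treat empty strings as absent values (the CSV interface encodes absence
# as "").
blank_to_na <- function(x) {
  if (is.character(x)) x[!nzchar(trimws(x))] <- NA_character_
  x
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}
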