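#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from a single root seed. Substreams for
#' (unit, trial, stage) combinations are derived by a stable integer hash so
#' that no hidden global random state is consumed and any simulation is
#' bitwise reproducible from its root seed alone.
#'
#' @param root Integer root seed.
#' @param ... Further non-negative integer indices (e.g. pixel id, trial id,
#'   stage id) identifying the substream.
#' @return A single integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1L, 3L, 7L)
#' @export
substream_seed <- function(root, ...) {
  ks <- c(root, ...)
  if (any(!is.finite(ks))) {
    stop("substream indices must be finite numbers", call. = FALSE)
  }
  m <- 2147483647 # 2^31 - 1, keeps every intermediate exact in doubles
  h <- 104729
  for (k in ks) {
    h <- (h * 69069 + (abs(k) %% m) + 1) %% m
  }
  as.integer(h)
}

#' Evaluate code under a derived substream seed
#'
#' Runs `code` with the RNG seeded from [substream_seed()] and restores the
#' previous RNG state afterwards.
#'
#' @inheritParams substream_seed
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_substream <- function(root, ..., code) {
  withr::with_seed(substream_seed(root, ...), code)
}
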