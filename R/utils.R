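#' Derive a child random seed from a master seed
#'
#' Every random stream in the resampling engine is a pure function of the
#' master seed plus structural indices (iteration, subgroup, target), so the
#' result of a run is bitwise identical for any worker count: stream i does
#' not depend on how many streams were consumed before it. The derivation is
#' a multiplicative-congruential hash over the integer parts, with all
#' arithmetic exact in doubles (< 2^53), reduced mod 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices identifying the stream.
#' @return A single integer seed in [0, 2^31 - 2].
#' @examples
#' deriveStreamSeed(7L, 3L, 1L)
#' @export
deriveStreamSeed <- function(master, ...) {
  parts <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (p %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Deterministic k-fold assignment: contiguous blocks of a seeded permutation,
# remainder rows spread one per fold starting from the first.
cvFoldIds <- function(nObs, kfolds, seed) {
  if (kfolds > nObs) stop("more CV folds than observations", call. = FALSE)
  perm <- withSeed(seed, sample.int(nObs))
  base <- nObs %/% kfolds
  rem <- nObs %% kfolds
  sizes <- rep.int(base, kfolds) + c(rep.int(1L, rem), rep.int(0L, kfolds - rem))
  fold <- integer(nObs)
  fold[perm] <- rep.int(seq_len(kfolds), sizes)
  fold
}

# Internal condition helpers: config errors (bad parameters/usage) are kept
# distinct from format errors (bad input files) so the CLI can map them to
# exit codes.
configError <- function(msg) {
  stop(errorCondition(msg, class = c("stabnet_config_error", "error")))
}

formatError <- function(msg) {
  stop(errorCondition(msg, class = c("stabnet_format_error", "error")))
}
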