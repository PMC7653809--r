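#' Partition samples into m disjoint subgroups
#'
#' Randomly splits the observation indices 1..nObs into m disjoint groups
#' without replacement, covering every index exactly once. Group sizes differ
#' by at most one: when m does not divide nObs, the first \code{nObs mod m}
#' groups receive one extra sample, so no observation is ever dropped. The
#' assignment is a deterministic function of \code{seed}.
#'
#' @param nObs number of observations.
#' @param m number of subgroups (1 <= m <= nObs).
#' @param seed integer seed.
#' @return A list of m integer index vectors.
#' @examples
#' partitionSamples(8, 2, seed = 1L)
#' @export
partitionSamples <- function(nObs, m, seed = 0L) {
  nObs <- as.integer(nObs)
  m <- as.integer(m)
  if (m < 1L) configError("m must be >= 1")
  if (m > nObs) configError(sprintf("m (%d) exceeds n_obs (%d)", m, nObs))
  perm <- withSeed(seed, sample.int(nObs))
  base <- nObs %/% m
  rem <- nObs %% m
  sizes <- rep.int(base, m) + c(rep.int(1L, rem), rep.int(0L, m - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  # groups are returned as sorted index sets: membership is what is random,
  # and a stable row order keeps downstream CV folds independent of it
  lapply(seq_len(m), function(g) sort(perm[starts[g]:ends[g]]))
}

#' Run one stability-selection trial
#'
#' Restricts the expression matrix to one subgroup of observations, regresses
#' the target gene on the candidate regulators with a cross-validated
#' elastic-net, and returns the selected regulators with their coefficient
#' signs. An empty candidate set yields an empty selection without error.
#'
#' @param object an [ExpressionMatrix-class].
#' @param subgroup integer vector of observation indices.
#' @param targetId the target gene id.
#' @param candidates character vector of candidate regulator ids (must not
#'   contain \code{targetId}).
#' @param en an [ENConfig-class].
#' @param seed integer seed for the CV fold assignment.
#' @return A list with \code{ids} (selected regulator ids) and \code{signs}.
#' @export
runTrial <- function(object, subgroup, targetId, candidates,
                     en = enConfig(), seed = 0L) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (targetId %in% candidates)
    configError("the target must not be among its own candidates")
  v <- object@values
  if (!targetId %in% colnames(v))
    configError(sprintf("unknown target gene: %s", targetId))
  if (length(candidates) == 0L)
    return(list(ids = character(0), signs = integer(0)))
  y <- v[subgroup, targetId]
  X <- v[subgroup, candidates, drop = FALSE]
  .trialSupport(X, y, en, seed)
}

# Shared trial core: fit + support, with a constant response short-circuit
# (a constant target has a null regression; nothing can be selected).
.trialSupport <- function(X, y, en, seed) {
  if (length(unique(y)) == 1L || sd(y) < 1e-12)
    return(list(ids = character(0), signs = integer(0)))
  fit <- fitElasticNetCV(X, y, en, seed)
  sup <- selectedSupport(fit)
  list(ids = sup$ids, signs = sup$signs)
}

#' Tally selections over n x m resampling trials
#'
#' The engine core. For each of \code{nIter} iterations, the samples are
#' partitioned into \code{m} disjoint subgroups; within every subgroup a
#' cross-validated elastic-net is fitted per target gene on its candidate
#' regulators, and each selected regulator scores one hit. A pair's final
#' tally is its hit count out of \code{nIter * m} trials. Candidate
#' regulators default to all genes except the current target; genes flagged
#' constant are never candidates. The per-trial random streams are derived
#' from \code{(seed, iteration, subgroup, target)}, so results are bitwise
#' identical for any \code{workers} setting.
#'
#' @param object an [ExpressionMatrix-class] (standardize first, or use
#'   [inferNetwork()] which does so by default).
#' @param config an [InferenceConfig-class].
#' @param verbose emit a per-iteration progress line to stderr.
#' @return A [SelectionTally-class].
#' @seealso [frequencyScores()], [inferNetwork()]
#' @export
tallySelections <- function(object, config, verbose = FALSE) {
  stopifnot(is(object, "ExpressionMatrix"), is(config, "InferenceConfig"))
  v <- object@values
  genes <- colnames(v)
  nObs <- nrow(v)
  targets <- if (length(config@targets)) config@targets else genes
  regs <- if (length(config@regulators)) config@regulators else genes
  if (!all(targets %in% genes))
    configError(sprintf("unknown target gene(s): %s",
                        paste(setdiff(targets, genes), collapse = ", ")))
  if (!all(regs %in% genes))
    configError(sprintf("unknown regulator gene(s): %s",
                        paste(setdiff(regs, genes), collapse = ", ")))
  regs <- setdiff(regs, object@constantGenes)
  if (config@m > nObs)
    configError(sprintf("m (%d) exceeds n_obs (%d)", config@m, nObs))
  if (nObs %/% config@m < config@en@kfolds)
    configError(sprintf(
      "subgroup size floor(%d/%d) = %d is below the %d CV folds",
      nObs, config@m, nObs %/% config@m, config@en@kfolds))

  nr <- length(regs)
  nt <- length(targets)
  regPos <- setNames(seq_len(nr), regs)
  en <- config@en
  m <- config@m

  perIteration <- function(it) {
    hits <- matrix(0L, nr, nt)
    sgn <- matrix(0L, nr, nt)
    part <- partitionSamples(nObs, m, deriveStreamSeed(config@seed, it, 0L))
    for (g in seq_len(m)) {
      sub <- part[[g]]
      Xsub <- v[sub, regs, drop = FALSE]
      for (ti in seq_len(nt)) {
        tgt <- targets[ti]
        y <- v[sub, tgt]
        Xc <- if (tgt %in% regs) Xsub[, colnames(Xsub) != tgt, drop = FALSE]
              else Xsub
        sel <- tryCatch(
          .trialSupport(Xc, y, en, deriveStreamSeed(config@seed, it, g, ti)),
          error = function(err) {
            message(sprintf(
              "trial failed (iteration %d, subgroup %d, target %s): %s",
              it, g, tgt, conditionMessage(err)))
            list(ids = character(0), signs = integer(0))
          })
        if (length(sel$ids)) {
          ri <- regPos[sel$ids]
          hits[ri, ti] <- hits[ri, ti] + 1L
          sgn[ri, ti] <- sgn[ri, ti] + sel$signs
        }
      }
    }
    if (verbose)
      message(sprintf("iteration %d/%d done (%d trials tallied)",
                      it, config@nIter, it * m * nt))
    list(hits = hits, sgn = sgn)
  }

  res <- if (config@workers > 1L) {
    out <- parallel::mclapply(seq_len(config@nIter), perIteration,
                              mc.cores = config@workers,
                              mc.preschedule = TRUE)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) stop(out[[which(bad)[1]]], call. = FALSE)
    out
  } else {
    lapply(seq_len(config@nIter), perIteration)
  }

  hits <- matrix(0L, nr, nt, dimnames = list(regs, targets))
  sgn <- matrix(0L, nr, nt, dimnames = list(regs, targets))
  for (r in res) {
    hits <- hits + r$hits
    sgn <- sgn + r$sgn
  }
  new("SelectionTally", hits = hits, signSum = sgn,
      trials = config@nIter * m)
}

#' Convert a selection tally to frequency scores
#'
#' The frequency score of a (target, regulator) pair is its hit count divided
#' by the total number of trials (\code{nIter * m}); the maximum score is 1,
#' meaning the regulator was selected in every trial. The edge sign is the
#' sign of the summed per-trial coefficient signs, 0 on an exact tie.
#'
#' @param tally a [SelectionTally-class].
#' @return A [FrequencyTable-class].
#' @export
frequencyScores <- function(tally) {
  stopifnot(is(tally, "SelectionTally"))
  if (tally@trials < 1L) configError("trials must be >= 1")
  new("FrequencyTable", score = tally@hits / tally@trials,
      sign = matrix(as.integer(sign(tally@signSum)), nrow(tally@signSum),
                    dimnames = dimnames(tally@signSum)),
      trials = tally@trials)
}

#' Infer a directed network by stability-selected elastic-net
#'
#' The full pipeline on an expression matrix: (optionally) standardize gene
#' columns, tally selections over \code{nIter * m} resampling trials, convert
#' to frequency scores, and keep the pairs whose score reaches the cutoff.
#' With \code{fullTable = TRUE} every pair selected at least once is returned
#' regardless of the cutoff, which is the input ROC/precision-recall sweeps
#' need.
#'
#' @param object an [ExpressionMatrix-class].
#' @param config an [InferenceConfig-class]; defaults are m = 4, nIter = 500,
#'   cutoff 0.95, alpha 0.5, 5-fold CV.
#' @param fullTable return all nonzero-score pairs instead of applying the
#'   cutoff.
#' @param standardize standardize gene columns first (default TRUE). Disable
#'   only if the input is already column-standardized.
#' @param verbose per-iteration progress to stderr.
#' @return An [EdgeTable-class]. The full [FrequencyTable-class] is attached
#'   as attribute \code{"frequencyTable"} for downstream evaluation.
#' @examples
#' sim <- simulateGRN(syntheticSpec(pGenes = 12, nObs = 60, nRegulators = 4,
#'                                  kPerTarget = 1, noiseSd = 0.1, seed = 3))
#' cfg <- inferenceConfig(m = 2, nIter = 3, cutoff = 0.9, seed = 3,
#'                        regulators = positivePairs(sim$gold)$regulator)
#' inferNetwork(sim$matrix, cfg)
#' @export
inferNetwork <- function(object, config = inferenceConfig(),
                         fullTable = FALSE, standardize = TRUE,
                         verbose = FALSE) {
  stopifnot(is(object, "ExpressionMatrix"))
  if (standardize) object <- suppressWarnings(standardizeExpression(object))
  tally <- tallySelections(object, config, verbose = verbose)
  freq <- frequencyScores(tally)
  et <- thresholdEdges(freq, if (fullTable) 0 else config@cutoff,
                       strict = if (fullTable) TRUE else config@strictCutoff,
                       keepZero = FALSE)
  attr(et, "frequencyTable") <- freq
  et
}

#' Apply a frequency cutoff to a score table
#'
#' @param freq a [FrequencyTable-class].
#' @param cutoff threshold in [0, 1].
#' @param strict if TRUE use score > cutoff, else score >= cutoff (default).
#' @param keepZero include zero-score pairs when the cutoff admits them
#'   (default FALSE: only pairs selected at least once are edges).
#' @return An [EdgeTable-class].
#' @export
thresholdEdges <- function(freq, cutoff, strict = FALSE, keepZero = FALSE) {
  stopifnot(is(freq, "FrequencyTable"))
  df <- as.data.frame(freq, dropZero = !keepZero)
  keep <- if (strict) df$score > cutoff else df$score >= cutoff
  df <- df[keep, , drop = FALSE]
  EdgeTable(df$regulator, df$target, df$score, df$sign)
}
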