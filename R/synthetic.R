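#' Simulate a sparse linear regulatory network benchmark
#'
#' Generates a two-layer network: source genes (named \code{R001}, ...) are
#' independent standard-normal "regulator" profiles; each target gene
#' (\code{T001}, ...) is a sparse linear combination of \code{kPerTarget}
#' distinct sources — coefficients drawn uniformly from the absolute-effect
#' interval with random sign — plus Gaussian noise. Because the generative
#' model is exactly the regression model the inference engine fits, recovery
#' of the drawn edges is a clean correctness benchmark. The gold standard
#' labels every drawn regulator -> target pair 1 and every other
#' source -> target pair 0, giving a fully labelled DREAM5-style universe of
#' \code{nRegulators * (pGenes - nRegulators)} pairs.
#'
#' The output is fully determined by \code{spec}: the same spec yields
#' bitwise-identical results.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list with \code{matrix} (an [ExpressionMatrix-class],
#'   observations x genes, sources first) and \code{gold} (a
#'   [GoldStandard-class]).
#' @examples
#' sim <- simulateGRN(syntheticSpec(pGenes = 10, nObs = 50, nRegulators = 3,
#'                                  kPerTarget = 1, seed = 2))
#' sim$matrix
#' sim$gold
#' @export
simulateGRN <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  nReg <- spec@nRegulators
  nTgt <- spec@pGenes - nReg
  wReg <- max(3L, nchar(as.character(nReg)))
  wTgt <- max(3L, nchar(as.character(nTgt)))
  regIds <- sprintf("R%0*d", wReg, seq_len(nReg))
  tgtIds <- sprintf("T%0*d", wTgt, seq_len(nTgt))
  k <- spec@kPerTarget
  out <- withSeed(spec@seed, {
    S <- matrix(rnorm(spec@nObs * nReg), spec@nObs, nReg)
    Tm <- matrix(0, spec@nObs, nTgt)
    who <- vector("list", nTgt)
    coefs <- vector("list", nTgt)
    for (t in seq_len(nTgt)) {
      if (k > 0L) {
        idx <- sort(sample.int(nReg, k))
        beta <- runif(k, spec@betaRange[1], spec@betaRange[2]) *
          sample(c(-1, 1), k, replace = TRUE)
        Tm[, t] <- S[, idx, drop = FALSE] %*% beta
        who[[t]] <- idx
        coefs[[t]] <- beta
      } else {
        who[[t]] <- integer(0)
        coefs[[t]] <- numeric(0)
      }
      Tm[, t] <- Tm[, t] + rnorm(spec@nObs, 0, spec@noiseSd)
    }
    list(S = S, Tm = Tm, who = who, coefs = coefs)
  })
  values <- cbind(out$S, out$Tm)
  colnames(values) <- c(regIds, tgtIds)
  em <- ExpressionMatrix(values)

  posReg <- regIds[unlist(out$who)]
  posTgt <- rep(tgtIds, lengths(out$who))
  posKey <- paste(posReg, posTgt, sep = "\r")
  allReg <- rep(regIds, times = nTgt)
  allTgt <- rep(tgtIds, each = nReg)
  allKey <- paste(allReg, allTgt, sep = "\r")
  lab <- as.integer(allKey %in% posKey)
  gold <- GoldStandard(allReg, allTgt, lab)
  list(matrix = em, gold = gold,
       effects = data.frame(regulator = posReg, target = posTgt,
                            beta = unlist(out$coefs),
                            stringsAsFactors = FALSE))
}

#' Simulate, infer and evaluate in one call
#'
#' Runs the full benchmark loop used throughout the package's own
#' validation: simulate a network from \code{spec}, infer frequency scores
#' with the candidate-regulator pool restricted to the true source genes and
#' targets restricted to the target layer (the labelled universe), then
#' sweep precision/recall over the requested cutoffs.
#'
#' @param spec a [SyntheticSpec-class].
#' @param config an [InferenceConfig-class]; its \code{targets} and
#'   \code{regulators} are overridden with the generator's layers.
#' @param cutoffs cutoffs for the evaluation sweep.
#' @param universe evaluation universe, see [confusionCounts()].
#' @param verbose progress lines to stderr.
#' @return A list: \code{evaluation} (sweep data.frame), \code{freq}
#'   (the [FrequencyTable-class]), \code{edges} (the [EdgeTable-class] at
#'   \code{config@cutoff}), \code{gold}, \code{matrix}, and \code{auc}
#'   (labeled-universe ROC-AUC, \code{NA} when the gold standard has a
#'   single class).
#' @export
benchmarkRun <- function(spec, config = inferenceConfig(),
                         cutoffs = seq(0.1, 1, by = 0.1),
                         universe = "labeled", verbose = FALSE) {
  stopifnot(is(spec, "SyntheticSpec"), is(config, "InferenceConfig"))
  sim <- simulateGRN(spec)
  genes <- geneIds(sim$matrix)
  sources <- genes[seq_len(spec@nRegulators)]
  targets <- genes[-seq_len(spec@nRegulators)]
  config@regulators <- sources
  config@targets <- targets
  et <- inferNetwork(sim$matrix, config, verbose = verbose)
  freq <- attr(et, "frequencyTable")
  hasPos <- sum(sim$gold@label == 1L) > 0
  evalTab <- if (hasPos)
    precisionRecallSweep(freq, sim$gold, cutoffs, universe = universe)
  else NULL
  auc <- if (hasPos && sum(sim$gold@label == 0L) > 0)
    rocAUC(freq, sim$gold, universe = universe) else NA_real_
  list(evaluation = evalTab, freq = freq, edges = et, gold = sim$gold,
       matrix = sim$matrix, auc = auc)
}
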