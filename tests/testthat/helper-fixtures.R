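# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# A small deterministic expression matrix with a planted sparse structure:
# the first nReg genes are sources, each remaining gene depends on one or two
# of them. Returned unstandardized.
makeFixtureMatrix <- function(nObs = 60L, nGenes = 10L, nReg = 4L,
                              noiseSd = 0.5, seed = 7L) {
  set.seed(seed)
  S <- matrix(rnorm(nObs * nReg), nObs, nReg)
  nTgt <- nGenes - nReg
  Tm <- matrix(0, nObs, nTgt)
  truth <- vector("list", nTgt)
  for (t in seq_len(nTgt)) {
    k <- 1L + (t %% 2L)
    idx <- ((t + seq_len(k)) %% nReg) + 1L
    beta <- rep(c(1.5, -1.2), length.out = k)
    Tm[, t] <- S[, idx, drop = FALSE] %*% beta + rnorm(nObs, 0, noiseSd)
    truth[[t]] <- idx
  }
  v <- cbind(S, Tm)
  colnames(v) <- c(sprintf("src%d", seq_len(nReg)),
                   sprintf("tgt%d", seq_len(nTgt)))
  list(em = ExpressionMatrix(v), truth = truth,
       sources = colnames(v)[seq_len(nReg)],
       targets = colnames(v)[-seq_len(nReg)])
}

# Brute-force pairwise ROC-AUC estimator: every (positive, negative)
# comparison scores 1 if the positive outranks, 1/2 on a tie.
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Independent sequential replay of the stability engine: same seed
# derivation contract, but a plain loop over partitionSamples + runTrial,
# sharing none of tallySelections' accumulation code.
bruteForceTally <- function(em, config) {
  emStd <- suppressWarnings(standardizeExpression(em))
  genes <- geneIds(emStd)
  targets <- if (length(config@targets)) config@targets else genes
  regs <- if (length(config@regulators)) config@regulators else genes
  regs <- setdiff(regs, constantGenes(emStd))
  hits <- matrix(0L, length(regs), length(targets),
                 dimnames = list(regs, targets))
  sgn <- matrix(0L, length(regs), length(targets),
                dimnames = list(regs, targets))
  for (it in seq_len(config@nIter)) {
    part <- partitionSamples(nObservations(emStd), config@m,
                             deriveStreamSeed(config@seed, it, 0L))
    for (g in seq_along(part)) {
      for (ti in seq_along(targets)) {
        tgt <- targets[ti]
        sel <- runTrial(emStd, part[[g]], tgt, setdiff(regs, tgt),
                        config@en, deriveStreamSeed(config@seed, it, g, ti))
        for (i in seq_along(sel$ids)) {
          hits[sel$ids[i], ti] <- hits[sel$ids[i], ti] + 1L
          sgn[sel$ids[i], ti] <- sgn[sel$ids[i], ti] + sel$signs[i]
        }
      }
    }
  }
  list(hits = hits, signSum = sgn, trials = config@nIter * config@m)
}

# Write an ExpressionMatrix fixture as a TSV and return the path.
writeMatrixTSV <- function(em, path = tempfile(fileext = ".tsv")) {
  writeExpressionMatrix(em, path)
  path
}
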