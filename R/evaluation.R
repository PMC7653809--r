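#' Confusion counts of called edges against a gold standard
#'
#' Compares the called edge set with the gold-standard labels. Under the
#' default \code{universe = "labeled"}, only pairs listed in the gold
#' standard are evaluated (DREAM5 practice: unlisted pairs are unevaluated)
#' and called edges outside it are ignored. Under \code{universe = "all"},
#' every called or labelled pair is in play and unlisted calls count as
#' false positives.
#'
#' Precision is tp / (tp + fp) and is reported as \code{NA} (undefined,
#' deliberately distinct from 0) when nothing was called; recall is
#' tp / (tp + fn).
#'
#' @param edges an [EdgeTable-class] of called edges.
#' @param gold a [GoldStandard-class] with at least one positive.
#' @param universe \code{"labeled"} (default) or \code{"all"}.
#' @param cutoff optional cutoff annotation copied into the result.
#' @return A one-row data.frame with columns cutoff, tp, fp, fn, tn,
#'   precision, recall.
#' @export
confusionCounts <- function(edges, gold, universe = c("labeled", "all"),
                            cutoff = NA_real_) {
  universe <- match.arg(universe)
  stopifnot(is(edges, "EdgeTable"), is(gold, "GoldStandard"))
  posKey <- with(positivePairs(gold), paste(regulator, target, sep = "\r"))
  if (length(posKey) == 0L)
    stop("gold standard has no positive pairs to evaluate against",
         call. = FALSE)
  goldKey <- paste(gold@regulator, gold@target, sep = "\r")
  e <- edges@edges
  callKey <- paste(e$regulator, e$target, sep = "\r")
  if (universe == "labeled") {
    callKey <- callKey[callKey %in% goldKey]
    uniKey <- goldKey
  } else {
    uniKey <- union(goldKey, callKey)
  }
  tp <- sum(callKey %in% posKey)
  fp <- length(callKey) - tp
  fn <- length(posKey) - tp
  tn <- length(uniKey) - tp - fp - fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  data.frame(cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall)
}

#' Precision/recall across a sweep of frequency cutoffs
#'
#' Applies each cutoff (inclusive threshold by default) to the frequency
#' table, then computes confusion counts against the gold standard. Results
#' are returned in the order the cutoffs were given.
#'
#' @param freq a [FrequencyTable-class].
#' @param gold a [GoldStandard-class].
#' @param cutoffs numeric vector of thresholds in [0, 1]; the conventional
#'   sweep is \code{seq(0.1, 1, by = 0.1)}.
#' @param universe evaluation universe, see [confusionCounts()].
#' @param strict use an exclusive threshold (score > cutoff).
#' @return A data.frame with one row per cutoff (columns as in
#'   [confusionCounts()]).
#' @export
precisionRecallSweep <- function(freq, gold, cutoffs = seq(0.1, 1, by = 0.1),
                                 universe = c("labeled", "all"),
                                 strict = FALSE) {
  universe <- match.arg(universe)
  stopifnot(is(freq, "FrequencyTable"))
  if (length(cutoffs) == 0L) configError("cutoffs must be non-empty")
  if (any(cutoffs < 0 | cutoffs > 1))
    configError("cutoffs must lie in [0, 1]")
  rows <- lapply(cutoffs, function(ct) {
    et <- thresholdEdges(freq, ct, strict = strict)
    confusionCounts(et, gold, universe = universe, cutoff = ct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-based ROC-AUC of frequency scores against a gold standard
#'
#' The area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney statistic): the probability that a randomly chosen gold
#' positive pair outranks a randomly chosen negative pair by frequency
#' score, with tied scores contributing 1/2. Pairs in the evaluation
#' universe that the score table never selected score 0.
#'
#' @param freq a [FrequencyTable-class].
#' @param gold a [GoldStandard-class] with at least one positive and one
#'   negative in the universe.
#' @param universe \code{"labeled"} (default): the gold-standard pairs;
#'   \code{"all"}: every candidate regulator x target pair in the score
#'   table (plus any labelled pair outside it), with non-positives treated
#'   as negatives.
#' @return The AUC, a number in [0, 1].
#' @export
rocAUC <- function(freq, gold, universe = c("labeled", "all")) {
  universe <- match.arg(universe)
  stopifnot(is(freq, "FrequencyTable"), is(gold, "GoldStandard"))
  lab <- .aucUniverse(freq, gold, universe)
  nPos <- sum(lab$label == 1L)
  nNeg <- sum(lab$label == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs at least one positive and one negative in the universe",
         call. = FALSE)
  r <- rank(lab$score)  # midranks for ties
  (sum(r[lab$label == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Assemble the (score, label) pairs an AUC is computed over.
.aucUniverse <- function(freq, gold, universe) {
  s <- freq@score
  goldKey <- paste(gold@regulator, gold@target, sep = "\r")
  posKey <- goldKey[gold@label == 1L]
  lookup <- function(keys) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    vapply(parts, function(p) {
      if (p[1] %in% rownames(s) && p[2] %in% colnames(s)) s[p[1], p[2]]
      else 0
    }, numeric(1))
  }
  if (universe == "labeled") {
    data.frame(score = lookup(goldKey),
               label = gold@label, stringsAsFactors = FALSE)
  } else {
    regs <- rownames(s)
    tgts <- colnames(s)
    allKey <- paste(rep(regs, times = length(tgts)),
                    rep(tgts, each = length(regs)), sep = "\r")
    selfs <- rep(regs, times = length(tgts)) == rep(tgts, each = length(regs))
    allKey <- allKey[!selfs]
    scores <- as.vector(s)[!selfs]
    extra <- setdiff(goldKey, allKey)
    data.frame(
      score = c(scores, lookup(extra)),
      label = as.integer(c(allKey %in% posKey, extra %in% posKey)),
      stringsAsFactors = FALSE)
  }
}

#' Write an evaluation report
#'
#' A TSV with one row per cutoff (cutoff, tp, fp, fn, tn, precision,
#' recall; undefined precision written as NA) followed by a single-line AUC
#' summary to stderr-style text at the end of the file when \code{auc} is
#' supplied.
#'
#' @param sweep data.frame from [precisionRecallSweep()].
#' @param path output path.
#' @param auc optional AUC to append as a trailing comment line.
#' @return Invisibly, the path.
#' @export
writeEvaluationReport <- function(sweep, path, auc = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sweep
  fmt$precision <- ifelse(is.na(sweep$precision), "NA",
                          sprintf("%.6f", sweep$precision))
  fmt$recall <- sprintf("%.6f", sweep$recall)
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(auc)) writeLines(sprintf("# AUC\t%.6f", auc), con)
  invisible(path)
}
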