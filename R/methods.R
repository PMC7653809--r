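#' @rdname stabnet-accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) colnames(object@values))

#' @rdname stabnet-accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) rownames(object@values))

#' @rdname stabnet-accessors
#' @export
setMethod("nGenes", "ExpressionMatrix", function(object) ncol(object@values))

#' @rdname stabnet-accessors
#' @export
setMethod("nObservations", "ExpressionMatrix",
          function(object) nrow(object@values))

#' @rdname stabnet-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname stabnet-accessors
#' @export
setMethod("constantGenes", "ExpressionMatrix",
          function(object) object@constantGenes)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d observations x %d genes\n",
              nObservations(object), nGenes(object)))
  if (length(object@constantGenes))
    cat(sprintf("  constant (zero-variance) genes: %d\n",
                length(object@constantGenes)))
  ids <- geneIds(object)
  cat("  genes:", paste(head(ids, 5), collapse = ", "),
      if (length(ids) > 5) "..." else "", "\n")
})

#' @rdname stabnet-accessors
#' @export
setMethod("positivePairs", "GoldStandard", function(object) {
  i <- object@label == 1L
  data.frame(regulator = object@regulator[i], target = object@target[i],
             stringsAsFactors = FALSE)
})

setMethod("length", "GoldStandard", function(x) length(x@label))

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d labelled pairs (%d positive, %d negative)\n",
              length(object), sum(object@label == 1L),
              sum(object@label == 0L)))
})

#' Coerce a GoldStandard to a data.frame
#' @param x a [GoldStandard-class].
#' @param ... ignored.
#' @return data.frame with columns regulator, target, label.
#' @export
as.data.frame.GoldStandard <- function(x, ...) {
  data.frame(regulator = x@regulator, target = x@target, label = x@label,
             stringsAsFactors = FALSE)
}

#' @rdname stabnet-accessors
#' @export
setMethod("edges", "EdgeTable", function(object) object@edges)

#' @rdname stabnet-accessors
#' @export
setMethod("nEdges", "EdgeTable", function(object) nrow(object@edges))

setMethod("show", "EdgeTable", function(object) {
  cat(sprintf("EdgeTable: %d directed edges\n", nEdges(object)))
  if (nEdges(object) > 0) {
    print(head(object@edges, 6))
    if (nEdges(object) > 6) cat("  ...\n")
  }
})

#' Coerce an EdgeTable to a data.frame
#' @param x an [EdgeTable-class].
#' @param ... ignored.
#' @return data.frame with columns regulator, target, score, sign.
#' @export
as.data.frame.EdgeTable <- function(x, ...) x@edges

#' @rdname stabnet-accessors
#' @export
setMethod("hitCounts", "SelectionTally", function(object) object@hits)

#' @rdname stabnet-accessors
#' @export
setMethod("nTrials", "SelectionTally", function(object) object@trials)

#' @rdname stabnet-accessors
#' @export
setMethod("signMatrix", "SelectionTally", function(object) object@signSum)

setMethod("show", "SelectionTally", function(object) {
  cat(sprintf(
    "SelectionTally: %d candidate regulators x %d targets, %d trials\n",
    nrow(object@hits), ncol(object@hits), object@trials))
  cat(sprintf("  nonzero tallies: %d\n", sum(object@hits > 0L)))
})

#' @rdname stabnet-accessors
#' @export
setMethod("scoreMatrix", "FrequencyTable", function(object) object@score)

#' @rdname stabnet-accessors
#' @export
setMethod("signMatrix", "FrequencyTable", function(object) object@sign)

#' @rdname stabnet-accessors
#' @export
setMethod("nTrials", "FrequencyTable", function(object) object@trials)

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf(
    "FrequencyTable: %d candidate regulators x %d targets, %d trials\n",
    nrow(object@score), ncol(object@score), object@trials))
  cat(sprintf("  pairs with score > 0: %d; max score: %s\n",
              sum(object@score > 0),
              format(suppressWarnings(max(object@score)), digits = 4)))
})

#' Long-format view of a FrequencyTable
#'
#' @param x a [FrequencyTable-class].
#' @param ... ignored.
#' @param dropZero drop pairs with score 0 (default TRUE).
#' @return data.frame with columns regulator, target, score, sign; self-pairs
#'   are never included.
#' @export
as.data.frame.FrequencyTable <- function(x, ..., dropZero = TRUE) {
  s <- x@score
  regs <- rownames(s)
  tgts <- colnames(s)
  keep <- if (dropZero) which(s > 0) else seq_along(s)
  if (length(keep) == 0L)
    return(data.frame(regulator = character(0), target = character(0),
                      score = numeric(0), sign = integer(0),
                      stringsAsFactors = FALSE))
  ri <- ((keep - 1L) %% nrow(s)) + 1L
  ci <- ((keep - 1L) %/% nrow(s)) + 1L
  out <- data.frame(regulator = regs[ri], target = tgts[ci],
                    score = s[keep], sign = as.integer(x@sign[keep]),
                    stringsAsFactors = FALSE)
  out <- out[out$regulator != out$target, , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "ENFit", function(object) {
  sup <- selectedSupport(object)
  cat(sprintf("ENFit: %d candidates, %d selected at lambda = %s\n",
              length(object@coefficients), length(sup$indices),
              format(object@lambdaSelected, digits = 4)))
})

setMethod("show", "ENConfig", function(object) {
  cat(sprintf(
    "ENConfig: alpha = %g, %d-fold CV, path %d (min ratio %g), rule '%s'\n",
    object@alpha, object@kfolds, object@nLambda, object@lambdaMinRatio,
    object@lambdaRule))
})

setMethod("show", "InferenceConfig", function(object) {
  cat(sprintf(
    "InferenceConfig: m = %d, nIter = %d (%d trials), cutoff %s %g, seed %d\n",
    object@m, object@nIter, object@m * object@nIter,
    if (object@strictCutoff) ">" else ">=", object@cutoff, object@seed))
  cat(sprintf("  targets: %s; regulators: %s; workers: %d\n",
              if (length(object@targets)) length(object@targets) else "all",
              if (length(object@regulators)) length(object@regulators) else "all",
              object@workers))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d genes (%d sources) x %d obs, k = %d, |beta| in [%g, %g], noise sd %g, seed %d\n",
    object@pGenes, object@nRegulators, object@nObs, object@kPerTarget,
    object@betaRange[1], object@betaRange[2], object@noiseSd, object@seed))
})
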