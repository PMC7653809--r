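#' @useDynLib stabnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Expression matrix container
#'
#' Holds a normalized expression matrix with observations (samples) in rows
#' and genes in columns, the orientation in which each gene can serve directly
#' as a response or predictor in a regression. Gene identifiers are the column
#' names and must be unique and non-empty; all values must be finite. Genes
#' found to have zero variance are recorded in \code{constantGenes} so that
#' downstream inference can exclude them from the candidate-regulator pool
#' (a constant predictor is degenerate under standardization) while keeping
#' them as potential targets.
#'
#' @slot values numeric matrix, observations x genes.
#' @slot constantGenes character vector of gene ids flagged as zero-variance.
#'
#' @seealso [readExpressionMatrix()], [standardizeExpression()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", constantGenes = "character"),
  prototype(constantGenes = character(0))
)

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L || ncol(v) < 2L)
    return("expression matrix needs at least 2 observations and 2 genes")
  ids <- colnames(v)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("gene identifiers (column names) must be present and non-empty")
  if (anyDuplicated(ids))
    return(sprintf("duplicate gene identifiers: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!all(is.finite(v)))
    return("expression values must all be finite (no NA/NaN/Inf)")
  if (!all(object@constantGenes %in% ids))
    return("constantGenes must be a subset of the gene identifiers")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, observations in rows and genes in columns.
#' @param geneIds character vector of unique gene identifiers; defaults to
#'   the column names of \code{values}.
#' @param sampleIds optional observation identifiers (row names).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = colnames(values),
                             sampleIds = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- geneIds
  rownames(values) <- sampleIds
  new("ExpressionMatrix", values = values)
}

#' Gold-standard edge labels
#'
#' A set of directed (regulator, target) pairs each labelled 1 (known true
#' interaction) or 0 (known non-interaction), in the style of the DREAM5
#' benchmark gold standards. Pairs absent from the set are unlabelled and are
#' handled by the evaluation universe policy.
#'
#' @slot regulator,target character vectors of equal length.
#' @slot label integer vector of 0/1 labels.
#' @seealso [readGoldStandard()], [confusionCounts()]
#' @export
setClass("GoldStandard",
  representation(regulator = "character", target = "character",
                 label = "integer")
)

setValidity("GoldStandard", function(object) {
  n <- length(object@regulator)
  if (length(object@target) != n || length(object@label) != n)
    return("regulator, target and label must have equal length")
  if (n > 0 && !all(object@label %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  key <- paste(object@regulator, object@target, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (regulator, target) pairs in gold standard")
  self <- object@label == 1L & object@regulator == object@target
  if (any(self)) return("self-pairs cannot be labelled positive")
  TRUE
})

#' @rdname GoldStandard-class
#' @param regulator,target character vectors naming the pair members.
#' @param label 0/1 integer labels (1 = true interaction).
#' @export
GoldStandard <- function(regulator = character(0), target = character(0),
                         label = integer(0)) {
  new("GoldStandard", regulator = as.character(regulator),
      target = as.character(target), label = as.integer(label))
}

#' Scored directed edges
#'
#' The inferred network: one row per directed regulator -> target edge with
#' its selection frequency score in [0, 1] and an optional aggregate
#' coefficient sign (-1, 0, +1). Rows are kept sorted by descending score,
#' ties broken lexicographically by (regulator, target), so written output is
#' stable across runs.
#'
#' @slot edges data.frame with columns regulator, target, score, sign.
#' @seealso [inferNetwork()], [writeEdgeTable()]
#' @export
setClass("EdgeTable", representation(edges = "data.frame"))

setValidity("EdgeTable", function(object) {
  e <- object@edges
  need <- c("regulator", "target", "score", "sign")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return(TRUE)
  if (any(e$regulator == e$target)) return("self-edges are not allowed")
  key <- paste(e$regulator, e$target, sep = "\r")
  if (anyDuplicated(key)) return("duplicate (regulator, target) edges")
  if (any(!is.finite(e$score)) || any(e$score < 0) || any(e$score > 1))
    return("scores must lie in [0, 1]")
  if (!all(e$sign %in% c(-1, 0, 1))) return("signs must be -1, 0 or +1")
  TRUE
})

#' @rdname EdgeTable-class
#' @param regulator,target character vectors naming each directed edge.
#' @param score numeric frequency scores in [0, 1].
#' @param sign aggregate coefficient signs (-1, 0, +1); defaults to 0.
#' @export
EdgeTable <- function(regulator = character(0), target = character(0),
                      score = numeric(0), sign = rep(0L, length(score))) {
  e <- data.frame(regulator = as.character(regulator),
                  target = as.character(target),
                  score = as.numeric(score), sign = as.integer(sign),
                  stringsAsFactors = FALSE)
  e <- e[order(-e$score, e$regulator, e$target), , drop = FALSE]
  rownames(e) <- NULL
  new("EdgeTable", edges = e)
}

#' Elastic-net fit configuration
#'
#' Settings for one cross-validation-tuned elastic-net fit. \code{alpha}
#' mixes the L1 and L2 penalties (1 = lasso); the penalty path has
#' \code{nLambda} log-spaced values down to \code{lambdaMinRatio} times the
#' smallest penalty that zeroes every coefficient. \code{lambdaRule} picks the
#' path point: \code{"min"} (smallest mean CV error, the default) or
#' \code{"1se"} (sparsest fit within one standard error of the minimum).
#'
#' @slot alpha numeric in (0, 1].
#' @slot kfolds integer >= 2 cross-validation folds.
#' @slot nLambda integer >= 2 path length.
#' @slot lambdaMinRatio numeric in (0, 1).
#' @slot tol numeric convergence tolerance of the coordinate-descent solver.
#' @slot maxIter integer sweep cap for the solver.
#' @slot lambdaRule "min" or "1se".
#' @export
setClass("ENConfig",
  representation(alpha = "numeric", kfolds = "integer", nLambda = "integer",
                 lambdaMinRatio = "numeric", tol = "numeric",
                 maxIter = "integer", lambdaRule = "character")
)

setValidity("ENConfig", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha > 1)
    return("alpha must be a single value in (0, 1]")
  if (object@kfolds < 2L) return("kfolds must be >= 2")
  if (object@nLambda < 2L) return("nLambda must be >= 2")
  if (object@lambdaMinRatio <= 0 || object@lambdaMinRatio >= 1)
    return("lambdaMinRatio must be in (0, 1)")
  if (object@tol <= 0) return("tol must be positive")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (!object@lambdaRule %in% c("min", "1se"))
    return("lambdaRule must be 'min' or '1se'")
  TRUE
})

#' @rdname ENConfig-class
#' @param alpha,kfolds,nLambda,lambdaMinRatio,tol,maxIter,lambdaRule see slots.
#' @export
enConfig <- function(alpha = 0.5, kfolds = 5L, nLambda = 100L,
                     lambdaMinRatio = 0.01, tol = 1e-4, maxIter = 10000L,
                     lambdaRule = c("min", "1se")) {
  new("ENConfig", alpha = alpha, kfolds = as.integer(kfolds),
      nLambda = as.integer(nLambda), lambdaMinRatio = lambdaMinRatio,
      tol = tol, maxIter = as.integer(maxIter),
      lambdaRule = match.arg(lambdaRule))
}

#' A cross-validated elastic-net fit
#'
#' @slot coefficients numeric vector over the candidate predictors (named)
#'   at the selected penalty.
#' @slot intercept numeric intercept at the selected penalty.
#' @slot lambdaSelected the selected penalty (a member of \code{lambda}).
#' @slot lambda the evaluated penalty path.
#' @slot cvErrors mean cross-validation squared error along the path.
#' @slot converged logical; FALSE if the solver hit its iteration cap.
#' @seealso [fitElasticNetCV()], [selectedSupport()]
#' @export
setClass("ENFit",
  representation(coefficients = "numeric", intercept = "numeric",
                 lambdaSelected = "numeric", lambda = "numeric",
                 cvErrors = "numeric", converged = "logical")
)

setValidity("ENFit", function(object) {
  if (length(object@lambda) > 0 &&
      !isTRUE(any(object@lambda == object@lambdaSelected)))
    return("lambdaSelected must be a member of the evaluated path")
  if (length(object@cvErrors) != length(object@lambda))
    return("cvErrors must align with the penalty path")
  TRUE
})

#' Stability-selection inference configuration
#'
#' Parameters of the resampling engine: in each of \code{nIter} iterations the
#' samples are partitioned into \code{m} disjoint subgroups and an elastic-net
#' is fitted per (subgroup, target), giving \code{nIter * m} trials per target.
#' Edges whose selection frequency reaches \code{cutoff} are reported.
#'
#' @slot m integer >= 1, subgroups per iteration.
#' @slot nIter integer >= 1, resampling iterations.
#' @slot cutoff numeric in [0, 1], frequency-score threshold.
#' @slot seed integer master seed; every random stream derives from it.
#' @slot targets character vector of target gene ids (empty = all genes).
#' @slot regulators character whitelist of candidate regulators (empty = all).
#' @slot en an [ENConfig-class].
#' @slot workers integer, requested parallel workers (results are identical
#'   for any worker count).
#' @slot strictCutoff logical; if TRUE the threshold is exclusive (score >
#'   cutoff) instead of the default inclusive (score >= cutoff).
#' @export
setClass("InferenceConfig",
  representation(m = "integer", nIter = "integer", cutoff = "numeric",
                 seed = "integer", targets = "character",
                 regulators = "character", en = "ENConfig",
                 workers = "integer", strictCutoff = "logical")
)

setValidity("InferenceConfig", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@nIter < 1L) return("nIter must be >= 1")
  if (object@cutoff < 0 || object@cutoff > 1)
    return("cutoff must be in [0, 1]")
  if (object@workers < 1L) return("workers must be >= 1")
  TRUE
})

#' @rdname InferenceConfig-class
#' @param m,nIter,cutoff,seed,targets,regulators,en,workers,strictCutoff see
#'   slots.
#' @export
inferenceConfig <- function(m = 4L, nIter = 500L, cutoff = 0.95, seed = 0L,
                            targets = character(0), regulators = character(0),
                            en = enConfig(), workers = 1L,
                            strictCutoff = FALSE) {
  new("InferenceConfig", m = as.integer(m), nIter = as.integer(nIter),
      cutoff = cutoff, seed = as.integer(seed),
      targets = as.character(targets), regulators = as.character(regulators),
      en = en, workers = as.integer(workers), strictCutoff = strictCutoff)
}

#' Per-pair selection tally
#'
#' Hit counts over the n x m resampling trials: \code{hits[r, t]} is the
#' number of trials in which candidate regulator r had a nonzero coefficient
#' in the fit for target t; \code{signSum} accumulates the coefficient signs
#' of those hits. \code{trials = nIter * m} is the common denominator.
#'
#' @slot hits integer matrix, candidate regulators x targets.
#' @slot signSum integer matrix of summed coefficient signs, same shape.
#' @slot trials integer, total trials per (target, regulator) pair.
#' @seealso [tallySelections()], [frequencyScores()]
#' @export
setClass("SelectionTally",
  representation(hits = "matrix", signSum = "matrix", trials = "integer")
)

setValidity("SelectionTally", function(object) {
  h <- object@hits
  if (is.null(rownames(h)) || is.null(colnames(h)))
    return("hits must carry regulator row names and target column names")
  if (!identical(dim(h), dim(object@signSum)))
    return("hits and signSum must have identical shape")
  if (any(h < 0L) || any(h > object@trials))
    return("hits must lie in [0, trials]")
  if (any(abs(object@signSum) > h))
    return("|signSum| cannot exceed hits")
  shared <- intersect(rownames(h), colnames(h))
  if (any(h[cbind(shared, shared)] != 0L))
    return("self-selection (gene regulating itself) must have zero hits")
  TRUE
})

#' Frequency scores per (target, regulator) pair
#'
#' Scores are hits/trials in [0, 1]; 1 means the regulator was selected in
#' every trial for that target (the highest confidence). \code{sign} is the
#' sign of the summed per-trial coefficient signs (0 on an exact tie).
#'
#' @slot score numeric matrix, candidate regulators x targets.
#' @slot sign integer matrix of -1/0/+1, same shape.
#' @slot trials integer denominator used.
#' @seealso [frequencyScores()], [rocAUC()]
#' @export
setClass("FrequencyTable",
  representation(score = "matrix", sign = "matrix", trials = "integer")
)

setValidity("FrequencyTable", function(object) {
  s <- object@score
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    return("scores must lie in [0, 1]")
  if (!identical(dim(s), dim(object@sign)))
    return("score and sign must have identical shape")
  TRUE
})

#' Synthetic sparse linear network specification
#'
#' Describes a two-layer benchmark network: the first \code{nRegulators}
#' genes are independent standard-normal sources; each of the remaining
#' \code{pGenes - nRegulators} genes is a target driven by
#' \code{kPerTarget} distinct sources with effect sizes drawn uniformly from
#' \code{[betaRange[1], betaRange[2]]} with random sign, plus Gaussian noise
#' of standard deviation \code{noiseSd}. The drawn regulator -> target pairs
#' form the gold-standard positives; every other source -> target pair is a
#' labelled negative.
#'
#' @slot pGenes,nObs,nRegulators,kPerTarget integers.
#' @slot betaRange numeric length-2 absolute effect-size interval.
#' @slot noiseSd numeric >= 0.
#' @slot seed integer.
#' @seealso [simulateGRN()], [benchmarkRun()]
#' @export
setClass("SyntheticSpec",
  representation(pGenes = "integer", nObs = "integer",
                 nRegulators = "integer", kPerTarget = "integer",
                 betaRange = "numeric", noiseSd = "numeric", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  if (object@pGenes < 3L) return("pGenes must be >= 3")
  if (object@nObs < 2L) return("nObs must be >= 2")
  if (object@nRegulators < 1L || object@nRegulators >= object@pGenes)
    return("nRegulators must be in [1, pGenes - 1]")
  if (object@kPerTarget < 0L || object@kPerTarget > object@nRegulators)
    return("kPerTarget must be in [0, nRegulators]")
  if (length(object@betaRange) != 2L || object@betaRange[1] <= 0 ||
      object@betaRange[1] > object@betaRange[2])
    return("betaRange must be 0 < low <= high")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @rdname SyntheticSpec-class
#' @param pGenes,nObs,nRegulators,kPerTarget,betaRange,noiseSd,seed see slots.
#' @export
syntheticSpec <- function(pGenes = 100L, nObs = 400L, nRegulators = 20L,
                          kPerTarget = 2L, betaRange = c(1, 2),
                          noiseSd = 0.5, seed = 1L) {
  new("SyntheticSpec", pGenes = as.integer(pGenes), nObs = as.integer(nObs),
      nRegulators = as.integer(nRegulators),
      kPerTarget = as.integer(kPerTarget), betaRange = as.numeric(betaRange),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}
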