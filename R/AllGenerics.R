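#' @name stabnet-accessors
#' @title Accessors for stabnet classes
#' @description Accessor generics for the core containers: gene and sample
#'   identifiers, dimensions, the underlying numeric values, and derived
#'   views such as gold-standard positives or the long-format score table.
#' @param object a stabnet S4 object.
#' @return See the individual methods.
NULL

#' @rdname stabnet-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname stabnet-accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname stabnet-accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname stabnet-accessors
#' @export
setGeneric("nObservations", function(object) standardGeneric("nObservations"))

#' @rdname stabnet-accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname stabnet-accessors
#' @export
setGeneric("constantGenes", function(object) standardGeneric("constantGenes"))

#' @rdname stabnet-accessors
#' @export
setGeneric("positivePairs", function(object) standardGeneric("positivePairs"))

#' @rdname stabnet-accessors
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname stabnet-accessors
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname stabnet-accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @rdname stabnet-accessors
#' @export
setGeneric("signMatrix", function(object) standardGeneric("signMatrix"))

#' @rdname stabnet-accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname stabnet-accessors
#' @export
setGeneric("hitCounts", function(object) standardGeneric("hitCounts"))

#' Selected predictors of an elastic-net fit
#'
#' @param fit an [ENFit-class].
#' @return A list with \code{indices} (1-based positions of the predictors
#'   with strictly nonzero coefficient at the selected penalty), \code{ids}
#'   (their names, when the design matrix had column names) and \code{signs}
#'   (the coefficient signs, aligned with \code{indices}).
#' @export
setGeneric("selectedSupport", function(fit) standardGeneric("selectedSupport"))
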