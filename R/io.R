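#' Read an expression matrix from delimited text
#'
#' The expected layout is a header row of gene identifiers with one row per
#' observation (genes in columns); a transposed file (genes in rows, first
#' column holding the gene identifier) is supported via
#' \code{orientation = "genes-in-rows"} and is transposed on load. Values
#' must be numeric and finite; the matrix is assumed to be already
#' normalized (this package performs no count normalization).
#'
#' @param path path to the delimited text file.
#' @param delimiter field separator (default tab). No auto-detection is
#'   attempted, so runs are reproducible bit-for-bit.
#' @param orientation \code{"genes-in-columns"} (default) or
#'   \code{"genes-in-rows"}.
#' @return An [ExpressionMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("g1\tg2", "0.1\t2.0", "1.5\t0.3", "0.7\t1.1"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, delimiter = "\t",
                                 orientation = c("genes-in-columns",
                                                 "genes-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) formatError(sprintf("no such file: %s", path))
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "genes-in-rows") {
    ids <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- ids
    rownames(m) <- NULL
  } else {
    ids <- names(df)
    m <- as.matrix(df)
    colnames(m) <- ids
  }
  if (any(is.na(ids)) || any(!nzchar(ids)))
    formatError("missing or empty gene identifiers in header")
  if (anyDuplicated(ids))
    formatError(sprintf("duplicate gene identifiers: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                 !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" (first at row %d, column %d)",
                                  bad[1, 1], bad[1, 2]) else ""
    formatError(sprintf("non-numeric expression value%s", loc))
  }
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(is.na(m) | !is.finite(m), arr.ind = TRUE)
    formatError(sprintf(
      "non-finite expression value at row %d, column %d (gene %s)",
      bad[1, 1], bad[1, 2], ids[bad[1, 2]]))
  }
  ExpressionMatrix(m, geneIds = ids)
}

#' Standardize gene columns for regression
#'
#' Centres every gene column to mean 0 and scales it to unit sample standard
#' deviation (denominator n - 1). Zero-variance genes cannot be scaled: they
#' are centred, flagged in \code{constantGenes} with a warning, and excluded
#' from the candidate-regulator pool downstream while remaining available as
#' (null-regression) targets. The transform is idempotent.
#'
#' @param object an [ExpressionMatrix-class].
#' @return A standardized [ExpressionMatrix-class] with constant genes
#'   flagged.
#' @export
standardizeExpression <- function(object) {
  stopifnot(is(object, "ExpressionMatrix"))
  v <- object@values
  mu <- colMeans(v)
  v <- sweep(v, 2L, mu, "-")
  sds <- apply(v, 2L, sd)
  const <- which(sds < 1e-12)
  if (length(const)) {
    warning(sprintf(
      "zero-variance gene(s) flagged constant and excluded from candidates: %s",
      paste(colnames(v)[const], collapse = ", ")), call. = FALSE)
    sds[const] <- 1
  }
  v <- sweep(v, 2L, sds, "/")
  out <- object
  out@values <- v
  out@constantGenes <- union(object@constantGenes, colnames(v)[const])
  validObject(out)
  out
}

#' Read a gold-standard edge list
#'
#' Three-column delimited text in the DREAM5 dialect: regulator id, target
#' id, 0/1 label (1 = known interaction). No header is expected. Duplicate
#' pairs with conflicting labels are a format error; exact duplicate rows are
#' collapsed.
#'
#' @param path path to the file.
#' @param delimiter field separator (default tab).
#' @return A [GoldStandard-class].
#' @export
readGoldStandard <- function(path, delimiter = "\t") {
  if (!file.exists(path)) formatError(sprintf("no such file: %s", path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(GoldStandard())
  df <- read.delim(path, sep = delimiter, header = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(GoldStandard())
  if (ncol(df) < 3L)
    formatError("gold standard must have 3 columns: regulator, target, label")
  lab <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    formatError("gold-standard labels must be 0 or 1")
  reg <- as.character(df[[1]])
  tgt <- as.character(df[[2]])
  key <- paste(reg, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(lab, key, function(x) length(unique(x)))
    if (any(agg > 1))
      formatError("duplicate (regulator, target) pair with conflicting labels")
    keep <- !duplicated(key)
    reg <- reg[keep]; tgt <- tgt[keep]; lab <- lab[keep]
  }
  GoldStandard(reg, tgt, as.integer(lab))
}

#' Write an edge table as delimited text
#'
#' One edge per row: regulator, target, score (fixed 6-decimal format) and
#' sign, tab-separated with a header. Rows are written in descending score
#' order with lexicographic (regulator, target) tie-breaks, so output files
#' are byte-stable across runs and worker counts.
#'
#' @param object an [EdgeTable-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @seealso [readEdgeTable()]
#' @export
writeEdgeTable <- function(object, path) {
  stopifnot(is(object, "EdgeTable"))
  e <- object@edges
  e <- e[order(-e$score, e$regulator, e$target), , drop = FALSE]
  out <- data.frame(regulator = e$regulator, target = e$target,
                    score = sprintf("%.6f", e$score), sign = e$sign,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(err) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write edge table to '%s'", path),
                call. = FALSE)
  invisible(path)
}

#' Read an edge table written by [writeEdgeTable()]
#'
#' @param path path to the file.
#' @return An [EdgeTable-class].
#' @export
readEdgeTable <- function(path) {
  if (!file.exists(path)) formatError(sprintf("no such file: %s", path))
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(EdgeTable())
  sgn <- if ("sign" %in% names(df)) df$sign else rep(0L, nrow(df))
  EdgeTable(df$regulator, df$target, df$score, sgn)
}

#' Write an expression matrix as delimited text
#'
#' Genes in columns, header of gene identifiers, one row per observation;
#' the layout [readExpressionMatrix()] reads back by default.
#'
#' @param object an [ExpressionMatrix-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeExpressionMatrix <- function(object, path) {
  stopifnot(is(object, "ExpressionMatrix"))
  write.table(object@values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = geneIds(object))
  invisible(path)
}

#' Write a gold standard as three-column delimited text
#'
#' @param object a [GoldStandard-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeGoldStandard <- function(object, path) {
  stopifnot(is(object, "GoldStandard"))
  df <- as.data.frame(object)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
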