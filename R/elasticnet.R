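#' Cross-validation-tuned elastic-net fit
#'
#' Fits the elastic-net penalized least-squares model
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'       \lambda\left[\alpha\|\beta\|_1 +
#'       \tfrac{1-\alpha}{2}\|\beta\|_2^2\right]}
#' over a log-spaced penalty path by coordinate descent (compiled, with warm
#' starts), then selects the path point by k-fold cross-validation. Fold
#' assignment is a deterministic function of \code{seed}: contiguous blocks
#' of a seeded permutation of the rows, remainder rows spread one per fold
#' from the first. The fold fits reuse the penalty path computed on the full
#' data, and the fit at the selected penalty is returned.
#'
#' Only the support (which coefficients are nonzero) matters downstream:
#' stability selection counts a predictor as a hit when its coefficient is
#' strictly nonzero at the selected penalty.
#'
#' @param X numeric design matrix, observations x candidate predictors.
#'   Column names, when present, become coefficient names.
#' @param y numeric response vector of length \code{nrow(X)}.
#' @param config an [ENConfig-class]; defaults follow the package defaults
#'   (alpha 0.5, 5-fold CV, 100-point path).
#' @param seed integer seed for the fold assignment.
#' @return An [ENFit-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
#' y <- 2 * X[, 1] + rnorm(100, sd = 0.1)
#' selectedSupport(fitElasticNetCV(X, y, seed = 1L))
#' @export
fitElasticNetCV <- function(X, y, config = enConfig(), seed = 0L) {
  stopifnot(is(config, "ENConfig"))
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) configError("length(y) must equal nrow(X)")
  if (p == 0L) {
    return(new("ENFit", coefficients = setNames(numeric(0), character(0)),
               intercept = mean(y), lambdaSelected = NA_real_,
               lambda = numeric(0), cvErrors = numeric(0), converged = TRUE))
  }
  if (n < config@kfolds)
    configError(sprintf("n_obs (%d) is below the number of CV folds (%d)",
                        n, config@kfolds))
  if (anyNA(X) || anyNA(y) || !all(is.finite(y)))
    configError("X and y must be finite with no missing values")

  full <- .enetPath(X, y, config@alpha, numeric(0), config@nLambda,
                    config@lambdaMinRatio, config@tol, config@maxIter, TRUE)
  lam <- full$lambda
  nl <- length(lam)
  foldid <- cvFoldIds(n, config@kfolds, seed)
  mse <- matrix(NA_real_, config@kfolds, nl)
  conv <- full$converged
  for (f in seq_len(config@kfolds)) {
    tr <- foldid != f
    fit <- .enetPath(X[tr, , drop = FALSE], y[tr], config@alpha, lam,
                     0L, config@lambdaMinRatio, config@tol, config@maxIter,
                     TRUE)
    conv <- conv && fit$converged
    pred <- X[!tr, , drop = FALSE] %*% fit$beta
    pred <- sweep(pred, 2L, fit$a0, "+")
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  imin <- which.min(cvm)
  ilam <- if (config@lambdaRule == "1se") {
    cvse <- apply(mse, 2L, sd) / sqrt(config@kfolds)
    min(which(cvm <= cvm[imin] + cvse[imin]))
  } else {
    imin
  }
  if (!conv)
    warning("coordinate descent hit its iteration cap; fit at last iterate",
            call. = FALSE)
  co <- full$beta[, ilam]
  names(co) <- colnames(X)
  new("ENFit", coefficients = co, intercept = full$a0[ilam],
      lambdaSelected = lam[ilam], lambda = lam, cvErrors = cvm,
      converged = conv)
}

#' @describeIn fitElasticNetCV Selected support of a fit: indices (and names,
#'   when available) of the strictly nonzero coefficients at the selected
#'   penalty, with their signs.
#' @param fit an [ENFit-class].
#' @export
setMethod("selectedSupport", "ENFit", function(fit) {
  co <- fit@coefficients
  idx <- which(co != 0)
  list(indices = as.integer(unname(idx)),
       ids = if (is.null(names(co))) NULL else names(co)[idx],
       signs = as.integer(sign(co[idx])))
})

# Path solver wrapper used by tests for oracle comparisons: fits the full
# penalty path without cross-validation.
#' Elastic-net penalty path (no cross-validation)
#'
#' Computes the full coordinate-descent solution path. Mainly useful for
#' inspecting the path or comparing solvers; network inference goes through
#' [fitElasticNetCV()].
#'
#' @inheritParams fitElasticNetCV
#' @param lambda optional decreasing penalty sequence; when omitted the
#'   standard log-spaced path from the data-derived maximum is used.
#' @return A list with \code{beta} (p x nLambda matrix), \code{a0}
#'   (intercepts), \code{lambda}, \code{df} and \code{converged}.
#' @export
elasticNetPath <- function(X, y, config = enConfig(), lambda = numeric(0)) {
  stopifnot(is(config, "ENConfig"))
  X <- as.matrix(X)
  fit <- .enetPath(X, y, config@alpha, as.numeric(lambda), config@nLambda,
                   config@lambdaMinRatio, config@tol, config@maxIter, TRUE)
  rownames(fit$beta) <- colnames(X)
  fit
}
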