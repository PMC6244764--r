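#' @include AllClasses.R pls.R evaluation.R
NULL

#' Train a PLS model on the training subset of a compound set
#'
#' Convenience wrapper: extracts the training rows, drops zero-variance
#' descriptors, chooses the component count by seven-group
#' cross-validation, fits the NIPALS model and (optionally) attaches the
#' jackknife coefficient half-widths.
#'
#' @param cs a [CompoundSet-class] with `set` assignments.
#' @param response response name.
#' @param n_groups,seed,threshold see [selectComponents()].
#' @param uncertainty also compute jackknife half-widths (default TRUE).
#' @param rows optional row index overriding the training-set selection.
#' @return a [PLSModel-class]
#' @export
trainPLS <- function(cs, response, n_groups = 7, seed = 1, threshold = 0.01,
                     uncertainty = TRUE, rows = NULL) {
  if (is.null(rows)) rows <- which(cs@info$set == "training")
  if (!length(rows)) stop("no training compounds")
  X <- cs@descriptors@values[rows, , drop = FALSE]
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  y <- cs@responses[[response]][rows]
  if (is.null(y)) stop("unknown response: ", response)
  sel <- selectComponents(X, y, n_groups, seed, threshold = threshold)
  m <- suppressWarnings(fitPLS(X, y, sel$A, responseName = response,
                               cvRecord = sel$record))
  if (uncertainty)
    m@coefHalfWidth <- coefficientUncertainty(X, y, m@ncomp, n_groups, seed)
  m
}

#' Evaluate a model on one split of a compound set
#'
#' @param model a [PLSModel-class]
#' @param cs a [CompoundSet-class]
#' @param set which split to evaluate (default `"test"`).
#' @return an [EvaluationReport-class]
#' @export
evaluateOnSet <- function(model, cs, set = "test") {
  rows <- which(cs@info$set == set)
  if (length(rows) < 2) stop("fewer than 2 compounds in set ", set)
  y <- cs@responses[[model@responseName]][rows]
  pred <- predict(model, cs@descriptors@values[rows, , drop = FALSE])
  evaluatePredictions(y, pred, response = model@responseName, set = set)
}

#' 95-percentile error windows from a validation set
#'
#' @param cs a [CompoundSet-class]
#' @param models named list of [PLSModel-class] objects (names are
#'   responses).
#' @param set split to compute the windows on (default
#'   `"external_validation"`).
#' @return named numeric vector of 95th-percentile absolute residuals, one
#'   per response
#' @export
errorWindows <- function(cs, models, set = "external_validation") {
  vapply(names(models), function(r) {
    evaluateOnSet(models[[r]], cs, set)@p95
  }, numeric(1))
}
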