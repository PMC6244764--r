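#' @include AllClasses.R splitting.R
NULL

#' Prediction-quality statistics
#'
#' Computes the root-mean-square error of prediction with the N-1
#' denominator convention used throughout this package,
#' `RMSE_P = sqrt(sum((y_obs - y_pred)^2) / (N - 1))`, together with the
#' mean absolute deviation, the mean relative deviation
#' (|residual| / observed; zero observations are skipped and counted) and
#' the 95th percentile of the absolute residuals (linear interpolation
#' between order statistics).
#'
#' @param y_obs,y_pred numeric vectors of equal length, N >= 2.
#' @param response,set labels carried on the report.
#' @return an [EvaluationReport-class]
#' @examples
#' evaluatePredictions(c(1, 2, 3), c(2, 2, 2))
#' @export
evaluatePredictions <- function(y_obs, y_pred, response = "response",
                                set = "test") {
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  n <- length(y_obs)
  if (n < 2) stop("at least 2 points required (N-1 denominator)")
  res <- y_obs - y_pred
  nz <- y_obs != 0
  if (any(!nz))
    warning(sprintf("%d zero observations skipped in the relative deviation",
                    sum(!nz)))
  methods::new("EvaluationReport",
    n = n,
    rmsep = sqrt(sum(res^2) / (n - 1)),
    avgDev = mean(abs(res)),
    avgRelDev = if (any(nz)) mean(abs(res[nz]) / abs(y_obs[nz])) else NA_real_,
    p95 = unname(stats::quantile(abs(res), 0.95, type = 7)),
    residuals = res, relSkipped = sum(!nz),
    response = response, set = set)
}

#' Reference models for benchmarking
#'
#' Two baselines against which the full models must be judged: a simple
#' least-squares model on the designated basic descriptor(s) -- boiling
#' point for first-dimension responses; logKow together with its
#' weight-normalised variant for second-dimension responses -- and a
#' constant mean-of-training predictor.
#'
#' @param train,test [CompoundSet-class] objects (typically the training
#'   and test subsets).
#' @param response response name.
#' @param benchmark_descriptors character names of the descriptor(s) for the
#'   simple linear reference model; default `"bp"` for `t1R`/`LRI` and
#'   `c("logKow", "logKow_perMW")` for `t2R`/`PEG2I`.
#' @return list with `simple` and `mean` ([EvaluationReport-class]) plus
#'   `predictions`, a data.frame of both reference predictions on the test
#'   rows.
#' @export
benchmarkModels <- function(train, test, response,
                            benchmark_descriptors = NULL) {
  if (is.null(benchmark_descriptors))
    benchmark_descriptors <- if (response %in% c("t1R", "LRI")) "bp"
                             else c("logKow", "logKow_perMW")
  Xtr <- train@descriptors@values
  Xte <- test@descriptors@values
  missing <- setdiff(benchmark_descriptors, colnames(Xtr))
  if (length(missing))
    stop("configuration error: benchmark descriptor(s) missing: ",
         paste(missing, collapse = ", "))
  ytr <- train@responses[[response]]
  yte <- test@responses[[response]]
  df <- data.frame(y = ytr, Xtr[, benchmark_descriptors, drop = FALSE])
  fit <- stats::lm(y ~ ., data = df)
  predSimple <- unname(stats::predict(fit,
    data.frame(Xte[, benchmark_descriptors, drop = FALSE])))
  predMean <- rep(mean(ytr), length(yte))
  list(simple = evaluatePredictions(yte, predSimple, response,
                                    "test (simple reference)"),
       mean = evaluatePredictions(yte, predMean, response,
                                  "test (mean baseline)"),
       predictions = data.frame(compound_id = test@info$compound_id,
                                simple = predSimple, mean = predMean,
                                stringsAsFactors = FALSE))
}

#' Average two prediction vectors
#'
#' Ensemble of the latent-variable and federated predictors: the
#' elementwise arithmetic mean of the two predictions, which tightens the
#' error window when the two methods err independently.
#'
#' @param pred_a,pred_b aligned numeric vectors.
#' @return numeric vector of means
#' @export
ensembleAverage <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) stop("length mismatch")
  (pred_a + pred_b) / 2
}

#' PCA-based applicability domain
#'
#' A query is in-domain when (i) its Hotelling T-squared over the retained
#' components is below the calibrated limit (the F-based limit, floored by
#' the empirical training quantile) and (ii) its residual distance-to-model
#' is below the corresponding quantile of the training residuals. The two
#' per-check levels are Bonferroni-split (`1 - (1-level)/2` each, lower
#' empirical quantiles, boundary inclusive), so the combined rule keeps at
#' least `level` of the training compounds in-domain by construction.
#'
#' @param pca a [PCAModel-class] fitted on the training descriptors.
#' @param query matrix of raw descriptor values (named columns covering the
#'   PCA descriptors); one row per query.
#' @param level target overall training coverage (default 0.95).
#' @return data.frame `t2`, `t2_limit`, `dmod`, `dmod_limit`, `in_domain`
#' @export
applicabilityDomain <- function(pca, query, level = 0.95) {
  if (is.null(dim(query)))
    query <- matrix(query, nrow = 1, dimnames = list(NULL, names(query)))
  a <- ncol(pca@scores)
  n <- nrow(pca@scores)
  alpha <- (1 - level) / 2
  s2 <- apply(pca@scores, 2, stats::var)
  nm <- rownames(pca@loadings)
  scQ <- sweep(sweep(query[, nm, drop = FALSE], 2, pca@center), 2,
               pca@scale, `/`)
  Sq <- scQ %*% pca@loadings
  t2 <- drop(sweep(Sq^2, 2, s2, `/`) %*% rep(1, a))
  resQ <- sqrt(rowSums((scQ - tcrossprod(Sq, pca@loadings))^2))
  t2lim <- pca@t2Limit
  if (!length(t2lim))
    t2lim <- max(a * (n - 1) * (n + 1) / (n * (n - a)) *
                   stats::qf(1 - alpha, a, n - a),
                 stats::quantile(t2, 1 - alpha, type = 1))
  dlim <- pca@dmodLimit
  ## without calibrated limits the queries are assumed to BE the training
  ## rows (self-calibration), the common case when auditing the split
  if (!length(dlim)) dlim <- unname(stats::quantile(resQ, 1 - alpha,
                                                    type = 1))
  data.frame(t2 = t2, t2_limit = unname(t2lim), dmod = resQ,
             dmod_limit = dlim,
             in_domain = t2 <= t2lim & resQ <= dlim)
}

#' Calibrate the applicability-domain limits on the training set
#'
#' Stores the residual distance-to-model limit (the Bonferroni-split lower
#' empirical quantile of the training residual distances) and the Hotelling
#' T-squared limit (the F-based limit, floored by the corresponding
#' empirical training quantile) on the PCA model, so that later
#' [applicabilityDomain()] calls judge queries against the training
#' distribution and at least `level` of the training compounds are
#' in-domain.
#'
#' @param pca a [PCAModel-class]
#' @param training matrix of raw training descriptor values.
#' @param level target overall training coverage (default 0.95).
#' @return the PCA model with the calibrated limits attached.
#' @export
calibrateDomain <- function(pca, training, level = 0.95) {
  alpha <- (1 - level) / 2
  a <- ncol(pca@scores)
  n <- nrow(pca@scores)
  nm <- rownames(pca@loadings)
  sc <- sweep(sweep(training[, nm, drop = FALSE], 2, pca@center), 2,
              pca@scale, `/`)
  S <- sc %*% pca@loadings
  s2 <- apply(pca@scores, 2, stats::var)
  t2 <- drop(sweep(S^2, 2, s2, `/`) %*% rep(1, a))
  resid <- sqrt(rowSums((sc - tcrossprod(S, pca@loadings))^2))
  pca@t2Limit <- unname(max(a * (n - 1) * (n + 1) / (n * (n - a)) *
                              stats::qf(1 - alpha, a, n - a),
                            stats::quantile(t2, 1 - alpha, type = 1)))
  pca@dmodLimit <- unname(stats::quantile(resid, 1 - alpha, type = 1))
  pca
}

#' Screen candidate structures against experimental retention
#'
#' A candidate is eliminated when, for any response in use, the absolute
#' difference between its predicted value and the experimental value of the
#' unknown exceeds the response's error window (typically the 95th
#' percentile of the validation residuals). The boundary is inclusive:
#' a deviation exactly equal to the window is retained. Out-of-domain
#' candidates are never eliminated on that ground alone but are flagged,
#' since higher errors must be expected for them.
#'
#' @param experimental named numeric vector: the measured retention
#'   values of the unknown, one per response.
#' @param candidates data.frame with a `candidate_id` column and one column
#'   per predicted response (same names as `experimental`).
#' @param windows named numeric vector of positive error half-widths per
#'   response.
#' @param in_domain optional logical vector aligned with `candidates`.
#' @return data.frame: `candidate_id`, per-response `within_<response>`
#'   flags, `in_domain`, `verdict` (`retained` / `eliminated`).
#' @export
filterCandidates <- function(experimental, candidates, windows,
                             in_domain = NULL) {
  shared <- intersect(names(experimental),
                      intersect(names(windows), names(candidates)))
  if (!length(shared)) stop("no shared response between unknown, candidates and windows")
  if (any(windows[shared] <= 0)) stop("windows must be positive")
  out <- data.frame(candidate_id = candidates$candidate_id,
                    stringsAsFactors = FALSE)
  ok <- rep(TRUE, nrow(candidates))
  for (r in shared) {
    within <- abs(candidates[[r]] - experimental[[r]]) <= windows[[r]]
    out[[paste0("within_", r)]] <- within
    ok <- ok & within
  }
  out$in_domain <- if (is.null(in_domain)) TRUE else in_domain
  out$verdict <- ifelse(ok, "retained", "eliminated")
  out
}
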