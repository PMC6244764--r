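#' @include AllClasses.R AllGenerics.R descriptors.R
NULL

## core NIPALS loop on an already autoscaled X, y. Returns weights/loadings/
## scores up to A components, stopping early when X or y is exhausted.
.nipals <- function(Xs, ys, A) {
  n <- nrow(Xs)
  K <- ncol(Xs)
  A <- min(A, K, n - 1L)
  W <- P <- matrix(0, K, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  E <- Xs
  f <- ys
  eps <- 1e-12 * max(1, sum(Xs^2))
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw^2 <= eps) break
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt <= eps) break
    p <- drop(crossprod(E, t_)) / tt
    qa <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p)
    f <- f - t_ * qa
    W <- cbind(W, w)
    P <- cbind(P, p)
    Tm <- cbind(Tm, t_)
    q <- c(q, qa)
  }
  if (ncol(W) < A)
    warning(sprintf("component count truncated to %d (rank limit)", ncol(W)))
  colnames(W) <- colnames(P) <- colnames(Tm) <- paste0("comp", seq_len(ncol(W)))
  rownames(W) <- rownames(P) <- colnames(Xs)
  list(W = W, P = P, q = q, T = Tm, A = ncol(W))
}

## scaled-space regression coefficients for the first `a` components
.plsCoef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a NIPALS PLS model
#'
#' Autoscales descriptors and response (sample SD) on the supplied rows,
#' runs the NIPALS algorithm for `A` components, and maps the regression
#' coefficients back to raw descriptor/response units so that predictions
#' come out in seconds or index units. At the full rank of `X` the model
#' coincides with ordinary least squares.
#'
#' @param X numeric matrix compounds x descriptors (raw units), complete.
#' @param y numeric response vector (raw units).
#' @param A number of PLS components; truncated with a warning when it
#'   exceeds the rank of `X`.
#' @param responseName,scope labels stored on the model.
#' @param cvRecord optional cross-validation record (from
#'   [selectComponents()]) stored for reporting.
#' @return a [PLSModel-class]
#' @export
fitPLS <- function(X, y, A, responseName = "response", scope = "global",
                   cvRecord = NULL) {
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed in PLS fit")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  sc <- autoscale(descriptorTable(.asIdMatrix(X)))
  Xs <- sc$table@values
  yc <- mean(y)
  ysd <- stats::sd(y)
  ys <- (y - yc) / ysd
  fit <- .nipals(Xs, ys, A)
  if (fit$A < A)
    warning(sprintf("component count truncated to %d (rank limit)", fit$A))
  bs <- .plsCoef(fit, fit$A)
  b <- bs * ysd / sc$params@scale
  intercept <- yc - sum(b * sc$params@center)
  model <- methods::new("PLSModel",
    weights = fit$W, loadings = fit$P, yloadings = fit$q, scores = fit$T,
    ncomp = fit$A, coefficients = stats::setNames(b, colnames(Xs)),
    intercept = intercept, xScaling = sc$params, yCenter = yc, yScale = ysd,
    vip = numeric(0), coefHalfWidth = numeric(0),
    cvRecord = if (is.null(cvRecord)) data.frame() else cvRecord,
    responseName = responseName, scope = scope)
  model@vip <- .vipScores(fit)
  model
}

.asIdMatrix <- function(X) {
  if (is.null(rownames(X))) rownames(X) <- paste0("r", seq_len(nrow(X)))
  X
}

#' Predict from a PLS model
#'
#' @param object a [PLSModel-class]
#' @param newdata numeric matrix (raw descriptor units) with named columns
#'   covering the model descriptors, or a [CompoundSet-class] /
#'   [DescriptorTable-class].
#' @param ... ignored
#' @return numeric vector of predictions in original response units
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is(newdata, "CompoundSet")) newdata <- newdata@descriptors@values
  if (is(newdata, "DescriptorTable")) newdata <- newdata@values
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  nm <- names(object@coefficients)
  missing <- setdiff(nm, colnames(newdata))
  if (length(missing))
    stop("missing descriptors: ", paste(utils::head(missing, 5), collapse = ", "))
  drop(object@intercept + newdata[, nm, drop = FALSE] %*% object@coefficients)
})

## VIP from a NIPALS fit: weights are unit vectors, SS_a = q_a^2 t_a't_a
.vipScores <- function(fit) {
  K <- nrow(fit$W)
  ss <- fit$q^2 * colSums(fit$T^2)
  w2 <- sweep(fit$W^2, 2, colSums(fit$W^2), `/`)
  stats::setNames(sqrt(K * drop(w2 %*% ss) / sum(ss)), rownames(fit$W))
}

#' @describeIn PLSModel VIP (variable importance on projection) per
#'   descriptor; the mean of the squared scores is 1 by construction.
#' @param object a PLSModel
#' @export
setMethod("vip", "PLSModel", function(object) object@vip)

## contiguous CV blocks of a seeded shuffle
.cvFolds <- function(n, n_groups, seed) {
  rng <- .seededRNG(seed)
  ord <- .withRNG(rng, sample.int(n))
  split(ord, cut(seq_len(n), n_groups, labels = FALSE))
}

#' Choose the PLS component count by cross-validation
#'
#' Seven-group cross-validation (contiguous blocks of a seeded shuffle of
#' the rows). Components are added while the incremental
#' `Q2 = 1 - PRESS/SS` gain, measured relative to the variance still
#' unexplained (`(Q2[a+1] - Q2[a]) / (1 - Q2[a])`, i.e. the fractional
#' PRESS reduction), exceeds `threshold` and Q2 stays positive; a response
#' that cannot beat the mean predictor yields `A = 1` with its
#' (non-positive) Q2 on record. The relative form keeps the rule meaningful
#' for retention responses whose span is orders of magnitude larger than
#' the measurement noise.
#'
#' @param X,y raw descriptor matrix and response, as in [fitPLS()].
#' @param n_groups number of cross-validation groups (default 7).
#' @param seed integer seed for the shuffle.
#' @param maxA largest component count examined (default
#'   `min(10, ncol(X), n - ceiling(n/n_groups) - 1)`).
#' @param threshold minimum Q2 increment to accept a further component
#'   (default 0.01).
#' @return list with `A` (chosen count) and `record`, a data.frame with
#'   one row per examined count: `ncomp`, `Q2`, `RMSE_CV` (response units,
#'   N-1 denominator).
#' @export
selectComponents <- function(X, y, n_groups = 7, seed = 1, maxA = NULL,
                             threshold = 0.01) {
  n <- nrow(X)
  if (n_groups > n) stop("more cross-validation groups than observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  if (is.null(maxA))
    maxA <- max(1L, min(10L, ncol(X), n - ceiling(n / n_groups) - 1L))
  folds <- .cvFolds(n, n_groups, seed)
  press <- matrix(0, length(folds), maxA)
  amax_seen <- maxA
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    Xtr <- X[-hold, , drop = FALSE]
    ytr <- y[-hold]
    keep <- apply(Xtr, 2, stats::sd) > 0
    Xtr <- Xtr[, keep, drop = FALSE]
    ctr <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    Xs <- sweep(sweep(Xtr, 2, ctr), 2, sdv, `/`)
    yc <- mean(ytr)
    ysd <- stats::sd(ytr)
    fit <- suppressWarnings(.nipals(Xs, (ytr - yc) / ysd, maxA))
    amax_seen <- min(amax_seen, fit$A)
    Xh <- sweep(sweep(X[hold, keep, drop = FALSE], 2, ctr), 2, sdv, `/`)
    for (a in seq_len(fit$A)) {
      pred <- yc + ysd * drop(Xh %*% .plsCoef(fit, a))
      press[i, a] <- sum((y[hold] - pred)^2)
    }
    if (fit$A < maxA)
      press[i, (fit$A + 1):maxA] <- press[i, fit$A]
  }
  ss <- sum((y - mean(y))^2)
  q2 <- 1 - colSums(press) / ss
  record <- data.frame(ncomp = seq_len(maxA), Q2 = q2,
                       RMSE_CV = sqrt(colSums(press) / (n - 1)))
  A <- 1L
  while (A < amax_seen &&
         (q2[A + 1] - q2[A]) / max(1 - q2[A], .Machine$double.eps) > threshold &&
         q2[A + 1] > 0) A <- A + 1L
  list(A = A, record = record)
}

#' Jackknife 95% half-widths for PLS coefficients
#'
#' Refits the model on each of the `n_groups` leave-one-group-out subsets
#' (the same contiguous-block construction as [selectComponents()]) and
#' converts the spread of the raw-unit coefficients into a 95% half-width:
#' `t[0.975, g-1] * sqrt((g-1)/g * sum((b_i - mean(b))^2))`.
#'
#' @param X,y raw descriptor matrix and response.
#' @param A component count.
#' @param n_groups number of jackknife groups (default 7).
#' @param seed integer seed for the shuffle.
#' @return named numeric vector of half-widths, one per descriptor (raw
#'   coefficient units); descriptors dropped in a subset (zero variance
#'   there) contribute a coefficient of 0 for that subset.
#' @export
coefficientUncertainty <- function(X, y, A, n_groups = 7, seed = 1) {
  n <- nrow(X)
  if (n_groups > n) stop("more jackknife groups than observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  folds <- .cvFolds(n, n_groups, seed)
  g <- length(folds)
  B <- matrix(0, g, ncol(X), dimnames = list(NULL, colnames(X)))
  for (i in seq_len(g)) {
    hold <- folds[[i]]
    Xtr <- X[-hold, , drop = FALSE]
    keep <- apply(Xtr, 2, stats::sd) > 0
    m <- suppressWarnings(fitPLS(Xtr[, keep, drop = FALSE], y[-hold], A))
    B[i, names(m@coefficients)] <- m@coefficients
  }
  bbar <- colMeans(B)
  se <- sqrt((g - 1) / g * colSums(sweep(B, 2, bbar)^2))
  stats::setNames(stats::qt(0.975, g - 1) * se, colnames(X))
}

#' Prune descriptors by uncertainty and/or importance
#'
#' Implements the model-simplification ladder: `"uncertainty"` drops every
#' descriptor whose jackknife 95% half-width exceeds the magnitude of its
#' coefficient; `"importance"` drops every descriptor with VIP below 1;
#' `"stepwise"` repeatedly removes the ten worst offenders (ranked by VIP
#' ascending, then uncertainty ratio descending) and refits, until every
#' surviving descriptor has VIP >= 1 and a half-width no larger than its
#' coefficient. The component count is re-selected by cross-validation
#' after every refit.
#'
#' @param X,y raw descriptor matrix and response.
#' @param strategy one of `"uncertainty"`, `"importance"`, `"stepwise"`.
#' @param n_groups,seed,threshold passed to [selectComponents()] /
#'   [coefficientUncertainty()].
#' @param responseName label stored on the refitted model.
#' @return list with `model` (refitted [PLSModel-class] on the surviving
#'   descriptors, half-widths populated), `kept`, `dropped` and `history`
#'   (data.frame of per-round descriptor counts).
#' @export
pruneDescriptors <- function(X, y, strategy = c("uncertainty", "importance",
                                                "stepwise"),
                             n_groups = 7, seed = 1, threshold = 0.01,
                             responseName = "response") {
  strategy <- match.arg(strategy)
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  refit <- function(Xk) {
    sel <- selectComponents(Xk, y, n_groups, seed, threshold = threshold)
    m <- suppressWarnings(fitPLS(Xk, y, sel$A, responseName = responseName,
                                 cvRecord = sel$record))
    m@coefHalfWidth <- coefficientUncertainty(Xk, y, m@ncomp, n_groups, seed)
    m
  }
  model <- refit(X)
  history <- data.frame(round = 0L, n_descriptors = ncol(X),
                        ncomp = model@ncomp)
  offenders <- function(m) {
    v <- m@vip[names(m@coefficients)]
    hw <- m@coefHalfWidth[names(m@coefficients)]
    ratio <- hw / pmax(abs(m@coefficients), .Machine$double.eps)
    switch(strategy,
      uncertainty = names(which(ratio > 1)),
      importance = names(which(v < 1)),
      stepwise = {
        bad <- names(which(v < 1 | ratio > 1))
        bad[order(v[bad], -ratio[bad])]
      })
  }
  kept <- colnames(X)
  round <- 0L
  repeat {
    bad <- offenders(model)
    if (!length(bad)) break
    if (strategy == "stepwise") bad <- utils::head(bad, 10L)
    if (length(bad) >= length(kept)) {
      warning("pruning would remove every descriptor; keeping last non-empty model")
      break
    }
    kept <- setdiff(kept, bad)
    model <- refit(X[, kept, drop = FALSE])
    round <- round + 1L
    history <- rbind(history, data.frame(round = round,
                                         n_descriptors = length(kept),
                                         ncomp = model@ncomp))
    if (strategy != "stepwise") break
  }
  list(model = model, kept = kept, dropped = setdiff(colnames(X), kept),
       history = history)
}

#' Fit per-group local PLS models alongside a global model
#'
#' Compounds are labelled 1 = fluorinated, 2 = chlorinated/brominated,
#' 3 = long carbon-chain homologues, 4 = remainder. A group gets its own
#' local PLS model when it has at least `max(10, 2 * n_groups)` training
#' members; smaller groups fall back to the global model and are flagged.
#'
#' @param cs a [CompoundSet-class] with `set` assignments and `group`
#'   labels in its info table.
#' @param response response name (column of `responses(cs)`).
#' @param n_groups,seed,threshold cross-validation settings, as in
#'   [selectComponents()].
#' @return list with `global` ([PLSModel-class]), `groups` (named list of
#'   group models, `NULL` where the group fell back), and `fallback`
#'   (character vector of group labels that fell back).
#' @export
fitGroupModels <- function(cs, response, n_groups = 7, seed = 1,
                           threshold = 0.01) {
  info <- cs@info
  tr <- which(info$set == "training")
  if (!length(tr)) stop("no training compounds")
  X <- cs@descriptors@values
  y <- cs@responses[[response]]
  fitOne <- function(rows, scope) {
    Xr <- X[rows, , drop = FALSE]
    keep <- apply(Xr, 2, stats::sd) > 0
    Xr <- Xr[, keep, drop = FALSE]
    sel <- selectComponents(Xr, y[rows], n_groups, seed,
                            threshold = threshold)
    suppressWarnings(fitPLS(Xr, y[rows], sel$A, responseName = response,
                            scope = scope, cvRecord = sel$record))
  }
  global <- fitOne(tr, "global")
  minSize <- max(10, 2 * n_groups)
  groups <- list()
  fallback <- character(0)
  for (gl in sort(unique(stats::na.omit(info$group)))) {
    rows <- tr[!is.na(info$group[tr]) & info$group[tr] == gl]
    key <- paste0("group_", gl)
    if (length(rows) >= minSize) {
      groups[[key]] <- fitOne(rows, key)
    } else {
      groups[key] <- list(NULL)
      fallback <- c(fallback, key)
    }
  }
  list(global = global, groups = groups, fallback = fallback)
}

#' Predict with group dispatch
#'
#' Each compound is predicted by its group's local model when one exists;
#' unlabeled compounds and groups without a local model use the global
#' model and are flagged.
#'
#' @param models result of [fitGroupModels()]
#' @param cs a [CompoundSet-class]
#' @return data.frame `compound_id`, `predicted`, `model` (scope used),
#'   `flagged` (TRUE when the global fallback was used).
#' @export
predictGrouped <- function(models, cs) {
  info <- cs@info
  X <- cs@descriptors@values
  pred <- numeric(nrow(info))
  used <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    key <- if (is.na(info$group[i])) NA_character_
           else paste0("group_", info$group[i])
    m <- if (!is.na(key) && !is.null(models$groups[[key]]))
           models$groups[[key]] else models$global
    pred[i] <- predict(m, X[i, , drop = FALSE])
    used[i] <- m@scope
  }
  ## local dispatch is always preferred, so any global use is a fallback
  data.frame(compound_id = info$compound_id, predicted = pred,
             model = used, flagged = used == "global",
             stringsAsFactors = FALSE)
}
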