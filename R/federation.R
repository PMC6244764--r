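#' @include AllClasses.R descriptors.R
NULL

#' Build a knowledge base for federated prediction
#'
#' Stores the "similarity properties" (a designated subset of the
#' descriptors) autoscaled over all entries, alongside the known responses.
#'
#' @param cs a [CompoundSet-class]
#' @param properties character names of descriptor columns used as
#'   similarity properties; default all descriptors.
#' @param responses character names of response columns carried; default all.
#' @param abraham character names of the properties that are Abraham
#'   solvation parameters (default: those among `E`, `S`, `A`, `B`, `L`
#'   present in `properties`), honoured by the `no_abraham` /
#'   `abraham_only` selectors.
#' @param rows optional subset of rows (ids, logical or integer index).
#' @return a [KnowledgeBase-class]
#' @export
buildKnowledgeBase <- function(cs, properties = NULL, responses = NULL,
                               abraham = NULL, rows = NULL) {
  stopifnot(is(cs, "CompoundSet"))
  v <- cs@descriptors@values
  idx <- .resolveRows(rows, v)
  if (is.null(properties)) properties <- colnames(v)
  if (is.null(responses)) responses <- names(cs@responses)
  if (is.null(abraham))
    abraham <- intersect(c("E", "S", "A", "B", "L"), properties)
  sc <- autoscale(descriptorTable(v[idx, properties, drop = FALSE]))
  methods::new("KnowledgeBase",
    ids = cs@info$compound_id[idx],
    properties = sc$table@values,
    responses = cs@responses[idx, responses, drop = FALSE],
    scaling = sc$params,
    abraham = intersect(abraham, colnames(sc$table@values)))
}

## property columns active under a FederationConfig selector
.activeProperties <- function(kb, config) {
  all <- colnames(kb@properties)
  switch(config@propertySet,
         all = all,
         no_abraham = setdiff(all, kb@abraham),
         abraham_only = intersect(all, kb@abraham))
}

#' Similarity between two property vectors
#'
#' Both metrics live on \[0, 1\] and reach 1 only for identical vectors
#' (for dice: identical non-zero vectors). The continuous dice coefficient
#' `2 sum(a b) / (sum(a^2) + sum(b^2))` is computed on vectors already
#' rescaled to be non-negative (see [selectNeighbors()], which min-max
#' rescales the knowledge-base property space); the Euclidean similarity is
#' `1 / (1 + d(a, b))`.
#'
#' @param a,b numeric property vectors of equal length.
#' @param metric `"dice"` or `"euclidean"`.
#' @return similarity score in \[0, 1\]
#' @export
similarity <- function(a, b, metric = c("dice", "euclidean")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("property vectors differ in length")
  if (metric == "dice") {
    den <- sum(a^2) + sum(b^2)
    if (den == 0) return(0)
    2 * sum(a * b) / den
  } else {
    1 / (1 + sqrt(sum((a - b)^2)))
  }
}

## min-max rescale the kb property space (and the query with the same
## parameters) to non-negative values so the continuous dice is meaningful
.minmaxParams <- function(P) {
  lo <- apply(P, 2, min)
  hi <- apply(P, 2, max)
  rg <- hi - lo
  rg[rg == 0] <- 1
  list(lo = lo, rg = rg)
}

.minmaxApply <- function(x, mm) {
  z <- sweep(sweep(x, 2, mm$lo), 2, mm$rg, `/`)
  pmin(pmax(z, 0), 1)
}

#' Select the most similar knowledge-base entries
#'
#' Ranks the entries by similarity to the query and returns the top `k`;
#' ties are broken by lexicographic compound id. In leave-one-out
#' evaluation the query's own entry (matched by `query_id`) is excluded
#' unless `include_self = TRUE`.
#'
#' @param kb a [KnowledgeBase-class]
#' @param query numeric named vector of raw property values (unscaled) or a
#'   1-row matrix; scaled internally with the knowledge-base parameters.
#' @param config a [FederationConfig-class]
#' @param query_id optional id identifying the query inside the knowledge
#'   base (for leave-one-out).
#' @param include_self keep the query's own entry among the candidates
#'   (default FALSE when `query_id` is given).
#' @return data.frame `compound_id`, `similarity`, most similar first, `k`
#'   rows.
#' @export
selectNeighbors <- function(kb, query, config, query_id = NULL,
                            include_self = FALSE) {
  props <- .activeProperties(kb, config)
  if (!length(props)) stop("no properties active under this configuration")
  P <- kb@properties[, props, drop = FALSE]
  q <- applyScaling(query, kb@scaling)[, props, drop = FALSE]
  ids <- kb@ids
  keep <- rep(TRUE, length(ids))
  if (!is.null(query_id) && !include_self) keep <- ids != query_id
  P <- P[keep, , drop = FALSE]
  ids <- ids[keep]
  if (config@k > length(ids))
    stop("knowledge base smaller than the requested neighbourhood")
  if (config@metric == "dice") {
    mm <- .minmaxParams(P)
    Pn <- .minmaxApply(P, mm)
    qn <- drop(.minmaxApply(q, mm))
    den <- rowSums(Pn^2) + sum(qn^2)
    sim <- ifelse(den == 0, 0, 2 * drop(Pn %*% qn) / den)
  } else {
    d <- sqrt(rowSums(sweep(P, 2, drop(q))^2))
    sim <- 1 / (1 + d)
  }
  ord <- order(-sim, ids)
  top <- ord[seq_len(config@k)]
  data.frame(compound_id = ids[top], similarity = sim[top],
             stringsAsFactors = FALSE)
}

#' Federated local-model prediction
#'
#' Selects the `k` most similar knowledge-base entries and fits a small
#' least-squares regression on just those neighbours: properties enter by
#' forward stepwise selection (largest residual-sum-of-squares reduction
#' first), capped at `floor(k/m)` parameters by the compounds-per-parameter
#' rule and stopped early when the relative RSS reduction falls below 1%.
#' The intercept is always included and not counted as a parameter.
#' First-dimension retention times are handled in minutes internally and
#' returned in seconds (a pure unit relabelling that mirrors how such
#' knowledge bases are typically imported).
#'
#' @param kb a [KnowledgeBase-class]
#' @param query raw named property vector (or 1-row matrix).
#' @param config a [FederationConfig-class]
#' @param response response column of the knowledge base to predict.
#' @param query_id,include_self leave-one-out controls, see
#'   [selectNeighbors()].
#' @return a [LocalPrediction-class]
#' @export
predictFederated <- function(kb, query, config, response,
                             query_id = NULL, include_self = FALSE) {
  if (!response %in% names(kb@responses))
    stop("unknown response: ", response)
  nb <- selectNeighbors(kb, query, config, query_id, include_self)
  rows <- match(nb$compound_id, kb@ids)
  yv <- kb@responses[[response]][rows]
  toMin <- response == "t1R"
  if (toMin) yv <- yv / 60
  props <- .activeProperties(kb, config)
  P <- kb@properties[rows, props, drop = FALSE]
  q <- drop(applyScaling(query, kb@scaling)[, props, drop = FALSE])
  p_max <- floor(config@k / config@m)
  usable <- props[apply(P, 2, function(x) stats::sd(x) > 0)]
  flag <- ""
  if (!length(usable)) {
    pred <- mean(yv)
    sel <- character(0)
    rss <- sum((yv - pred)^2)
    flag <- "constant_properties"
  } else {
    sel <- character(0)
    resid <- yv - mean(yv)
    rss <- sum(resid^2)
    design <- matrix(1, nrow(P), 1)
    while (length(sel) < p_max && rss > 0) {
      cand <- setdiff(usable, sel)
      if (!length(cand)) break
      best <- NULL
      bestRss <- rss
      for (cn in cand) {
        Xc <- cbind(design, P[, cn])
        fit <- tryCatch(stats::lm.fit(Xc, yv), error = function(e) NULL)
        if (is.null(fit) || anyNA(fit$coefficients)) next
        r <- sum(fit$residuals^2)
        if (r < bestRss) {
          bestRss <- r
          best <- cn
        }
      }
      if (is.null(best)) break
      if (rss > 0 && (rss - bestRss) / rss < 0.01) break
      sel <- c(sel, best)
      design <- cbind(design, P[, best])
      rss <- bestRss
    }
    fit <- stats::lm.fit(design, yv)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- sum(beta * c(1, q[sel]))
    rss <- sum(fit$residuals^2)
  }
  if (toMin) {
    pred <- pred * 60
    rss <- rss * 3600
  }
  methods::new("LocalPrediction", predicted = pred, neighbors = nb,
               parameters = sel,
               localRMSE = sqrt(rss / length(yv)), flag = flag)
}

#' Leave-one-out federated evaluation over a knowledge base
#'
#' Predicts every entry of the knowledge base from its own neighbours
#' (self excluded) -- the standard way to estimate the federated
#' predictor's error without an external hold-out.
#'
#' @param kb a [KnowledgeBase-class]
#' @param config a [FederationConfig-class]
#' @param response response column to predict.
#' @param raw matrix of raw (unscaled) property values aligned with the
#'   knowledge base (needed because the stored properties are scaled);
#'   typically `descriptorValues(cs)[ids, properties]`.
#' @return data.frame `compound_id`, `observed`, `predicted`
#' @export
looFederated <- function(kb, config, response, raw) {
  ids <- kb@ids
  preds <- vapply(seq_along(ids), function(i) {
    predictFederated(kb, raw[i, , drop = FALSE], config, response,
                     query_id = ids[i])@predicted
  }, numeric(1))
  data.frame(compound_id = ids, observed = kb@responses[[response]],
             predicted = preds, stringsAsFactors = FALSE)
}
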