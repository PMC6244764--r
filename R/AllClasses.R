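#' Reference-standard series for retention indexing
#'
#' Holds the n-alkane series used for first-dimension linear retention
#' indices (LRI), the polyethylene-glycol (PEG) series used for the
#' second-dimension index, and optionally the alkane second-dimension
#' retention times that define the non-polar baseline of the GCxGC plane.
#'
#' @slot alkanes data.frame with columns `carbon` (integer carbon number)
#'   and `t1` (first-dimension retention time, seconds), strictly increasing
#'   in both.
#' @slot pegs data.frame with columns `eo` (ethylene-oxide unit count),
#'   `t1` and `t2` (seconds); `t1` strictly increasing with `eo`. May have
#'   zero rows when only first-dimension indexing is needed.
#' @slot alkane2d data.frame with columns `t1`, `t2` (seconds) giving the
#'   measured second-dimension times of the alkanes; may have zero rows, in
#'   which case a flat baseline at the minimum observed reference `t2` is
#'   used.
#'
#' @seealso [referenceSeries()], [computeLRI()], [fitReferenceLines()]
#' @export
setClass("ReferenceSeries",
  representation(alkanes = "data.frame", pegs = "data.frame",
                 alkane2d = "data.frame"))

setValidity("ReferenceSeries", function(object) {
  msg <- character(0)
  a <- object@alkanes
  if (!all(c("carbon", "t1") %in% names(a)))
    msg <- c(msg, "alkanes must have columns 'carbon' and 't1'")
  else {
    if (nrow(a) < 2)
      msg <- c(msg, "invalid reference series: fewer than 2 alkanes")
    if (nrow(a) >= 2) {
      if (any(diff(a$carbon) <= 0))
        msg <- c(msg, "invalid reference series: alkane carbon numbers not strictly increasing")
      if (any(diff(a$t1) <= 0))
        msg <- c(msg, "invalid reference series: alkane t1 not strictly increasing")
    }
  }
  p <- object@pegs
  if (nrow(p) > 0) {
    if (!all(c("eo", "t1", "t2") %in% names(p)))
      msg <- c(msg, "pegs must have columns 'eo', 't1' and 't2'")
    else {
      if (nrow(p) == 1)
        msg <- c(msg, "invalid reference series: a single PEG is under-determined")
      if (nrow(p) >= 2 && any(diff(p$t1[order(p$eo)]) <= 0))
        msg <- c(msg, "invalid reference series: PEG t1 not strictly increasing with eo units")
    }
  }
  b <- object@alkane2d
  if (nrow(b) > 0 && !all(c("t1", "t2") %in% names(b)))
    msg <- c(msg, "alkane2d must have columns 't1' and 't2'")
  if (length(msg)) msg else TRUE
})

#' Descriptor matrix with provenance metadata
#'
#' A compounds-by-descriptors numeric matrix together with per-descriptor
#' metadata recording whether a column is a base descriptor, a
#' weight-normalised variant, or a linearising transformation of another
#' column.
#'
#' @slot values numeric matrix, rows = compounds (rownames are compound
#'   identifiers), columns = descriptors.
#' @slot meta data.frame with one row per descriptor: `name`, `source`
#'   (one of `base`, `weight_normalized`, `transformed`), `transform`
#'   (one of `none`, `log10_shift`, `sqrt`, `reciprocal`, `square`) and
#'   `parent` (name of the parent descriptor, `NA` for base columns).
#'
#' @seealso [descriptorTable()], [augmentWeightNormalized()],
#'   [applyManualTransformations()], [autoscale()]
#' @export
setClass("DescriptorTable",
  representation(values = "matrix", meta = "data.frame"))

setValidity("DescriptorTable", function(object) {
  msg <- character(0)
  v <- object@values
  m <- object@meta
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (is.null(rownames(v))) msg <- c(msg, "'values' must carry compound ids as rownames")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate descriptor names")
  cn <- colnames(v)
  if (is.null(cn)) cn <- character(0)
  if (!identical(cn, m$name))
    msg <- c(msg, "meta rows must align with value columns")
  if (!all(m$source %in% c("base", "weight_normalized", "transformed")))
    msg <- c(msg, "unknown descriptor source")
  tr <- m$source == "transformed"
  if (any(tr) && !all(m$parent[tr] %in% m$name))
    msg <- c(msg, "transformed descriptors must reference an existing parent")
  if (length(msg)) msg else TRUE
})

#' Centering/scaling parameters learned on a training subset
#'
#' @slot center named numeric vector of per-descriptor training means.
#' @slot scale named numeric vector of per-descriptor training standard
#'   deviations (sample convention, N-1 denominator).
#' @slot dropped character vector of descriptor names dropped because they
#'   had zero variance over the fitting rows.
#'
#' @seealso [autoscale()], [applyScaling()], [revertScaling()]
#' @export
setClass("ScalingParams",
  representation(center = "numeric", scale = "numeric", dropped = "character"))

setValidity("ScalingParams", function(object) {
  msg <- character(0)
  if (!identical(names(object@center), names(object@scale)))
    msg <- c(msg, "center and scale must be aligned")
  if (any(object@scale <= 0))
    msg <- c(msg, "retained descriptors must have positive SD")
  if (length(msg)) msg else TRUE
})

#' Principal component analysis model
#'
#' PCA of the centered/unit-variance descriptor matrix via singular value
#' decomposition, with a deterministic sign convention (the
#' largest-magnitude loading of each component is made positive).
#'
#' @slot loadings descriptors x components orthonormal matrix.
#' @slot scores compounds x components score matrix.
#' @slot explained fraction of total variance explained per component
#'   (non-increasing).
#' @slot center,scale named numeric vectors used to autoscale the input.
#' @slot dmodLimit,t2Limit residual distance-to-model and Hotelling
#'   T-squared limits set by [calibrateDomain()]; length 0 until calibrated.
#'
#' @seealso [runPCA()], [projectPCA()], [applicabilityDomain()]
#' @export
setClass("PCAModel",
  representation(loadings = "matrix", scores = "matrix",
                 explained = "numeric", center = "numeric", scale = "numeric",
                 dmodLimit = "numeric", t2Limit = "numeric"),
  prototype(dmodLimit = numeric(0), t2Limit = numeric(0)))

setValidity("PCAModel", function(object) {
  msg <- character(0)
  if (ncol(object@loadings) != ncol(object@scores))
    msg <- c(msg, "loadings and scores disagree on component count")
  if (length(object@explained) != ncol(object@loadings))
    msg <- c(msg, "one explained-variance fraction per component required")
  if (length(object@explained) > 1 && any(diff(object@explained) > 1e-8))
    msg <- c(msg, "explained variance must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Training/test/external-validation split of a compound set
#'
#' @slot assignment data.frame with columns `compound_id`, `set` (one of
#'   `training`, `test`, `external_validation`) and `provenance` (one of
#'   `pcb_rule`, `component_1` .. `component_4`, `random_remainder`).
#'
#' @seealso [systematicSplit()], [coverageCheck()]
#' @export
setClass("SplitAssignment",
  representation(assignment = "data.frame"))

setValidity("SplitAssignment", function(object) {
  msg <- character(0)
  a <- object@assignment
  if (!all(c("compound_id", "set", "provenance") %in% names(a)))
    msg <- c(msg, "assignment needs compound_id, set, provenance")
  else {
    if (anyDuplicated(a$compound_id))
      msg <- c(msg, "a compound may belong to one set only")
    if (!all(a$set %in% c("training", "test", "external_validation")))
      msg <- c(msg, "unknown set label")
  }
  if (length(msg)) msg else TRUE
})

#' NIPALS partial least squares regression model
#'
#' A PLS1 model fitted by the NIPALS algorithm on an autoscaled descriptor
#' matrix and response, carrying everything needed to predict new compounds
#' in original units and to diagnose the model: weights, loadings, scores,
#' regression coefficients mapped back to raw descriptor space, VIP scores,
#' jackknife 95% coefficient half-widths and the cross-validation record
#' used to choose the component count.
#'
#' @slot weights descriptors x components NIPALS weight matrix W.
#' @slot loadings descriptors x components X-loading matrix P.
#' @slot yloadings numeric vector of response loadings q (one per component).
#' @slot scores training scores T (compounds x components).
#' @slot ncomp number of components A.
#' @slot coefficients named numeric vector of regression coefficients in raw
#'   descriptor units.
#' @slot intercept numeric intercept in raw response units.
#' @slot xScaling,yCenter,yScale scaling parameters for descriptors and
#'   response.
#' @slot vip named numeric VIP per descriptor (mean of VIP^2 is 1).
#' @slot coefHalfWidth named numeric 95% jackknife half-width per descriptor
#'   (length 0 until [coefficientUncertainty()] is run).
#' @slot cvRecord data.frame with one row per candidate component count:
#'   `ncomp`, `Q2`, `RMSE_CV` (empty when A was fixed by the caller).
#' @slot responseName one of `t1R`, `LRI`, `t2R`, `PEG2I` (or any label).
#' @slot scope `global` or `group_1` .. `group_4`.
#'
#' @seealso [fitPLS()], [selectComponents()], [vip()],
#'   [coefficientUncertainty()], [pruneDescriptors()], [fitGroupModels()]
#' @export
setClass("PLSModel",
  representation(weights = "matrix", loadings = "matrix",
                 yloadings = "numeric", scores = "matrix", ncomp = "numeric",
                 coefficients = "numeric", intercept = "numeric",
                 xScaling = "ScalingParams", yCenter = "numeric",
                 yScale = "numeric", vip = "numeric",
                 coefHalfWidth = "numeric", cvRecord = "data.frame",
                 responseName = "character", scope = "character"))

setValidity("PLSModel", function(object) {
  msg <- character(0)
  if (object@ncomp < 1) msg <- c(msg, "at least one component required")
  if (ncol(object@weights) != object@ncomp)
    msg <- c(msg, "weight matrix must have ncomp columns")
  if (length(object@vip)) {
    k <- length(object@vip)
    if (abs(sum(object@vip^2) - k) > 1e-6 * k)
      msg <- c(msg, "VIP normalisation violated (sum of VIP^2 must equal K)")
  }
  if (length(msg)) msg else TRUE
})

#' Knowledge base for the federation-of-local-models predictor
#'
#' @slot ids character compound identifiers.
#' @slot properties compounds x properties matrix, autoscaled with the
#'   stored parameters ("similarity properties").
#' @slot responses data.frame of response values per entry (columns are
#'   response names), aligned with `ids`.
#' @slot scaling [ScalingParams-class] used to scale the property space.
#' @slot abraham character vector naming which property columns are Abraham
#'   solvation parameters (used by the `abraham_only` / `no_abraham`
#'   property-set selectors).
#'
#' @seealso [buildKnowledgeBase()], [selectNeighbors()], [predictFederated()]
#' @export
setClass("KnowledgeBase",
  representation(ids = "character", properties = "matrix",
                 responses = "data.frame", scaling = "ScalingParams",
                 abraham = "character"))

setValidity("KnowledgeBase", function(object) {
  msg <- character(0)
  if (nrow(object@properties) != length(object@ids))
    msg <- c(msg, "property matrix rows must match ids")
  if (nrow(object@responses) != length(object@ids))
    msg <- c(msg, "response rows must match ids")
  if (anyNA(object@properties))
    msg <- c(msg, "property vectors must be complete")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate knowledge-base ids")
  if (length(msg)) msg else TRUE
})

#' Settings for the federation-of-local-models predictor
#'
#' @slot metric similarity metric, `dice` or `euclidean`.
#' @slot k number of nearest knowledge-base neighbours used for the local
#'   model (20 or 25 in typical use).
#' @slot m compounds-per-parameter rule: the local regression may use at
#'   most `floor(k / m)` properties (3 or 4 in typical use).
#' @slot propertySet `all`, `no_abraham` or `abraham_only`.
#'
#' @seealso [federationConfig()], [predictFederated()]
#' @export
setClass("FederationConfig",
  representation(metric = "character", k = "numeric", m = "numeric",
                 propertySet = "character"))

setValidity("FederationConfig", function(object) {
  msg <- character(0)
  if (!object@metric %in% c("dice", "euclidean"))
    msg <- c(msg, "metric must be 'dice' or 'euclidean'")
  if (!object@propertySet %in% c("all", "no_abraham", "abraham_only"))
    msg <- c(msg, "unknown property-set selector")
  if (object@k < 2 * object@m)
    msg <- c(msg, "k must be at least 2*m (a 2-parameter local model must be possible)")
  if (length(msg)) msg else TRUE
})

#' One federated local prediction
#'
#' @slot predicted predicted response value (original units).
#' @slot neighbors data.frame `compound_id`, `similarity` of the k selected
#'   knowledge-base entries, most similar first.
#' @slot parameters character names of the properties selected into the
#'   local regression.
#' @slot localRMSE root-mean-square residual of the local fit over the
#'   neighbours.
#' @slot flag character, e.g. `constant_properties` when all properties were
#'   constant among the neighbours and the neighbour mean was returned.
#'
#' @seealso [predictFederated()]
#' @export
setClass("LocalPrediction",
  representation(predicted = "numeric", neighbors = "data.frame",
                 parameters = "character", localRMSE = "numeric",
                 flag = "character"))

#' Prediction-quality report
#'
#' @slot n number of compound predictions evaluated.
#' @slot rmsep root-mean-square error of prediction with the N-1
#'   denominator convention used throughout this package.
#' @slot avgDev mean absolute residual.
#' @slot avgRelDev mean of |residual| / observed (fraction); observations
#'   equal to zero are skipped and counted in `relSkipped`.
#' @slot p95 95th percentile of the absolute residuals (linear interpolation
#'   between order statistics).
#' @slot residuals numeric vector observed - predicted.
#' @slot relSkipped number of points skipped in the relative deviation.
#' @slot response,set labels for reporting.
#'
#' @seealso [evaluatePredictions()]
#' @export
setClass("EvaluationReport",
  representation(n = "numeric", rmsep = "numeric", avgDev = "numeric",
                 avgRelDev = "numeric", p95 = "numeric",
                 residuals = "numeric", relSkipped = "numeric",
                 response = "character", set = "character"))

setValidity("EvaluationReport", function(object) {
  msg <- character(0)
  if (object@rmsep < 0) msg <- c(msg, "RMSE_P must be non-negative")
  if (object@n != length(object@residuals))
    msg <- c(msg, "n must match the residual count")
  if (length(object@residuals) >= 2 &&
      object@p95 < stats::median(abs(object@residuals)) - 1e-12)
    msg <- c(msg, "95th percentile below the median absolute residual")
  if (length(msg)) msg else TRUE
})

#' A set of compounds with responses and descriptors
#'
#' The central container: per-compound annotation (identifier, name,
#' optional structure string, compound group, optional PCB chlorination
#' level, optional set assignment), the measured responses, and the
#' descriptor matrix.
#'
#' @slot info data.frame with columns `compound_id`, `name`, `smiles`,
#'   `group` (integer 1-4 or NA), `pcb_chlorine` (chlorination level for
#'   PCBs, NA otherwise) and `set` (split assignment or NA).
#' @slot responses data.frame with any subset of columns `t1R`, `t2R`
#'   (seconds), `LRI`, `PEG2I` (index units), aligned with `info`.
#' @slot descriptors [DescriptorTable-class] aligned with `info`.
#'
#' @seealso [compoundSet()], [generateDataset()], [readCompoundTable()]
#' @export
setClass("CompoundSet",
  representation(info = "data.frame", responses = "data.frame",
                 descriptors = "DescriptorTable"))

setValidity("CompoundSet", function(object) {
  msg <- character(0)
  ids <- object@info$compound_id
  if (is.null(ids)) return("info must have a compound_id column")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate compound ids")
  if (nrow(object@responses) != nrow(object@info))
    msg <- c(msg, "responses must align with info")
  if (nrow(object@descriptors@values) != nrow(object@info))
    msg <- c(msg, "descriptor rows must align with info")
  num <- vapply(object@responses, is.numeric, logical(1))
  if (length(num) && !all(num)) msg <- c(msg, "responses must be numeric")
  for (cn in intersect(names(object@responses), c("t1R", "t2R"))) {
    x <- object@responses[[cn]]
    if (any(!is.na(x) & x < 0))
      msg <- c(msg, sprintf("response %s contains negative retention times", cn))
  }
  if (length(msg)) msg else TRUE
})
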