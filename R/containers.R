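#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a reference-standard series
#'
#' @param alkanes data.frame with columns `carbon`, `t1` (seconds).
#' @param pegs data.frame with columns `eo`, `t1`, `t2`; may be omitted when
#'   only first-dimension indexing is needed.
#' @param alkane2d optional data.frame with columns `t1`, `t2` giving the
#'   alkane second-dimension times (the non-polar baseline).
#' @return a [ReferenceSeries-class]
#' @examples
#' rs <- referenceSeries(data.frame(carbon = c(10, 11), t1 = c(1200, 1500)))
#' computeLRI(1350, rs)
#' @export
referenceSeries <- function(alkanes,
                            pegs = data.frame(eo = numeric(0),
                                              t1 = numeric(0),
                                              t2 = numeric(0)),
                            alkane2d = data.frame(t1 = numeric(0),
                                                  t2 = numeric(0))) {
  alkanes <- alkanes[order(alkanes$carbon), , drop = FALSE]
  if (nrow(pegs)) pegs <- pegs[order(pegs$eo), , drop = FALSE]
  methods::new("ReferenceSeries", alkanes = alkanes, pegs = pegs,
               alkane2d = alkane2d)
}

#' Construct a descriptor table
#'
#' @param values numeric matrix compounds x descriptors; rownames are
#'   compound ids, colnames are descriptor names.
#' @param meta optional metadata data.frame (`name`, `source`, `transform`,
#'   `parent`); by default every column is a base descriptor.
#' @return a [DescriptorTable-class]
#' @export
descriptorTable <- function(values, meta = NULL) {
  if (is.null(meta)) {
    nm <- colnames(values)
    if (is.null(nm)) nm <- character(0)
    meta <- data.frame(name = nm,
                       source = rep("base", length(nm)),
                       transform = rep("none", length(nm)),
                       parent = rep(NA_character_, length(nm)),
                       stringsAsFactors = FALSE)
  }
  methods::new("DescriptorTable", values = values, meta = meta)
}

#' Construct a compound set
#'
#' @param info data.frame of per-compound annotation; must contain
#'   `compound_id`. Missing annotation columns are filled with NA.
#' @param responses data.frame of responses (`t1R`, `t2R`, `LRI`, `PEG2I`,
#'   any subset), aligned with `info`.
#' @param descriptors a [DescriptorTable-class] aligned with `info`.
#' @return a [CompoundSet-class]
#' @export
compoundSet <- function(info, responses, descriptors) {
  for (cn in c("name", "smiles"))
    if (is.null(info[[cn]])) info[[cn]] <- NA_character_
  for (cn in c("group", "pcb_chlorine"))
    if (is.null(info[[cn]])) info[[cn]] <- NA_integer_
  if (is.null(info$set)) info$set <- NA_character_
  methods::new("CompoundSet", info = info, responses = responses,
               descriptors = descriptors)
}

#' Construct federation settings
#'
#' @param metric similarity metric, `"dice"` or `"euclidean"`.
#' @param k neighbourhood size (default 25).
#' @param m compounds per local-model parameter (default 4); the local
#'   regression uses at most `floor(k/m)` properties.
#' @param propertySet `"all"`, `"no_abraham"` or `"abraham_only"`.
#' @return a [FederationConfig-class]
#' @export
federationConfig <- function(metric = c("dice", "euclidean"), k = 25, m = 4,
                             propertySet = c("all", "no_abraham",
                                             "abraham_only")) {
  methods::new("FederationConfig", metric = match.arg(metric), k = k, m = m,
               propertySet = match.arg(propertySet))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn DescriptorTable compound identifiers
#' @param x a DescriptorTable
#' @aliases compoundIds,DescriptorTable-method
#' @export
setMethod("compoundIds", "DescriptorTable", function(x) rownames(x@values))

#' @describeIn DescriptorTable descriptor names
#' @export
setMethod("descriptorNames", "DescriptorTable", function(x) colnames(x@values))

#' @describeIn DescriptorTable value matrix
#' @export
setMethod("descriptorValues", "DescriptorTable", function(x) x@values)

#' @describeIn DescriptorTable provenance metadata
#' @export
setMethod("descriptorMeta", "DescriptorTable", function(x) x@meta)

#' @describeIn CompoundSet compound identifiers
#' @param x a CompoundSet
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@info$compound_id)

#' @describeIn CompoundSet descriptor names
#' @export
setMethod("descriptorNames", "CompoundSet",
          function(x) colnames(x@descriptors@values))

#' @describeIn CompoundSet descriptor value matrix
#' @export
setMethod("descriptorValues", "CompoundSet",
          function(x) x@descriptors@values)

#' @describeIn CompoundSet descriptor metadata
#' @export
setMethod("descriptorMeta", "CompoundSet", function(x) x@descriptors@meta)

#' @describeIn CompoundSet response table
#' @export
setMethod("responses", "CompoundSet", function(x) x@responses)

#' @describeIn CompoundSet per-compound annotation
#' @export
setMethod("compoundInfo", "CompoundSet", function(x) x@info)

#' @describeIn SplitAssignment the assignment table
#' @param x a SplitAssignment
#' @export
setMethod("assignmentTable", "SplitAssignment", function(x) x@assignment)

#' Subset operators
#'
#' `x[i, j]` subsets a [DescriptorTable-class] by compounds/descriptors and
#' `x[i]` a [CompoundSet-class] by compounds; the class is always kept
#' (`drop` is ignored). A transformed descriptor that loses its parent in a
#' column subset is demoted to a base descriptor.
#'
#' @param x a DescriptorTable or CompoundSet
#' @param i row (compound) index
#' @param j column (descriptor) index, DescriptorTable only
#' @param ... ignored
#' @param drop ignored
#' @return an object of the same class
#' @name subset-methods
#' @aliases [,DescriptorTable-method [,CompoundSet-method
#' @exportMethod "["
NULL

setMethod("[", signature(x = "DescriptorTable", i = "ANY", j = "ANY",
                         drop = "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  v <- v[i, j, drop = FALSE]
  m <- x@meta[match(colnames(v), x@meta$name), , drop = FALSE]
  rownames(m) <- NULL
  ## a surviving transformed column may lose its parent on subset; demote it
  orphan <- m$source == "transformed" & !(m$parent %in% m$name)
  if (any(orphan)) {
    m$source[orphan] <- "base"
    m$parent[orphan] <- NA_character_
  }
  methods::new("DescriptorTable", values = v, meta = m)
})

setMethod("[", signature(x = "CompoundSet", i = "ANY", j = "ANY",
                         drop = "ANY"),
          function(x, i, j, ..., drop = FALSE) {
  if (!missing(i) && is.character(i)) {
    i <- match(i, x@info$compound_id)
    if (anyNA(i)) stop("unknown compound id(s)")
  }
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  resp <- x@responses[i, , drop = FALSE]
  rownames(resp) <- NULL
  methods::new("CompoundSet", info = info, responses = resp,
               descriptors = x@descriptors[i, ])
})

## ---- show ------------------------------------------------------------------

setMethod("show", "ReferenceSeries", function(object) {
  cat("ReferenceSeries:", nrow(object@alkanes), "alkanes (C",
      min(object@alkanes$carbon), "-C", max(object@alkanes$carbon), "), ",
      nrow(object@pegs), " PEGs, ",
      if (nrow(object@alkane2d)) "measured" else "flat",
      " alkane baseline\n", sep = "")
})

setMethod("show", "DescriptorTable", function(object) {
  src <- table(object@meta$source)
  cat("DescriptorTable:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors\n")
  cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet:", nrow(object@info), "compounds,",
      ncol(object@descriptors@values), "descriptors\n")
  cat("  responses:", paste(names(object@responses), collapse = ", "), "\n")
  if (!all(is.na(object@info$set))) {
    tab <- table(object@info$set, useNA = "no")
    cat("  split:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel (", object@scope, ") for ", object@responseName, ": ",
      object@ncomp, " components, ", length(object@coefficients),
      " descriptors\n", sep = "")
  if (nrow(object@cvRecord)) {
    best <- object@cvRecord[object@cvRecord$ncomp == object@ncomp, ]
    if (nrow(best))
      cat(sprintf("  cross-validated Q2 = %.3f, RMSE_CV = %.4g\n",
                  best$Q2[1], best$RMSE_CV[1]))
  }
})

setMethod("show", "SplitAssignment", function(object) {
  tab <- table(object@assignment$set)
  cat("SplitAssignment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", length(object@ids), "entries,",
      ncol(object@properties), "similarity properties,",
      "responses:", paste(names(object@responses), collapse = ", "), "\n")
})

setMethod("show", "FederationConfig", function(object) {
  cat(sprintf("FederationConfig: metric=%s, k=%d, m=%d (max %d parameters), properties=%s\n",
              object@metric, object@k, object@m,
              floor(object@k / object@m), object@propertySet))
})

setMethod("show", "LocalPrediction", function(object) {
  cat(sprintf("LocalPrediction: %.6g from %d neighbours, %d parameters (local RMSE %.4g)\n",
              object@predicted, nrow(object@neighbors),
              length(object@parameters), object@localRMSE))
  if (nzchar(object@flag)) cat("  flag:", object@flag, "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s, %s]: N=%d\n", object@response,
              object@set, object@n))
  cat(sprintf("  RMSE_P = %.4g, avg dev = %.4g, avg rel dev = %.2f%%, 95-percentile = %.4g\n",
              object@rmsep, object@avgDev, 100 * object@avgRelDev,
              object@p95))
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel:", ncol(object@loadings), "components, explained:",
      paste(sprintf("%.1f%%", 100 * object@explained), collapse = " "), "\n")
})

#' Turn an evaluation report into a one-row data.frame
#'
#' @param x an [EvaluationReport-class]
#' @param row.names,optional,... passed through for the generic's signature
#' @return one-row data.frame with n, rmsep, avg_dev, avg_rel_dev, p95
#' @export
as.data.frame.EvaluationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(response = x@response, set = x@set, n = x@n, rmsep = x@rmsep,
             avg_dev = x@avgDev, avg_rel_dev = x@avgRelDev, p95 = x@p95,
             stringsAsFactors = FALSE)
}
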