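#' @include AllClasses.R
NULL

#' Append weight-normalised descriptor variants
#'
#' Size-dependent properties (lipophilicity, polarizability proxies, ...)
#' are made comparable across molecular sizes by dividing by the molecular
#' weight. One column `<name>_perMW` is appended per requested descriptor.
#'
#' @param table a [DescriptorTable-class] containing a column `MW`.
#' @param which character vector of descriptor names to normalise; default
#'   all base descriptors except `MW` itself.
#' @return a [DescriptorTable-class] with the extra columns
#'   (`source = "weight_normalized"`, `parent` = the original name).
#' @export
augmentWeightNormalized <- function(table, which = NULL) {
  stopifnot(is(table, "DescriptorTable"))
  v <- table@values
  if (!"MW" %in% colnames(v))
    stop("configuration error: molecular weight column 'MW' required for weight normalisation")
  if (any(is.na(v[, "MW"]) | v[, "MW"] <= 0))
    stop("molecular weight must be strictly positive for every compound")
  if (is.null(which))
    which <- setdiff(table@meta$name[table@meta$source == "base"], "MW")
  missing <- setdiff(which, colnames(v))
  if (length(missing))
    stop("unknown descriptors: ", paste(missing, collapse = ", "))
  newv <- v[, which, drop = FALSE] / v[, "MW"]
  colnames(newv) <- paste0(which, "_perMW")
  dup <- colnames(newv) %in% colnames(v)
  newv <- newv[, !dup, drop = FALSE]
  meta <- rbind(table@meta,
                data.frame(name = colnames(newv),
                           source = "weight_normalized", transform = "none",
                           parent = which[!dup], stringsAsFactors = FALSE))
  methods::new("DescriptorTable", values = cbind(v, newv), meta = meta)
}

## transform catalog; each entry maps raw x to transformed values or NULL
## when undefined on this column
.transformCatalog <- list(
  log10_shift = function(x) {
    z <- x - min(x) + 1
    if (any(z <= 0)) return(NULL)
    log10(z)
  },
  sqrt = function(x) {
    z <- x - min(x)
    if (any(z < 0)) return(NULL)
    sqrt(z)
  },
  reciprocal = function(x) {
    if (any(x <= 0)) return(NULL)
    1 / x
  },
  square = function(x) x^2
)

#' Append linearising transformations of descriptors
#'
#' For each descriptor, every candidate transformation in the catalog is
#' evaluated against a response measured on the training rows; a transformed
#' copy is appended when it improves the absolute Pearson correlation with
#' the response by at least `margin`. At most one transform (the best
#' improver) is kept per descriptor; originals are always retained.
#'
#' @param table a [DescriptorTable-class]
#' @param response numeric response aligned with the table rows (training
#'   subset only).
#' @param catalog character subset of `c("log10_shift", "sqrt",
#'   "reciprocal", "square")`.
#' @param margin minimum improvement in |Pearson r| (default 0.05).
#' @return a [DescriptorTable-class] with appended `transformed` columns
#'   named `<name>_<transform>`.
#' @export
applyManualTransformations <- function(table, response,
                                       catalog = names(.transformCatalog),
                                       margin = 0.05) {
  stopifnot(is(table, "DescriptorTable"))
  v <- table@values
  if (length(response) != nrow(v))
    stop("response must align with table rows")
  catalog <- match.arg(catalog, names(.transformCatalog), several.ok = TRUE)
  addv <- list()
  addm <- list()
  for (nm in table@meta$name[table@meta$source != "transformed"]) {
    x <- v[, nm]
    if (stats::sd(x) == 0 || anyNA(x)) next
    r0 <- abs(stats::cor(x, response))
    best <- NULL
    bestr <- r0 + margin
    for (tf in catalog) {
      z <- .transformCatalog[[tf]](x)
      if (is.null(z)) {
        warning(sprintf("transform %s undefined for descriptor %s; skipped",
                        tf, nm))
        next
      }
      if (stats::sd(z) == 0) next
      r1 <- abs(stats::cor(z, response))
      if (r1 >= bestr) {
        bestr <- r1
        best <- list(tf = tf, z = z)
      }
    }
    if (!is.null(best)) {
      cn <- paste0(nm, "_", best$tf)
      if (cn %in% colnames(v)) next
      addv[[cn]] <- best$z
      addm[[cn]] <- data.frame(name = cn, source = "transformed",
                               transform = best$tf, parent = nm,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(addv)) return(table)
  newv <- do.call(cbind, addv)
  rownames(newv) <- rownames(v)
  methods::new("DescriptorTable", values = cbind(v, newv),
               meta = rbind(table@meta, do.call(rbind, addm)))
}

#' Autoscale a descriptor table on a training subset
#'
#' Centers each descriptor to mean 0 and scales to unit variance (sample SD,
#' N-1 denominator) using only the fitting rows, so held-out compounds are
#' scaled with training parameters. Zero-variance columns are dropped and
#' recorded. Descriptors with more than `maxMissing` missing values over the
#' fitting rows are dropped; remaining missing values are imputed with the
#' training median.
#'
#' @param table a [DescriptorTable-class]
#' @param fit_rows compound ids (or logical/integer index) defining the
#'   training subset; default all rows.
#' @param maxMissing maximum tolerated fraction of missing values per
#'   descriptor over the fitting rows (default 0.05).
#' @return list with `table` (scaled [DescriptorTable-class], dropped
#'   columns removed) and `params` (a [ScalingParams-class]).
#' @export
autoscale <- function(table, fit_rows = NULL, maxMissing = 0.05) {
  stopifnot(is(table, "DescriptorTable"))
  v <- table@values
  idx <- .resolveRows(fit_rows, v)
  if (!length(idx)) stop("fit_rows must be nonempty")
  fit <- v[idx, , drop = FALSE]
  missFrac <- colMeans(is.na(fit))
  keep1 <- missFrac <= maxMissing
  ## median-impute the tolerated gaps, training median everywhere
  med <- apply(fit, 2, stats::median, na.rm = TRUE)
  for (j in which(keep1)) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- med[j]
  }
  ctr <- colMeans(v[idx, , drop = FALSE])
  sdv <- apply(v[idx, , drop = FALSE], 2, stats::sd)
  keep <- keep1 & !is.na(sdv) & sdv > 0
  params <- methods::new("ScalingParams",
                         center = ctr[keep], scale = sdv[keep],
                         dropped = colnames(v)[!keep])
  scaled <- sweep(sweep(v[, keep, drop = FALSE], 2, ctr[keep]), 2,
                  sdv[keep], `/`)
  meta <- table@meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  orphan <- meta$source == "transformed" & !(meta$parent %in% meta$name)
  if (any(orphan)) {
    meta$source[orphan] <- "base"
    meta$parent[orphan] <- NA_character_
  }
  list(table = methods::new("DescriptorTable", values = scaled, meta = meta),
       params = params)
}

.resolveRows <- function(rows, v) {
  if (is.null(rows)) return(seq_len(nrow(v)))
  if (is.character(rows)) {
    idx <- match(rows, rownames(v))
    if (anyNA(idx)) stop("unknown compound ids in fit_rows")
    return(idx)
  }
  if (is.logical(rows)) return(which(rows))
  rows
}

#' Scale new rows with stored training parameters
#'
#' @param x numeric matrix (or [DescriptorTable-class]) with named columns
#'   covering the retained descriptors.
#' @param params a [ScalingParams-class] from [autoscale()]
#' @return numeric matrix restricted to the retained descriptors, scaled.
#' @export
applyScaling <- function(x, params) {
  if (is(x, "DescriptorTable")) x <- x@values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  nm <- names(params@center)
  missing <- setdiff(nm, colnames(x))
  if (length(missing))
    stop("missing descriptors: ", paste(utils::head(missing, 5), collapse = ", "))
  sweep(sweep(x[, nm, drop = FALSE], 2, params@center), 2, params@scale, `/`)
}

#' Undo autoscaling
#'
#' @param x scaled numeric matrix with columns matching the retained
#'   descriptors.
#' @param params a [ScalingParams-class]
#' @return matrix in original descriptor units.
#' @export
revertScaling <- function(x, params) {
  nm <- names(params@center)
  sweep(sweep(x[, nm, drop = FALSE], 2, params@scale, `*`), 2,
        params@center, `+`)
}
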