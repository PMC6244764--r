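#' @include AllClasses.R containers.R
NULL

.annotationCols <- c("compound_id", "name", "smiles", "group",
                     "pcb_chlorine", "set")
.responseCols <- c("t1R", "t2R", "LRI", "PEG2I")

#' Write a compound set to a delimited table
#'
#' Canonical dialect: comma-separated, UTF-8, header row, "." decimal.
#' Annotation and response columns first, descriptors after.
#'
#' @param cs a [CompoundSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCompoundTable <- function(cs, path) {
  df <- cbind(cs@info[, intersect(.annotationCols, names(cs@info))],
              cs@responses, as.data.frame(cs@descriptors@values))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a compound table
#'
#' Annotation and response columns are recognised by name
#' (`compound_id`, `name`, `smiles`, `group`, `pcb_chlorine`, `set`;
#' `t1R`, `t2R`, `LRI`, `PEG2I`); every unknown column is routed to the
#' descriptor matrix. Non-numeric descriptor cells become missing values
#' and are counted in the parse report.
#'
#' @param path delimited file with a header row.
#' @param sep field separator (default comma).
#' @return list with `compounds` (a [CompoundSet-class]) and `report`
#'   (`rows_read`, `rows_dropped`, `missing_values`)
#' @export
readCompoundTable <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (is.null(df$compound_id)) stop("missing compound_id column")
  df$compound_id <- as.character(df$compound_id)
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  info <- df[, intersect(.annotationCols, names(df)), drop = FALSE]
  resp <- df[, intersect(.responseCols, names(df)), drop = FALSE]
  descCols <- setdiff(names(df), c(.annotationCols, .responseCols))
  nMissing <- 0L
  values <- matrix(NA_real_, nrow(df), length(descCols),
                   dimnames = list(df$compound_id, descCols))
  for (j in seq_along(descCols)) {
    x <- df[[descCols[j]]]
    num <- suppressWarnings(as.numeric(x))
    bad <- is.na(num) & !is.na(x) & x != ""
    if (any(bad)) {
      .log("warn", sprintf("%d non-numeric cell(s) in descriptor '%s' treated as missing",
                           sum(bad), descCols[j]))
      nMissing <- nMissing + sum(bad)
    }
    values[, j] <- num
  }
  for (cn in intersect(c("t1R", "t2R", "LRI", "PEG2I"), names(resp)))
    resp[[cn]] <- as.numeric(resp[[cn]])
  cs <- compoundSet(info, resp, descriptorTable(values))
  list(compounds = cs,
       report = list(rows_read = nrow(df), rows_dropped = 0L,
                     missing_values = nMissing))
}

#' Write a reference-standard series
#'
#' One row per standard with columns `series` (`alkane`, `peg`,
#' `alkane2d`), `label` (`C10`, `PEG-6`, ...), `t1_s`, `t2_s`.
#'
#' @param series a [ReferenceSeries-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeReferenceSeries <- function(series, path) {
  a <- series@alkanes
  p <- series@pegs
  b <- series@alkane2d
  df <- rbind(
    data.frame(series = "alkane", label = paste0("C", a$carbon),
               t1_s = a$t1, t2_s = NA_real_),
    if (nrow(p)) data.frame(series = "peg", label = paste0("PEG-", p$eo),
                            t1_s = p$t1, t2_s = p$t2),
    if (nrow(b)) data.frame(series = "alkane2d", label = "",
                            t1_s = b$t1, t2_s = b$t2))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reference-standard series
#'
#' @param path file written by [writeReferenceSeries()] (or hand-prepared
#'   with the same columns); alkane carbon numbers and PEG ethylene-oxide
#'   counts are parsed from the labels.
#' @return a [ReferenceSeries-class]
#' @export
readReferenceSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("series", "label", "t1_s")
  if (!all(need %in% names(df)))
    stop("reference-series file needs columns: ",
         paste(need, collapse = ", "))
  a <- df[df$series == "alkane", ]
  p <- df[df$series == "peg", ]
  b <- df[df$series == "alkane2d", ]
  referenceSeries(
    alkanes = data.frame(carbon = as.integer(sub("^C", "", a$label)),
                         t1 = a$t1_s),
    pegs = if (nrow(p))
      data.frame(eo = as.integer(sub("^PEG-", "", p$label)),
                 t1 = p$t1_s, t2 = p$t2_s)
    else data.frame(eo = numeric(0), t1 = numeric(0), t2 = numeric(0)),
    alkane2d = if (nrow(b)) data.frame(t1 = b$t1_s, t2 = b$t2_s)
    else data.frame(t1 = numeric(0), t2 = numeric(0)))
}

#' Write a split assignment
#'
#' @param assignment a [SplitAssignment-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSplitAssignment <- function(assignment, path) {
  utils::write.csv(assignment@assignment, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a split assignment
#'
#' Accepts the two-column form (`compound_id`, `set`) so an externally
#' prepared split can be injected verbatim instead of recomputed.
#'
#' @param path delimited file with `compound_id` and `set` columns.
#' @return a [SplitAssignment-class]
#' @export
readSplitAssignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (is.null(df$provenance)) df$provenance <- NA_character_
  df$compound_id <- as.character(df$compound_id)
  methods::new("SplitAssignment",
               assignment = df[, c("compound_id", "set", "provenance")])
}

#' Attach a split assignment to a compound set
#'
#' @param cs a [CompoundSet-class]
#' @param assignment a [SplitAssignment-class] covering (at least) the
#'   compounds of `cs`.
#' @return `cs` with the `set` column of its info table filled in.
#' @export
applySplit <- function(cs, assignment) {
  a <- assignment@assignment
  idx <- match(cs@info$compound_id, a$compound_id)
  if (anyNA(idx)) stop("assignment does not cover every compound")
  cs@info$set <- a$set[idx]
  methods::validObject(cs)
  cs
}

#' Serialize a PLS model to portable JSON
#'
#' Carries everything needed to predict and audit: scaling parameters,
#' descriptor names, coefficients, component count, weights/loadings, VIP,
#' uncertainty half-widths and the cross-validation record.
#'
#' @param model a [PLSModel-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeModelJSON <- function(model, path) {
  x <- list(format = "qsrr2d-pls", version = 1L,
            responseName = model@responseName, scope = model@scope,
            ncomp = model@ncomp, intercept = model@intercept,
            descriptors = names(model@coefficients),
            coefficients = unname(model@coefficients),
            xCenter = unname(model@xScaling@center),
            xScale = unname(model@xScaling@scale),
            xDropped = model@xScaling@dropped,
            yCenter = model@yCenter, yScale = model@yScale,
            weights = model@weights, loadings = model@loadings,
            yloadings = model@yloadings, scores = model@scores,
            vip = unname(model@vip),
            coefHalfWidth = unname(model@coefHalfWidth),
            cvRecord = model@cvRecord)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PLS model serialized by [writeModelJSON()]
#'
#' @param path JSON file
#' @return a [PLSModel-class]
#' @export
readModelJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "qsrr2d-pls"))
    stop("not a serialized PLS model")
  nm <- x$descriptors
  asMat <- function(m) {
    m <- as.matrix(m)
    rownames(m) <- nm
    colnames(m) <- paste0("comp", seq_len(ncol(m)))
    m
  }
  scores <- as.matrix(x$scores)
  colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  methods::new("PLSModel",
    weights = asMat(x$weights), loadings = asMat(x$loadings),
    yloadings = as.numeric(x$yloadings), scores = scores,
    ncomp = as.numeric(x$ncomp),
    coefficients = stats::setNames(as.numeric(x$coefficients), nm),
    intercept = as.numeric(x$intercept),
    xScaling = methods::new("ScalingParams",
                            center = stats::setNames(as.numeric(x$xCenter), nm),
                            scale = stats::setNames(as.numeric(x$xScale), nm),
                            dropped = as.character(x$xDropped)),
    yCenter = as.numeric(x$yCenter), yScale = as.numeric(x$yScale),
    vip = stats::setNames(as.numeric(x$vip), nm),
    coefHalfWidth = if (length(x$coefHalfWidth))
      stats::setNames(as.numeric(x$coefHalfWidth), nm) else numeric(0),
    cvRecord = as.data.frame(x$cvRecord),
    responseName = x$responseName, scope = x$scope)
}

#' Read compound records from an SDF structure file
#'
#' Parses a V2000/V3000 SDF with ChemmineR; per-record data fields carry
#' the responses. Records whose molecule block does not parse are skipped
#' with a logged warning.
#'
#' @param path SDF file
#' @param fieldMap named character vector mapping response names to SDF
#'   data-field names (default: the response names themselves, with
#'   `compound_id` taken from the `compound_id` field or the molecule
#'   title).
#' @return list with `compounds` (a [CompoundSet-class] with an empty
#'   descriptor table) and `report` (`records_read`, `records_skipped`)
#' @export
readStructuresSDF <- function(path, fieldMap = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required to read SDF files")
  if (is.null(fieldMap))
    fieldMap <- stats::setNames(.responseCols, .responseCols)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdf)
  skipped <- sum(!valid)
  if (skipped)
    .log("warn", sprintf("%d unparseable SDF record(s) skipped", skipped))
  sdf <- sdf[valid]
  blocks <- ChemmineR::datablock(sdf)
  getField <- function(b, f) if (f %in% names(b)) b[[f]] else NA_character_
  ids <- vapply(seq_along(blocks), function(i) {
    v <- getField(blocks[[i]], "compound_id")
    if (is.na(v)) ChemmineR::sdfid(sdf[i]) else v
  }, character(1))
  resp <- as.data.frame(lapply(fieldMap, function(f) {
    vapply(blocks, function(b) suppressWarnings(as.numeric(getField(b, f))),
           numeric(1))
  }))
  resp <- resp[, colSums(!is.na(resp)) > 0, drop = FALSE]
  values <- matrix(numeric(0), nrow = length(ids), ncol = 0,
                   dimnames = list(ids, NULL))
  cs <- compoundSet(data.frame(compound_id = ids, stringsAsFactors = FALSE),
                    resp, descriptorTable(values))
  list(compounds = cs,
       report = list(records_read = length(ids), records_skipped = skipped))
}

#' Write compound records to an SDF structure file
#'
#' Responses and the compound id are written as data fields. Compounds
#' without structures get a single-carbon placeholder molecule block
#' (clearly synthetic; the fields, not the structure, carry the
#' information a knowledge-base import needs).
#'
#' @param cs a [CompoundSet-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeStructuresSDF <- function(cs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  info <- cs@info
  resp <- cs@responses
  for (i in seq_len(nrow(info))) {
    writeLines(c(info$compound_id[i], "  qsrr2d", "",
                 "  2  1  0  0  0  0  0  0  0  0999 V2000",
                 "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                 "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
                 "  1  2  1  0  0  0  0",
                 "M  END"), con)
    writeLines(c("> <compound_id>", info$compound_id[i], ""), con)
    for (cn in names(resp)) {
      v <- resp[[cn]][i]
      if (!is.na(v))
        writeLines(c(sprintf("> <%s>", cn), format(v, digits = 15), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

## ---- logging ---------------------------------------------------------------

.logLevels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package logging
#'
#' Timestamped, leveled messages on stderr; the threshold is the
#' `qsrr2d.logLevel` option (`debug`, `info`, `warn`, `error`; default
#' `warn`).
#'
#' @param level message level
#' @param msg message text
#' @return invisibly, whether the message was emitted
#' @keywords internal
.log <- function(level, msg) {
  threshold <- getOption("qsrr2d.logLevel", "warn")
  emit <- .logLevels[[level]] >= .logLevels[[threshold]]
  if (emit)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), msg))
  invisible(emit)
}

#' Run manifest for reproducibility
#'
#' @param config named list of settings (e.g. a [syntheticConfig()]).
#' @param inputs character vector of input file paths (digested with MD5).
#' @param seed the run seed
#' @return list with timestamp, seed, config hash, and input digests
#' @export
runManifest <- function(config = list(), inputs = character(0), seed = NA) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config[order(names(config))], NULL, version = 2), tf)
  cfgHash <- unname(tools::md5sum(tf))
  list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, config_hash = cfgHash,
       inputs = if (length(inputs))
         as.list(tools::md5sum(inputs)) else list())
}
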