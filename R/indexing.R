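#' @include AllClasses.R
NULL

#' First-dimension linear retention index
#'
#' Computes the temperature-programmed linear retention index (van den
#' Dool-Kratz): between consecutive n-alkanes C_n and C_{n+1},
#' `LRI = 100 n + 100 (t - t_n) / (t_{n+1} - t_n)`, so an alkane C_n gets
#' exactly `100 n`. Outside the alkane span the nearest segment is
#' extrapolated linearly and the result is flagged.
#'
#' @param t1 numeric vector of first-dimension retention times (seconds),
#'   strictly positive.
#' @param series a [ReferenceSeries-class]
#' @return data.frame with one row per input: `value` (index units),
#'   `extrapolated` (logical), `dimension` (`"first"`).
#' @examples
#' rs <- referenceSeries(data.frame(carbon = c(10, 11), t1 = c(1200, 1500)))
#' computeLRI(c(1200, 1350, 1650), rs)
#' @export
computeLRI <- function(t1, series) {
  stopifnot(is(series, "ReferenceSeries"))
  methods::validObject(series)
  if (any(!is.finite(t1) | t1 <= 0))
    stop("t1 must be positive and finite")
  a <- series@alkanes
  ## segment index: clamp to the outermost segments for extrapolation
  seg <- findInterval(t1, a$t1, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(a) - 1L)
  n0 <- a$carbon[seg]
  n1 <- a$carbon[seg + 1L]
  frac <- (t1 - a$t1[seg]) / (a$t1[seg + 1L] - a$t1[seg])
  value <- 100 * n0 + 100 * (n1 - n0) * frac
  data.frame(value = value,
             extrapolated = t1 < min(a$t1) | t1 > max(a$t1),
             dimension = "first", stringsAsFactors = FALSE)
}

#' Fit the PEG and alkane reference lines of the GCxGC plane
#'
#' Ordinary least squares straight lines in (t1, t2) space: one through the
#' PEG series and one through the alkane second-dimension times (the
#' non-polar baseline). When no alkane t2 measurements are available the
#' baseline is an intercept-only line at the minimum observed reference t2.
#'
#' @param series a [ReferenceSeries-class] with at least two PEGs carrying
#'   t2 values.
#' @return list with elements `peg` and `baseline`, each a list
#'   `(slope, intercept, span, rms)` where `span` is the t1 range of the
#'   points fitted and `rms` the residual root-mean-square, plus
#'   `peg_span`, the PEG t1 range used for extrapolation flagging.
#' @export
fitReferenceLines <- function(series) {
  stopifnot(is(series, "ReferenceSeries"))
  methods::validObject(series)
  p <- series@pegs
  if (nrow(p) < 2)
    stop("invalid reference series: at least 2 PEGs with t2 required")
  peg <- .olsLine(p$t1, p$t2)
  b <- series@alkane2d
  if (nrow(b) >= 2) {
    baseline <- .olsLine(b$t1, b$t2)
  } else {
    t2min <- min(p$t2, if (nrow(b)) b$t2 else numeric(0))
    baseline <- list(slope = 0, intercept = t2min,
                     span = range(p$t1), rms = 0)
  }
  list(peg = peg, baseline = baseline, peg_span = range(p$t1))
}

.olsLine <- function(x, y) {
  if (diff(range(x)) == 0)
    stop("degenerate reference line: all t1 equal")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       span = range(x),
       rms = sqrt(mean(fit$residuals^2)))
}

#' Second-dimension PEG-based retention index
#'
#' Places an analyte between the alkane baseline (index 0) and the PEG line
#' (index 100) at its first-dimension position:
#' `PEG-2I = 100 (t2 - base(t1)) / (peg(t1) - base(t1))`. Values above 100
#' are legitimate (analytes more retained than the PEGs); analytes whose t1
#' falls outside the PEG t1 span are flagged as extrapolated.
#'
#' @param t1,t2 numeric vectors of first- and second-dimension retention
#'   times (seconds).
#' @param lines fitted reference lines from [fitReferenceLines()].
#' @return data.frame with one row per input: `value`, `extrapolated`,
#'   `dimension` (`"second"`).
#' @export
computePEG2I <- function(t1, t2, lines) {
  stopifnot(length(t1) == length(t2))
  base <- lines$baseline$intercept + lines$baseline$slope * t1
  peg <- lines$peg$intercept + lines$peg$slope * t1
  gap <- peg - base
  if (any(gap <= 0))
    stop("degenerate geometry: PEG line at or below the alkane baseline")
  data.frame(value = 100 * (t2 - base) / gap,
             extrapolated = t1 < lines$peg_span[1] | t1 > lines$peg_span[2],
             dimension = "second", stringsAsFactors = FALSE)
}

#' Index every compound of a set from its raw retention times
#'
#' Convenience wrapper: computes LRI from `t1R` and PEG-2I from
#' (`t1R`, `t2R`) and stores them as the `LRI` and `PEG2I` responses.
#'
#' @param cs a [CompoundSet-class] with `t1R` (and `t2R` for PEG-2I) among
#'   its responses.
#' @param series a [ReferenceSeries-class]
#' @return `cs` with `LRI` (and `PEG2I`) responses filled in, and logical
#'   columns `LRI_extrapolated` / `PEG2I_extrapolated` added to the info
#'   table.
#' @export
indexCompoundSet <- function(cs, series) {
  stopifnot(is(cs, "CompoundSet"))
  resp <- cs@responses
  info <- cs@info
  lri <- computeLRI(resp$t1R, series)
  resp$LRI <- lri$value
  info$LRI_extrapolated <- lri$extrapolated
  if (!is.null(resp$t2R) && nrow(series@pegs) >= 2) {
    lines <- fitReferenceLines(series)
    p2 <- computePEG2I(resp$t1R, resp$t2R, lines)
    resp$PEG2I <- p2$value
    info$PEG2I_extrapolated <- p2$extrapolated
  }
  methods::new("CompoundSet", info = info, responses = resp,
               descriptors = cs@descriptors)
}
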