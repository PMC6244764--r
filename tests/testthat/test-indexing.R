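test_that("LRI is exact on the reference alkanes and linear in between", {
  rs <- referenceSeries(data.frame(carbon = 8:12,
                                   t1 = c(400, 550, 730, 940, 1180)))
  at <- computeLRI(c(400, 550, 730, 940, 1180), rs)
  expect_equal(at$value, 100 * (8:12))
  expect_false(any(at$extrapolated))
  mid <- computeLRI((550 + 730) / 2, rs)
  expect_equal(mid$value, 950)
})

test_that("LRI extrapolates the outer segments and flags it", {
  rs <- referenceSeries(data.frame(carbon = c(10, 11, 12),
                                   t1 = c(1000, 1200, 1400)))
  lo <- computeLRI(900, rs)
  hi <- computeLRI(1500, rs)
  expect_true(lo$extrapolated)
  expect_true(hi$extrapolated)
  expect_equal(lo$value, 950)   # 100*10 + 100*(900-1000)/200
  expect_equal(hi$value, 1250)
})

test_that("computeLRI rejects non-positive retention times", {
  rs <- referenceSeries(data.frame(carbon = c(10, 11), t1 = c(1000, 1200)))
  expect_error(computeLRI(0, rs), "positive")
  expect_error(computeLRI(c(1100, -5), rs), "positive")
})

test_that("fitReferenceLines recovers straight reference lines exactly", {
  t1 <- seq(500, 2000, length.out = 6)
  rs <- referenceSeries(
    alkanes = data.frame(carbon = 10:15, t1 = t1),
    pegs = data.frame(eo = 3:8, t1 = t1, t2 = 4 - 0.001 * t1),
    alkane2d = data.frame(t1 = t1, t2 = 1.5 - 0.0002 * t1))
  ln <- fitReferenceLines(rs)
  expect_equal(ln$peg$slope, -0.001, tolerance = 1e-12)
  expect_equal(ln$peg$intercept, 4, tolerance = 1e-9)
  expect_equal(ln$baseline$slope, -0.0002, tolerance = 1e-12)
  expect_equal(ln$peg$rms, 0, tolerance = 1e-9)
})

test_that("baseline falls back to an intercept-only line without alkane t2", {
  rs <- referenceSeries(
    alkanes = data.frame(carbon = 10:12, t1 = c(1000, 1200, 1400)),
    pegs = data.frame(eo = 3:5, t1 = c(1000, 1200, 1400), t2 = c(3, 3.2, 3.4)))
  ln <- fitReferenceLines(rs)
  expect_equal(ln$baseline$slope, 0)
  expect_equal(ln$baseline$intercept, 3)  # minimum reference t2
})

test_that("PEG-2I anchors: baseline scores 0, the PEG line scores 100", {
  rs <- syntheticReferenceSeries(syntheticConfig(seed = 1))
  ln <- fitReferenceLines(rs)
  t1 <- c(1400, 1800, 2200)
  base <- ln$baseline$intercept + ln$baseline$slope * t1
  peg <- ln$peg$intercept + ln$peg$slope * t1
  expect_equal(computePEG2I(t1, base, ln)$value, rep(0, 3), tolerance = 1e-9)
  expect_equal(computePEG2I(t1, peg, ln)$value, rep(100, 3), tolerance = 1e-9)
  ## midpoint scores 50; values above the PEG line exceed 100
  expect_equal(computePEG2I(t1, (base + peg) / 2, ln)$value, rep(50, 3),
               tolerance = 1e-9)
  expect_gt(computePEG2I(1800, peg[2] + 1, ln)$value, 100)
})

test_that("PEG-2I flags first-dimension extrapolation beyond the PEG span", {
  rs <- syntheticReferenceSeries(syntheticConfig(seed = 1))
  ln <- fitReferenceLines(rs)
  p <- computePEG2I(c(ln$peg_span[1] - 1, mean(ln$peg_span),
                      ln$peg_span[2] + 1), c(2, 2, 2), ln)
  expect_equal(p$extrapolated, c(TRUE, FALSE, TRUE))
})

test_that("degenerate geometry (PEG at or below baseline) is rejected", {
  ln <- list(baseline = list(slope = 0, intercept = 2),
             peg = list(slope = 0, intercept = 2), peg_span = c(0, 1))
  expect_error(computePEG2I(0.5, 2, ln), "degenerate")
})

test_that("indexCompoundSet fills LRI and PEG2I with extrapolation flags", {
  cs <- indexCompoundSet(sharedData$compounds, sharedData$series)
  r <- responses(cs)
  expect_true(all(c("LRI", "PEG2I") %in% names(r)))
  info <- compoundInfo(cs)
  expect_type(info$LRI_extrapolated, "logical")
  expect_type(info$PEG2I_extrapolated, "logical")
  ## re-indexing is idempotent
  expect_equal(r$LRI, responses(sharedData$compounds)$LRI)
})
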