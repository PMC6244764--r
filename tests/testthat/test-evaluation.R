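test_that("RMSE_P uses the N-1 denominator (constant-offset identity)", {
  y <- c(10, 20, 30, 40, 50)
  r <- evaluatePredictions(y, y - 3)
  expect_equal(r@rmsep, 3 * sqrt(5 / 4))
  expect_equal(r@avgDev, 3)
  expect_equal(r@p95, 3)
  expect_equal(r@n, 5L)
  expect_equal(r@residuals, rep(3, 5))
})

test_that("the 95th percentile interpolates order statistics (type 7)", {
  res <- 1:100
  r <- evaluatePredictions(res + 1000, rep(1000, 100))
  expect_equal(r@p95, 95.05)
})

test_that("zero observations are skipped in the relative deviation", {
  expect_warning(r <- evaluatePredictions(c(0, 10, 20), c(1, 11, 21)),
                 "skipped")
  expect_equal(r@relSkipped, 1L)
  expect_equal(r@avgRelDev, mean(c(1 / 10, 1 / 20)))
  expect_error(evaluatePredictions(1, 1), "at least 2")
  expect_error(evaluatePredictions(1:3, 1:4), "mismatch")
})

test_that("EvaluationReport converts to a one-row data.frame", {
  df <- as.data.frame(evaluatePredictions(c(1, 2, 4), c(1, 2, 4),
                                          response = "t1R", set = "test"))
  expect_equal(df$response, "t1R")
  expect_equal(df$rmsep, 0)
  expect_equal(nrow(df), 1)
})

test_that("benchmark models bracket the PLS model on the shared study", {
  info <- compoundInfo(sharedCS)
  tr <- sharedCS[which(info$set == "training")]
  te <- sharedCS[which(info$set == "test")]
  bm <- benchmarkModels(tr, te, "t1R")
  expect_s4_class(bm$simple, "EvaluationReport")
  expect_lt(bm$simple@rmsep, bm$mean@rmsep)
  expect_equal(nrow(bm$predictions), bm$simple@n)
  expect_error(benchmarkModels(tr, te, "t1R", "not_a_descriptor"),
               "missing")
})

test_that("ensembleAverage is the elementwise mean", {
  expect_equal(ensembleAverage(c(1, 2), c(3, 6)), c(2, 4))
  expect_error(ensembleAverage(1:2, 1:3), "mismatch")
})

test_that("calibrated applicability domain keeps 95% of training in-domain", {
  Xtr <- descriptorValues(sharedCS)[compoundInfo(sharedCS)$set == "training", ]
  pca <- calibrateDomain(runPCA(Xtr, 5), Xtr)
  ad <- applicabilityDomain(pca, Xtr)
  expect_gte(mean(ad$in_domain), 0.95)
  expect_true(all(c("t2", "t2_limit", "dmod", "dmod_limit") %in% names(ad)))
})

test_that("a far-outside query is out of domain", {
  Xtr <- descriptorValues(sharedCS)[compoundInfo(sharedCS)$set == "training", ]
  pca <- calibrateDomain(runPCA(Xtr, 5), Xtr)
  far <- Xtr[1, , drop = FALSE] + 50 * apply(Xtr, 2, sd)
  ad <- applicabilityDomain(pca, far)
  expect_false(ad$in_domain)
})

test_that("filterCandidates eliminates on any window violation, boundary inclusive", {
  cand <- data.frame(candidate_id = c("a", "b", "c"),
                     LRI = c(1500, 1520, 1490),
                     PEG2I = c(40, 40, 70))
  exp_ <- c(LRI = 1500, PEG2I = 42)
  win <- c(LRI = 20, PEG2I = 5)
  out <- filterCandidates(exp_, cand, win)
  expect_equal(out$verdict, c("retained", "retained", "eliminated"))
  expect_equal(out$within_LRI, c(TRUE, TRUE, TRUE))
  expect_equal(out$within_PEG2I, c(TRUE, TRUE, FALSE))
  ## candidate b sits exactly on the LRI boundary and is retained
  expect_true(abs(cand$LRI[2] - exp_["LRI"]) == win["LRI"])
  ## out-of-domain flag is carried, not used for elimination
  out2 <- filterCandidates(exp_, cand, win, in_domain = c(TRUE, FALSE, TRUE))
  expect_equal(out2$verdict, out$verdict)
  expect_equal(out2$in_domain, c(TRUE, FALSE, TRUE))
  expect_error(filterCandidates(exp_, cand, c(LRI = -1, PEG2I = 5)),
               "positive")
  expect_error(filterCandidates(c(zzz = 1), cand, win), "no shared")
})

test_that("errorWindows returns the validation p95 per response", {
  m1 <- trainPLS(sharedCS, "t1R", seed = 7, uncertainty = FALSE)
  w <- errorWindows(sharedCS, list(t1R = m1))
  expect_named(w, "t1R")
  ev <- evaluateOnSet(m1, sharedCS, "external_validation")
  expect_equal(unname(w["t1R"]), ev@p95)
  expect_gt(w["t1R"], 0)
})
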