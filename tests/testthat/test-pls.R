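test_that("full-rank PLS equals ordinary least squares", {
  X <- smallProblem$X
  y <- smallProblem$y
  m <- fitPLS(X, y, A = ncol(X))
  ref <- lm(y ~ X)
  expect_equal(unname(m@coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-8)
  expect_equal(m@intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(predict(m, X)), unname(fitted(ref)), tolerance = 1e-8)
})

test_that("one-component PLS matches mixOmics", {
  skip_if_not_installed("mixOmics")
  X <- smallProblem$X
  y <- smallProblem$y
  for (A in 1:3) {
    m <- fitPLS(X, y, A = A)
    ref <- mixOmics::pls(X, y, ncomp = A, mode = "regression",
                         scale = TRUE)
    pref <- predict(ref, X)$predict[, 1, A]
    expect_equal(unname(predict(m, X)), unname(pref), tolerance = 1e-6)
  }
})

test_that("VIP scores satisfy the sum rule and rank signal above noise", {
  m <- fitPLS(smallProblem$X, smallProblem$y, A = 2)
  v <- vip(m)
  expect_equal(sum(v^2), ncol(smallProblem$X), tolerance = 1e-9)
  expect_gt(v["x1"], v["x3"])  # x3 is noise
})

test_that("fitPLS rejects degenerate inputs and truncates at rank", {
  X <- smallProblem$X
  y <- smallProblem$y
  expect_error(fitPLS(rbind(X, NA), c(y, 1), 2), "missing")
  expect_error(fitPLS(X, rep(1, nrow(X)), 2), "zero-variance")
  expect_warning(m <- fitPLS(X, y, A = 10), "truncated")
  expect_lte(m@ncomp, ncol(X))
})

test_that("predict dispatches on matrices, vectors and CompoundSets", {
  m <- fitPLS(smallProblem$X, smallProblem$y, A = 2)
  row1 <- smallProblem$X[1, ]
  expect_equal(predict(m, row1), predict(m, smallProblem$X)[1])
  expect_error(predict(m, smallProblem$X[, 1:2]), "missing descriptors")
  sub <- sharedCS[1:5]
  m2 <- fitPLS(descriptorValues(sharedCS), responses(sharedCS)$t1R, 2)
  expect_equal(predict(m2, sub),
               predict(m2, descriptorValues(sharedCS)[1:5, ]))
})

test_that("selectComponents picks more components for richer structure", {
  set.seed(11)
  n <- 120
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y1 <- 3 * X[, 1] + rnorm(n, 0, 0.5)
  y3 <- 3 * X[, 1] - 2 * X[, 2] + X[, 3] + rnorm(n, 0, 0.5)
  s1 <- selectComponents(X, y1, seed = 1)
  s3 <- selectComponents(X, y3, seed = 1)
  expect_gte(s3$A, 3)
  ## parsimony: stops well before the examined maximum once flat
  expect_lte(s1$A, 4)
  ## the chosen model is within 10% of the best cross-validated error
  expect_lte(s1$record$RMSE_CV[s1$A], 1.1 * min(s1$record$RMSE_CV))
  expect_lte(s3$record$RMSE_CV[s3$A], 1.1 * min(s3$record$RMSE_CV))
  expect_named(s1$record, c("ncomp", "Q2", "RMSE_CV"))
  expect_true(all(diff(s1$record$Q2[1:s1$A]) >= 0))
})

test_that("selectComponents returns A = 1 for a pure-noise response", {
  set.seed(12)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- rnorm(60)
  s <- selectComponents(X, y, seed = 1)
  expect_equal(s$A, 1L)
})

test_that("jackknife half-widths cover a strong coefficient, flag a null one", {
  set.seed(13)
  n <- 140
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("big", "nil", "n2")))
  y <- 5 * X[, "big"] + rnorm(n, 0, 0.2)
  m <- fitPLS(X, y, 3)
  hw <- coefficientUncertainty(X, y, A = 3, seed = 1)
  expect_named(hw, colnames(X))
  expect_true(all(hw >= 0))
  expect_lt(hw["big"], abs(m@coefficients["big"]))   # precise signal
  expect_gt(hw["nil"], abs(m@coefficients["nil"]))   # indistinct from zero
})

test_that("pruning removes noise descriptors and keeps the signal", {
  set.seed(14)
  n <- 150
  X <- cbind(sig1 = rnorm(n), sig2 = rnorm(n),
             matrix(rnorm(6 * n), n, 6,
                    dimnames = list(NULL, paste0("junk", 1:6))))
  y <- 4 * X[, "sig1"] - 3 * X[, "sig2"] + rnorm(n, 0, 0.3)
  for (strategy in c("uncertainty", "importance", "stepwise")) {
    pr <- suppressWarnings(pruneDescriptors(X, y, strategy, seed = 1))
    ## the dominant descriptor always survives; no junk survives the
    ## one-shot strategies, and stepwise iterates until VIP/uncertainty
    ## criteria hold (which can also sacrifice the weaker true descriptor)
    expect_true("sig1" %in% pr$kept, label = strategy)
    expect_lt(length(pr$kept), ncol(X))
    expect_setequal(c(pr$kept, pr$dropped), colnames(X))
    expect_equal(pr$history$n_descriptors[1], ncol(X))
    if (strategy != "stepwise")
      expect_true("sig2" %in% pr$kept, label = strategy)
    else
      expect_false(any(grepl("^junk", pr$kept)))
  }
})

test_that("group models dispatch locally and fall back to global", {
  gm <- fitGroupModels(sharedCS, "t2R", seed = 7)
  expect_s4_class(gm$global, "PLSModel")
  expect_equal(gm$global@scope, "global")
  info <- compoundInfo(sharedCS)
  big <- names(which(table(info$group[info$set == "training"]) >= 14))
  for (g in big) expect_s4_class(gm$groups[[paste0("group_", g)]], "PLSModel")
  pred <- predictGrouped(gm, sharedCS[1:20])
  expect_equal(nrow(pred), 20)
  expect_equal(pred$flagged, pred$model == "global")
  ## compounds of modelled groups use their local model
  gl <- info$group[1:20]
  has_local <- !is.na(gl) & paste0("group_", gl) %in%
    names(Filter(Negate(is.null), gm$groups))
  expect_equal(pred$model[has_local], paste0("group_", gl[has_local]))
})
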