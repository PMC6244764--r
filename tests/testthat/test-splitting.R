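test_that("runPCA matches prcomp up to the sign convention", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5,
              dimnames = list(paste0("c", 1:40), paste0("d", 1:5)))
  p <- runPCA(X, 3)
  ref <- prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(abs(p@loadings), abs(unname(ref$rotation[, 1:3])),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(abs(p@scores), abs(unname(ref$x[, 1:3])),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(p@explained,
               unname(ref$sdev[1:3]^2 / sum(ref$sdev^2)), tolerance = 1e-9)
  ## deterministic sign: largest-|loading| entry positive
  for (j in 1:3) expect_gt(p@loadings[which.max(abs(p@loadings[, j])), j], 0)
})

test_that("runPCA reduces the component count to the rank with a warning", {
  X <- cbind(a = 1:10, b = 2 * (1:10) + 0.001 * rnorm(10))
  rownames(X) <- paste0("c", 1:10)
  expect_warning(p <- runPCA(X, 5), "rank")
  expect_lte(ncol(p@scores), 2)
})

test_that("projectPCA reproduces the training scores", {
  X <- descriptorValues(sharedData$compounds)[1:50, ]
  p <- runPCA(X, 3)
  expect_equal(projectPCA(p, X), p@scores, tolerance = 1e-9)
})

test_that("systematic split partitions every compound into exactly one set", {
  a <- assignmentTable(sharedSplit)
  expect_setequal(a$compound_id, compoundIds(sharedData$compounds))
  expect_false(anyNA(a$set))
  expect_true(all(a$set %in% c("training", "test", "external_validation")))
  expect_false(any(duplicated(a$compound_id)))
  ## all three sets are populated, training is the largest
  tab <- table(a$set)
  expect_length(tab, 3)
  expect_equal(names(which.max(tab)), "training")
})

test_that("split is deterministic in the seed", {
  s1 <- systematicSplit(sharedData$compounds, sharedPCA, seed = 99)
  s2 <- systematicSplit(sharedData$compounds, sharedPCA, seed = 99)
  s3 <- systematicSplit(sharedData$compounds, sharedPCA, seed = 100)
  expect_identical(assignmentTable(s1), assignmentTable(s2))
  expect_false(identical(assignmentTable(s1)$set, assignmentTable(s3)$set))
})

test_that("split does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(systematicSplit(sharedData$compounds, sharedPCA, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("PCB rule keeps two congeners per chlorination level", {
  info <- compoundInfo(sharedData$compounds)
  a <- assignmentTable(sharedSplit)
  for (lev in sort(unique(na.omit(info$pcb_chlorine)))) {
    members <- info$compound_id[!is.na(info$pcb_chlorine) &
                                  info$pcb_chlorine == lev]
    forced <- a$provenance[match(members, a$compound_id)] == "pcb_rule"
    if (length(members) > 2) {
      expect_equal(sum(!forced), 2)
      expect_true(all(a$set[match(members[forced], a$compound_id)] ==
                        "external_validation"))
    }
  }
})

test_that("systematic pass assigns by the documented position rule", {
  ## hand-built set: 45 compounds, no PCBs, scores = identity ordering
  n <- 45
  ids <- sprintf("c%02d", 1:n)
  v <- cbind(d1 = seq_len(n), d2 = rnorm(n, 0, 1e-3))
  rownames(v) <- ids
  cs <- compoundSet(data.frame(compound_id = ids),
                    data.frame(t1R = 100 + seq_len(n)), descriptorTable(v))
  p <- suppressWarnings(runPCA(v, 2))
  a <- assignmentTable(systematicSplit(cs, p, seed = 1))
  ord <- order(p@scores[, 1])
  ## every fifth position of the component-1 pass goes to training
  pass1 <- a[match(ids[ord], a$compound_id), ]
  pos <- seq_len(n)
  expect_true(all(pass1$set[pos %% 5 == 0] == "training"))
  expect_true(all(pass1$provenance[pos %% 5 == 0] == "component_1"))
  expect_true(all(pass1$set[pos %% 5 != 0 & pos %% 8 == 0] == "test"))
  expect_true(all(pass1$set[pos %% 5 != 0 & pos %% 8 != 0 & pos %% 9 == 0] ==
                    "external_validation"))
})

test_that("coverageCheck reports the test range covered by training", {
  cov <- coverageCheck(sharedSplit, sharedPCA)
  expect_equal(cov$component, 1:2)
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 1))
  ## the pass over component 1 guarantees near-complete coverage there;
  ## later components are only partly controlled
  expect_false(cov$flagged[1])
  expect_gte(cov$coverage[2], 0.8)
  expect_equal(cov$flagged, cov$coverage < 0.9)
})

test_that("applySplit validates coverage", {
  short <- methods::new("SplitAssignment",
    assignment = assignmentTable(sharedSplit)[1:10, ])
  expect_error(applySplit(sharedData$compounds, short), "cover")
})
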