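kbProps <- c("bp", "logKow", "MW", "E", "S", "A", "B", "L")
trainRows <- which(compoundInfo(sharedCS)$set == "training")
sharedKB <- buildKnowledgeBase(sharedCS, properties = kbProps,
                               rows = trainRows)
rawProps <- descriptorValues(sharedCS)[trainRows, kbProps]

test_that("similarity metrics live on [0,1] and reach 1 at identity", {
  a <- c(0.2, 0.8, 0.5)
  expect_equal(similarity(a, a, "dice"), 1)
  expect_equal(similarity(a, a, "euclidean"), 1)
  expect_equal(similarity(a, c(0, 0, 0), "dice"), 0)
  b <- c(0.9, 0.1, 0.4)
  expect_equal(similarity(a, b, "dice"), 2 * sum(a * b) / (sum(a^2) + sum(b^2)))
  expect_equal(similarity(a, b, "euclidean"), 1 / (1 + sqrt(sum((a - b)^2))))
  expect_error(similarity(a, b[1:2]), "length")
})

test_that("selectNeighbors returns k entries, most similar first", {
  fc <- federationConfig("euclidean", k = 10)
  q <- rawProps[1, ]
  nb <- selectNeighbors(sharedKB, q, fc, query_id = rownames(rawProps)[1])
  expect_equal(nrow(nb), 10)
  expect_false(rownames(rawProps)[1] %in% nb$compound_id)  # self excluded
  expect_true(all(diff(nb$similarity) <= 0))
  ## with self included the query itself is the top hit
  nb2 <- selectNeighbors(sharedKB, q, fc, query_id = rownames(rawProps)[1],
                         include_self = TRUE)
  expect_equal(nb2$compound_id[1], rownames(rawProps)[1])
  expect_equal(nb2$similarity[1], 1)
})

test_that("dice neighbourhoods differ from euclidean ones but overlap", {
  q <- rawProps[5, ]
  nbd <- selectNeighbors(sharedKB, q, federationConfig("dice", k = 25),
                         query_id = rownames(rawProps)[5])
  nbe <- selectNeighbors(sharedKB, q, federationConfig("euclidean", k = 25),
                         query_id = rownames(rawProps)[5])
  expect_true(all(nbd$similarity >= 0 & nbd$similarity <= 1))
  expect_gt(length(intersect(nbd$compound_id, nbe$compound_id)), 5)
})

test_that("neighbourhood larger than the knowledge base is rejected", {
  fc <- federationConfig("dice", k = length(sharedKB@ids) + 1)
  expect_error(selectNeighbors(sharedKB, rawProps[1, ], fc), "smaller")
})

test_that("property-set selectors restrict the active properties", {
  q <- rawProps[3, ]
  for (ps in c("all", "no_abraham", "abraham_only")) {
    fc <- federationConfig("euclidean", k = 5, m = 2, propertySet = ps)
    nb <- selectNeighbors(sharedKB, q, fc)
    expect_equal(nrow(nb), 5)
  }
  emptyKB <- buildKnowledgeBase(sharedCS, properties = c("E", "S"),
                                rows = trainRows)
  fc <- federationConfig("euclidean", k = 5, m = 2,
                         propertySet = "no_abraham")
  expect_error(selectNeighbors(emptyKB, q[c("E", "S")], fc), "no properties")
})

test_that("local model respects the compounds-per-parameter cap", {
  fc <- federationConfig("euclidean", k = 25, m = 4)
  lp <- predictFederated(sharedKB, rawProps[2, ], fc, "t1R",
                         query_id = rownames(rawProps)[2])
  expect_s4_class(lp, "LocalPrediction")
  expect_lte(length(lp@parameters), floor(25 / 4))
  expect_true(is.finite(lp@predicted))
  expect_gte(lp@localRMSE, 0)
})

test_that("constant neighbour properties fall back to the neighbour mean", {
  ids <- sprintf("k%02d", 1:12)
  ## one outlying entry: the 10 neighbours of k01 share identical properties
  v <- cbind(p1 = c(rep(1, 11), 5))
  rownames(v) <- ids
  cs <- compoundSet(data.frame(compound_id = ids),
                    data.frame(t1R = 600 + 1:12), descriptorTable(v))
  kb <- buildKnowledgeBase(cs)
  fc <- federationConfig("euclidean", k = 10, m = 4)
  lp <- predictFederated(kb, v[1, , drop = FALSE], fc, "t1R",
                         query_id = "k01")
  expect_equal(lp@flag, "constant_properties")
  nb <- match(lp@neighbors$compound_id, ids)
  expect_equal(lp@predicted, mean((600 + 1:12)[nb]))
})

test_that("leave-one-out federation beats the mean baseline", {
  fc <- federationConfig("dice", k = 25, m = 4)
  loo <- looFederated(sharedKB, fc, "t1R", rawProps)
  expect_equal(loo$compound_id, sharedKB@ids)
  fed <- rmsep(loo$observed, loo$predicted)
  base <- rmsep(loo$observed, rep(mean(loo$observed), nrow(loo)))
  expect_lt(fed, base / 3)
})

test_that("unknown response is rejected", {
  fc <- federationConfig("dice", k = 10)
  expect_error(predictFederated(sharedKB, rawProps[1, ], fc, "nope"),
               "unknown response")
})
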