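## shared synthetic study used across test files: one dataset, one split
sharedConfig <- syntheticConfig(seed = 42)
sharedData <- generateDataset(sharedConfig)
sharedPCA <- runPCA(descriptorValues(sharedData$compounds), 5)
sharedSplit <- systematicSplit(sharedData$compounds, sharedPCA, seed = 142)
sharedCS <- applySplit(sharedData$compounds, sharedSplit)

rmsep <- function(obs, pred) sqrt(sum((obs - pred)^2) / (length(obs) - 1))

## a small deterministic regression problem for unit-level tests
smallProblem <- local({
  set.seed(7)
  n <- 40
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 + 1.5 * X[, "x1"] - 0.8 * X[, "x2"] + 0.1 * rnorm(n)
  list(X = X, y = y)
})
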