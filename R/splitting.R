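#' @include AllClasses.R
NULL

#' Principal component analysis of an autoscaled descriptor matrix
#'
#' SVD-based PCA. The input is centered (and unit-variance scaled unless
#' already autoscaled) internally; component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param X numeric matrix compounds x descriptors (raw or scaled; scaling
#'   is refit here on all rows of `X`).
#' @param n_components number of components to retain (default 5). Reduced
#'   with a warning when it exceeds the matrix rank.
#' @param scale logical, divide by the sample SD (default TRUE).
#' @return a [PCAModel-class]
#' @export
runPCA <- function(X, n_components = 5, scale = TRUE) {
  ctr <- colMeans(X)
  sdv <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  keep <- sdv > 0
  if (!all(keep)) {
    X <- X[, keep, drop = FALSE]
    ctr <- ctr[keep]
    sdv <- sdv[keep]
  }
  Z <- sweep(sweep(X, 2, ctr), 2, sdv, `/`)
  sv <- svd(Z)
  rank <- sum(sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1])
  if (n_components > rank) {
    warning(sprintf("n_components reduced from %d to rank %d",
                    n_components, rank))
    n_components <- rank
  }
  a <- seq_len(n_components)
  load <- sv$v[, a, drop = FALSE]
  scores <- sv$u[, a, drop = FALSE] %*% diag(sv$d[a], n_components)
  ## deterministic sign: largest-|loading| entry positive per component
  for (j in a) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(load) <- colnames(X)
  rownames(scores) <- rownames(X)
  colnames(load) <- colnames(scores) <- paste0("PC", a)
  explained <- sv$d[a]^2 / sum(sv$d^2)
  methods::new("PCAModel", loadings = load, scores = scores,
               explained = explained, center = ctr, scale = sdv)
}

#' Project new rows onto a fitted PCA
#'
#' @param pca a [PCAModel-class]
#' @param X matrix with named columns covering the PCA descriptors.
#' @return scores matrix (rows x components)
#' @export
projectPCA <- function(pca, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  nm <- rownames(pca@loadings)
  Z <- sweep(sweep(X[, nm, drop = FALSE], 2, pca@center), 2, pca@scale, `/`)
  Z %*% pca@loadings
}

#' Systematic training/test/external-validation split along PCA scores
#'
#' PCBs are handled first: per chlorination level, two congeners (seeded
#' random choice) stay in the general pool and all others are pre-assigned
#' to the external validation set, avoiding over-training on the PCB
#' homologue pattern. The remaining compounds are then sorted in ascending
#' order of the component-1 scores and walked in 1-based positions: every
#' fifth goes to training, otherwise every eighth to test, otherwise every
#' ninth to external validation. Assigned compounds leave the pool, and the
#' pass is repeated on components 2, 3 and 4. Leftovers are assigned
#' uniformly at random (seeded) among the three sets.
#'
#' @param cs a [CompoundSet-class]; PCB rows are identified by a non-NA
#'   `pcb_chlorine` level in the info table.
#' @param pca a [PCAModel-class] whose scores rows align with `cs` (at least
#'   4 components for the standard rule).
#' @param seed integer seed for the PCB choice and the leftover assignment.
#' @return a [SplitAssignment-class]
#' @export
systematicSplit <- function(cs, pca, seed) {
  stopifnot(is(cs, "CompoundSet"), is(pca, "PCAModel"))
  info <- cs@info
  if (nrow(info) == 0) stop("empty compound set")
  scores <- pca@scores
  if (nrow(scores) != nrow(info))
    stop("every record needs PCA scores")
  ids <- info$compound_id
  set <- stats::setNames(rep(NA_character_, length(ids)), ids)
  prov <- stats::setNames(rep(NA_character_, length(ids)), ids)
  rng <- .seededRNG(seed)

  ## (1) PCB rule: all except two per chlorination level go to validation
  ispcb <- !is.na(info$pcb_chlorine)
  if (any(ispcb)) {
    if (!is.numeric(info$pcb_chlorine))
      stop("PCB chlorination level must be numeric")
    for (lev in sort(unique(info$pcb_chlorine[ispcb]))) {
      members <- which(ispcb & info$pcb_chlorine == lev)
      if (length(members) > 2) {
        keep <- .rngSample(rng, members, 2)
        forced <- setdiff(members, keep)
        set[forced] <- "external_validation"
        prov[forced] <- "pcb_rule"
      }
    }
  }

  ## (2) systematic passes over components 1..4
  ncomp <- min(4L, ncol(scores))
  for (comp in seq_len(ncomp)) {
    pool <- which(is.na(set))
    if (!length(pool)) break
    pool <- pool[order(scores[pool, comp])]
    pos <- seq_along(pool)
    lab <- rep(NA_character_, length(pool))
    lab[pos %% 5 == 0] <- "training"
    lab[is.na(lab) & pos %% 8 == 0] <- "test"
    lab[is.na(lab) & pos %% 9 == 0] <- "external_validation"
    hit <- !is.na(lab)
    set[pool[hit]] <- lab[hit]
    prov[pool[hit]] <- paste0("component_", comp)
  }

  ## (3) leftovers uniformly at random
  pool <- which(is.na(set))
  if (length(pool)) {
    set[pool] <- .rngChoice(rng,
                            c("training", "test", "external_validation"),
                            length(pool))
    prov[pool] <- "random_remainder"
  }
  methods::new("SplitAssignment",
               assignment = data.frame(compound_id = ids,
                                       set = unname(set),
                                       provenance = unname(prov),
                                       stringsAsFactors = FALSE))
}

## local RNG helpers: keep the split deterministic without touching the
## caller's global RNG state
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  env
}

.withRNG <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

.rngSample <- function(rng, x, size) .withRNG(rng, sample(x, size))

.rngChoice <- function(rng, values, n)
  .withRNG(rng, sample(values, n, replace = TRUE))

#' Check that the split covers descriptor space evenly
#'
#' For the leading principal components, reports the fraction of the
#' test-set score range contained within the training-set score range; a
#' well-constructed systematic split keeps the test set inside the space
#' the model is trained on.
#'
#' @param assignment a [SplitAssignment-class]
#' @param pca a [PCAModel-class] whose score rownames are compound ids.
#' @param components integer vector of components to report (default 1:2).
#' @param threshold flag coverage below this value (default 0.9).
#' @return data.frame with `component`, `coverage`, `flagged`.
#' @export
coverageCheck <- function(assignment, pca, components = 1:2,
                          threshold = 0.9) {
  a <- assignment@assignment
  sc <- pca@scores
  tr <- a$compound_id[a$set == "training"]
  te <- a$compound_id[a$set == "test"]
  if (length(tr) < 2 || length(te) < 2)
    stop("at least 2 records per set required")
  out <- lapply(components, function(comp) {
    rtr <- range(sc[tr, comp])
    rte <- range(sc[te, comp])
    overlap <- max(0, min(rtr[2], rte[2]) - max(rtr[1], rte[1]))
    width <- diff(rte)
    cov <- if (width == 0) as.numeric(rte[1] >= rtr[1] && rte[1] <= rtr[2])
           else overlap / width
    data.frame(component = comp, coverage = cov,
               flagged = cov < threshold)
  })
  do.call(rbind, out)
}
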