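#' @include AllClasses.R containers.R indexing.R
NULL

#' Configuration of the synthetic GCxGC compound-set generator
#'
#' The generative model mirrors the structure the analysis assumes:
#' first-dimension retention is driven by a volatility latent, mapped
#' linearly onto the temperature-programmed run; second-dimension retention
#' is the non-polar baseline at the analyte's elution temperature plus
#' polarity and polarizability contributions and a positive offset for
#' halogenated compounds. Compound classes are 1 = fluorinated,
#' 2 = chlorinated/brominated (incl. a PCB-like homologue family),
#' 3 = long carbon-chain homologous series, 4 = remainder.
#'
#' @param n_compounds number of compounds (default 600).
#' @param n_base_descriptors total descriptor count (default 150), of which
#'   `noise_fraction` are pure noise and 8 are the named physico-chemical
#'   anchors (`bp`, `logKow`, `MW`, `nC` and the Abraham parameters `E`,
#'   `S`, `A`, `B`, `L` minus overlaps).
#' @param seed mandatory integer seed; the whole dataset is a deterministic
#'   function of it.
#' @param sigma_t1,sigma_t2 response noise SDs, seconds (defaults 30 and
#'   0.15).
#' @param sigma_t1_series,sigma_t2_series response noise SDs for the
#'   homologous-series group 3, which behaves almost deterministically in
#'   chain length (defaults 4 and 0.02).
#' @param fluor_t2_inflation multiplier on `sigma_t2` for fluorinated
#'   compounds (default 2.5), reflecting their larger second-dimension
#'   scatter.
#' @param group_weights mixture weights of groups 1-4 (must sum to 1).
#' @param group3_t1_shift,group3_t2_shift constant retention offsets (s) of
#'   the homologous-series group relative to the global mapping (defaults 0
#'   and 0.5): stationary-phase interactions specific to long-chain
#'   homologues that no descriptor encodes, so a global linear model cannot
#'   remove them while a group-local model absorbs them into its intercept.
#'   The second-dimension offset is where local models shine, the
#'   first-dimension mapping is shared.
#' @param halo_t2_offset positive second-dimension offset (s) for
#'   halogenated groups 1-2 (default 0.25).
#' @param c_polarity,d_polarizability effect sizes (s per latent unit) in
#'   the second dimension (defaults 0.55 and 0.35).
#' @param sigma_descriptor noise SD of the informative descriptor columns
#'   on the latent scale (default 0.01), kept small relative to the
#'   retention noise so that a recovery study measures the injected noise,
#'   not descriptor error.
#' @param sigma_bp noise SD of the boiling-point proxy, expressed in
#'   seconds of first-dimension retention (default 50): the single-predictor
#'   reference model is informative but clearly worse than a multivariate
#'   model, as for estimated boiling points of diverse chemistry.
#' @param noise_fraction fraction of descriptors that are pure noise
#'   (default 0.3), so descriptor pruning has work to do.
#' @param t_start,ramp,t_final,hold_min temperature program constants:
#'   35 degC start, 0.2 min hold, 5 degC/min ramp, 310 degC final.
#' @param t1_C8,t1_per_carbon alkane anchors: C8 elutes at 400 s, one
#'   carbon adds 2900/22 s (C8..C30 span the run).
#' @return validated configuration list (class `qsrr2dConfig`)
#' @export
syntheticConfig <- function(n_compounds = 600, n_base_descriptors = 150,
                            seed, sigma_t1 = 30, sigma_t2 = 0.15,
                            sigma_t1_series = 4, sigma_t2_series = 0.02,
                            fluor_t2_inflation = 2.5,
                            group_weights = c(0.10, 0.25, 0.20, 0.45),
                            group3_t1_shift = 0, group3_t2_shift = 0.5,
                            halo_t2_offset = 0.25,
                            c_polarity = 0.55, d_polarizability = 0.35,
                            sigma_descriptor = 0.01, sigma_bp = 50,
                            noise_fraction = 0.3,
                            t_start = 35, ramp = 5, t_final = 310,
                            hold_min = 0.2,
                            t1_C8 = 400, t1_per_carbon = 2900 / 22) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(group_weights) - 1) > 1e-8)
    stop("group weights must sum to 1")
  if (any(c(sigma_t1, sigma_t2, sigma_t1_series, sigma_t2_series,
            sigma_descriptor, sigma_bp) < 0))
    stop("noise SDs must be non-negative")
  cfg <- list(n_compounds = n_compounds,
              n_base_descriptors = n_base_descriptors, seed = as.integer(seed),
              sigma_t1 = sigma_t1, sigma_t2 = sigma_t2,
              sigma_t1_series = sigma_t1_series,
              sigma_t2_series = sigma_t2_series,
              fluor_t2_inflation = fluor_t2_inflation,
              group_weights = group_weights,
              group3_t1_shift = group3_t1_shift,
              group3_t2_shift = group3_t2_shift,
              halo_t2_offset = halo_t2_offset,
              c_polarity = c_polarity, d_polarizability = d_polarizability,
              sigma_descriptor = sigma_descriptor, sigma_bp = sigma_bp,
              noise_fraction = noise_fraction,
              t_start = t_start, ramp = ramp, t_final = t_final,
              hold_min = hold_min, t1_C8 = t1_C8,
              t1_per_carbon = t1_per_carbon)
  class(cfg) <- "qsrr2dConfig"
  cfg
}

## elution temperature (degC) after t1 seconds of the temperature program
.elutionTemp <- function(t1, cfg) {
  pmin(cfg$t_start + cfg$ramp * (t1 / 60 - cfg$hold_min), cfg$t_final)
}

## non-polar (alkane) second-dimension baseline at first-dimension time t1
.t2Baseline <- function(t1, cfg) {
  2.0 - 0.002 * (.elutionTemp(t1, cfg) - cfg$t_start)
}

## volatility latent -> first-dimension time; u = 0 is alkane C8, u = 1 C30
.t1FromVolatility <- function(u, cfg) {
  runEnd <- 60 * (cfg$hold_min + (cfg$t_final - cfg$t_start) / cfg$ramp) +
    12 * 60
  pmin(pmax(cfg$t1_C8 + 22 * cfg$t1_per_carbon * u, 60), runEnd)
}

#' Noiseless retention model of the synthetic generator
#'
#' @param latents data.frame (or list) with `volatility`, `polarity`,
#'   `polarizability` (volatility on the 0..1 scale where 0 is alkane C8
#'   and 1 alkane C30).
#' @param group integer vector of group labels 1-4.
#' @param config a [syntheticConfig()] list.
#' @return data.frame with noiseless `t1` and `t2` (seconds)
#' @export
trueRetentionModel <- function(latents, group, config) {
  u <- latents$volatility
  t1 <- .t1FromVolatility(u, config) +
    ifelse(group == 3, config$group3_t1_shift, 0)
  t2 <- .t2Baseline(t1, config) +
    config$c_polarity * latents$polarity +
    config$d_polarizability * latents$polarizability +
    ifelse(group %in% c(1, 2), config$halo_t2_offset, 0) +
    ifelse(group == 3, config$group3_t2_shift, 0)
  data.frame(t1 = t1, t2 = t2)
}

#' Reference-standard series of the synthetic instrument
#'
#' Alkanes C8..C30 on the volatility mapping with second-dimension times on
#' the non-polar baseline, and PEG-3..PEG-10 on a parallel line 2.5 s above
#' it. Both series are noiseless, as reference standards measured with
#' dedicated runs.
#'
#' @param config a [syntheticConfig()] list.
#' @return a [ReferenceSeries-class]
#' @export
syntheticReferenceSeries <- function(config) {
  carbons <- 8:30
  t1a <- config$t1_C8 + config$t1_per_carbon * (carbons - 8)
  eo <- 3:10
  t1p <- 700 + 200 * eo
  referenceSeries(
    alkanes = data.frame(carbon = carbons, t1 = t1a),
    pegs = data.frame(eo = eo, t1 = t1p,
                      t2 = .t2Baseline(t1p, config) + 2.5),
    alkane2d = data.frame(t1 = t1a, t2 = .t2Baseline(t1a, config)))
}

#' Generate a synthetic compound dataset with ground truth
#'
#' Draws latent volatility/polarity/polarizability per compound, assigns
#' groups by the configured mixture, builds descriptor columns as noisy
#' linear images of the latents (plus named physico-chemical anchors and
#' pure-noise columns), simulates noisy retention times, and indexes every
#' compound against the synthetic reference series. A PCB-like homologue
#' family inside group 2 carries chlorination levels so the splitting
#' rule can be exercised.
#'
#' @param config a [syntheticConfig()] list.
#' @return list with `compounds` (a [CompoundSet-class] carrying `t1R`,
#'   `t2R`, `LRI`, `PEG2I`), `series` (the [ReferenceSeries-class]) and
#'   `truth` (data.frame of latents, group and noiseless responses).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "qsrr2dConfig"))
  n <- config$n_compounds
  if (n < 50) warning("fewer than 50 compounds: splits become degenerate")
  rng <- .seededRNG(config$seed)
  .withRNG(rng, {
    group <- sample(1:4, n, replace = TRUE, prob = config$group_weights)
    ## latents
    u <- runif(n, 0.02, 0.98)
    chain <- sample(8:30, n, replace = TRUE)
    seriesId <- sample(1:3, n, replace = TRUE)
    g3 <- group == 3
    u[g3] <- (chain[g3] - 8) / 22
    polarity <- 0.9 * abs(rnorm(n))
    polarity[g3] <- c(0.05, 0.15, 0.25)[seriesId[g3]]
    polarizability <- 0.6 * abs(rnorm(n))
    polarizability[g3] <- 0.1 + 0.02 * (chain[g3] - 8)
    truth0 <- trueRetentionModel(
      data.frame(volatility = u, polarity = polarity,
                 polarizability = polarizability), group, config)

    ## response noise
    s1 <- ifelse(g3, config$sigma_t1_series, config$sigma_t1)
    s2 <- ifelse(g3, config$sigma_t2_series,
                 ifelse(group == 1,
                        config$sigma_t2 * config$fluor_t2_inflation,
                        config$sigma_t2))
    t1R <- pmax(truth0$t1 + rnorm(n, 0, s1), 60)
    t2R <- pmax(truth0$t2 + rnorm(n, 0, s2), 0.3)

    ## descriptors
    span <- 22 * config$t1_per_carbon
    named <- cbind(
      bp = 50 + 300 * u + rnorm(n, 0, 300 * config$sigma_bp / span),
      logKow = -1 + 9 * u - 1.5 * polarity + rnorm(n, 0, 0.2),
      MW = 80 + 400 * u + rnorm(n, 0, 8),
      nC = ifelse(g3, chain, pmax(1, round(3 + 20 * u + rnorm(n, 0, 1.5)))),
      E = polarizability + rnorm(n, 0, config$sigma_descriptor),
      S = polarity + rnorm(n, 0, config$sigma_descriptor),
      A = abs(rnorm(n, 0, 0.3)),
      B = 0.3 * polarity + abs(rnorm(n, 0, 0.2)),
      L = 3 + 10 * u + rnorm(n, 0, 10 * config$sigma_descriptor))
    nNoise <- round(config$noise_fraction * config$n_base_descriptors)
    nInfo <- max(0, config$n_base_descriptors - ncol(named) - nNoise)
    L3 <- cbind(u, polarity, polarizability)
    coef <- matrix(runif(3 * nInfo, -1, 1), 3, nInfo)
    info <- L3 %*% coef +
      matrix(rnorm(n * nInfo, 0, config$sigma_descriptor), n, nInfo)
    colnames(info) <- sprintf("d%03d", seq_len(nInfo))
    noise <- matrix(rnorm(n * nNoise), n, nNoise)
    colnames(noise) <- sprintf("z%03d", seq_len(nNoise))
    values <- cbind(named, info, noise)
    ids <- sprintf("CMP%04d", seq_len(n))
    rownames(values) <- ids

    ## a PCB-like homologue family inside group 2 with chlorination levels
    pcb <- rep(NA_integer_, n)
    g2 <- which(group == 2)
    npcb <- round(0.4 * length(g2))
    if (npcb > 0) {
      sel <- sample(g2, npcb)
      pcb[sel] <- sample(1:10, npcb, replace = TRUE)
    }

    cinfo <- data.frame(compound_id = ids,
                        name = paste0("synthetic-", ids),
                        smiles = NA_character_, group = group,
                        pcb_chlorine = pcb, set = NA_character_,
                        stringsAsFactors = FALSE)
    cs <- compoundSet(cinfo,
                      data.frame(t1R = t1R, t2R = t2R),
                      descriptorTable(values))
    series <- syntheticReferenceSeries(config)
    cs <- indexCompoundSet(cs, series)
    truth <- data.frame(compound_id = ids, volatility = u,
                        polarity = polarity,
                        polarizability = polarizability,
                        chain = ifelse(g3, chain, NA_integer_),
                        group = group, t1_true = truth0$t1,
                        t2_true = truth0$t2, stringsAsFactors = FALSE)
    list(compounds = cs, series = series, truth = truth)
  })
}
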