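test_that("the generator is a deterministic function of its seed", {
  d1 <- generateDataset(syntheticConfig(n_compounds = 80, seed = 5))
  d2 <- generateDataset(syntheticConfig(n_compounds = 80, seed = 5))
  d3 <- generateDataset(syntheticConfig(n_compounds = 80, seed = 6))
  expect_identical(descriptorValues(d1$compounds),
                   descriptorValues(d2$compounds))
  expect_identical(responses(d1$compounds), responses(d2$compounds))
  expect_false(identical(responses(d1$compounds)$t1R,
                         responses(d3$compounds)$t1R))
})

test_that("the seed is mandatory and configs are validated", {
  expect_error(syntheticConfig(), "seed")
  expect_error(syntheticConfig(seed = 1, group_weights = c(1, 1, 1, 1)),
               "sum to 1")
  expect_error(syntheticConfig(seed = 1, sigma_t1 = -1), "non-negative")
})

test_that("generated sets have the advertised shape", {
  cfg <- syntheticConfig(n_compounds = 120, seed = 9)
  d <- generateDataset(cfg)
  cs <- d$compounds
  expect_equal(length(compoundIds(cs)), 120)
  expect_equal(ncol(descriptorValues(cs)), cfg$n_base_descriptors)
  expect_setequal(names(responses(cs)), c("t1R", "t2R", "LRI", "PEG2I"))
  info <- compoundInfo(cs)
  expect_true(all(info$group %in% 1:4))
  expect_true(any(!is.na(info$pcb_chlorine)))   # PCB family present
  expect_true(all(is.na(info$pcb_chlorine) | info$group == 2))
  expect_equal(nrow(d$truth), 120)
  ## pure-noise columns are present for pruning to find
  expect_equal(sum(grepl("^z", colnames(descriptorValues(cs)))),
               round(cfg$noise_fraction * cfg$n_base_descriptors))
})

test_that("noiseless responses follow the declared physical model", {
  cfg <- syntheticConfig(seed = 1)
  tm <- trueRetentionModel(
    data.frame(volatility = c(0, 0.5, 1), polarity = 0, polarizability = 0),
    group = rep(4, 3), config = cfg)
  ## volatility maps linearly onto the alkane anchors C8..C30
  expect_equal(tm$t1, cfg$t1_C8 + 22 * cfg$t1_per_carbon * c(0, 0.5, 1))
  ## apolar compounds sit on the second-dimension baseline (within 2 s of 2.0)
  expect_true(all(tm$t2 < 2 & tm$t2 > 0))
  ## halogenated and homologous-series offsets are additive
  tmh <- trueRetentionModel(
    data.frame(volatility = 0.5, polarity = 0, polarizability = 0),
    group = 2, config = cfg)
  expect_equal(tmh$t2 - tm$t2[2], cfg$halo_t2_offset)
  tm3 <- trueRetentionModel(
    data.frame(volatility = 0.5, polarity = 0, polarizability = 0),
    group = 3, config = cfg)
  expect_equal(tm3$t2 - tm$t2[2], cfg$group3_t2_shift)
})

test_that("reference alkanes index at exactly 100 x carbon number", {
  cfg <- syntheticConfig(seed = 2)
  rs <- syntheticReferenceSeries(cfg)
  lri <- computeLRI(rs@alkanes$t1, rs)
  expect_equal(lri$value, 100 * rs@alkanes$carbon, tolerance = 1e-12)
})

test_that("a compound placed at a prescribed PEG-2I is recovered exactly", {
  cfg <- syntheticConfig(seed = 3)
  rs <- syntheticReferenceSeries(cfg)
  ln <- fitReferenceLines(rs)
  t1 <- c(1500, 2000, 2500)
  target <- c(25, 60, 110)
  base <- ln$baseline$intercept + ln$baseline$slope * t1
  peg <- ln$peg$intercept + ln$peg$slope * t1
  t2 <- base + target / 100 * (peg - base)
  expect_equal(computePEG2I(t1, t2, ln)$value, target, tolerance = 1e-9)
})

test_that("group 3 is a near-noiseless homologous series in chain length", {
  d <- generateDataset(syntheticConfig(seed = 4))
  tr <- d$truth[d$truth$group == 3, ]
  r <- responses(d$compounds)$t1R[match(tr$compound_id,
                                        compoundIds(d$compounds))]
  fit <- lm(r ~ tr$chain)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("small compound counts warn about degenerate splits", {
  expect_warning(generateDataset(syntheticConfig(n_compounds = 30, seed = 1)),
                 "degenerate")
})
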