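---
title: "Methods: retention prediction for GCxGC with qsrr2d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retention prediction for GCxGC with qsrr2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrr2d)
```

# The problem

Comprehensive two-dimensional gas chromatography (GCxGC) separates analytes
on two coupled columns: a long non-polar column whose first-dimension
retention time (`t1R`, seconds) mainly tracks volatility, and a short polar
column whose second-dimension retention time (`t2R`, seconds) mainly tracks
polarity and polarizability at the temperature the analyte happens to elute.
When an unknown peak is detected, candidate structures from a library can be
screened by predicting where each candidate *would* elute and discarding
candidates whose predicted retention is incompatible with the measurement.
qsrr2d implements such a quantitative structure-retention relationship
(QSRR) workflow end to end: retention indexing, descriptor engineering,
dataset splitting, latent-variable regression, a federated local-model
alternative, evaluation, and candidate screening.

# Retention indexing

Raw retention times depend on the instrument program, so they are converted
to indices anchored to reference-standard series.

**First dimension.** With a temperature-programmed run, the linear
retention index interpolates between consecutive n-alkanes
C~n~ and C~n+1~:

$$\mathrm{LRI} = 100\,n + 100\,\frac{t - t_n}{t_{n+1} - t_n},$$

so alkane C~n~ scores exactly $100n$ (`computeLRI()`). Outside the alkane
span the nearest segment is extrapolated linearly and the value is flagged:
an extrapolated index is still usable, but carries more uncertainty.

**Second dimension.** Because the second column's hold-up time changes with
elution temperature, a per-`t1` anchoring is used. Two straight lines are
fitted through the reference standards in the (`t1`, `t2`) plane
(`fitReferenceLines()`): the n-alkane second-dimension trace (the non-polar
baseline, index 0) and a polyethylene-glycol (PEG) series (index 100). An
analyte is then placed proportionally between the lines at its own `t1`:

$$\mathrm{PEG\mbox{-}2I} = 100\,
  \frac{t_2 - \mathrm{base}(t_1)}{\mathrm{peg}(t_1) - \mathrm{base}(t_1)}.$$

Values above 100 (more retained than the PEGs) and slightly below 0 (noise
around the baseline) are legitimate; geometry where the PEG line touches
the baseline is rejected as an error. When no alkane `t2` trace is
available, the baseline degrades to an intercept-only line at the minimum
observed reference `t2`.

# Descriptor engineering

Molecular descriptors arrive on wildly different scales and with size
confounds, so three preparation steps precede any regression
(`augmentWeightNormalized()`, `applyManualTransformations()`,
`autoscale()`):

1. **Weight normalisation** appends `<name>_perMW` variants (descriptor
   divided by molecular weight) so size-driven properties become comparable
   across molecular sizes.
2. **Linearising transformations** (log10 with a positivity shift, square
   root, reciprocal, square) are screened per descriptor against the
   response on the *training* rows; a transformed copy is appended only
   when it improves the absolute Pearson correlation by at least 0.05 (one
   best transform per descriptor, originals always kept). The margin keeps
   chance improvements out; transforms undefined on a column (e.g.
   reciprocal of zero) are skipped with a warning.
3. **Autoscaling** centers and scales to unit sample variance using
   training rows only; held-out compounds are scaled with the training
   parameters. Zero-variance columns are dropped and recorded; columns with
   more than 5% missing values are dropped, remaining gaps are imputed
   with the training median.

# Dataset splitting

Training, test and external-validation sets must each span the descriptor
space rather than be random slices. `systematicSplit()` first runs a PCA on
the autoscaled descriptors and then walks the compounds in ascending order
of their component-1 scores, sending every fifth compound to training,
otherwise every eighth to test, otherwise every ninth to external
validation. Assigned compounds leave the pool and the pass repeats on
components 2-4; the few leftovers are assigned uniformly at random under
the split seed. This yields roughly 46/26/28 proportions while forcing all
three sets to cover each leading component.

Homologue families are a known over-training hazard: dozens of near-identical
PCB congeners would let the model memorise the family. Therefore, before the
systematic passes, all but two (seeded choice) congeners per chlorination
level are pre-assigned to external validation. `coverageCheck()` audits the
result: it reports, per leading component, the fraction of the test score
range contained in the training range (flagged below 0.9).

# PLS regression

The core model is PLS1 regression fitted by NIPALS (`fitPLS()`), with
descriptors and response autoscaled internally and coefficients mapped back
to raw units, so predictions come out in seconds or index units. At the
full rank of X, PLS coincides with ordinary least squares - one of the test
oracles.

**Component selection** (`selectComponents()`) uses seven-group
cross-validation (contiguous blocks of a seeded shuffle). The classic rule
"add a component while Q2 improves by more than 0.01" is scale-blind:
retention responses span thousands of seconds while the noise floor is tens
of seconds, so Q2 saturates near 1 long before the noise floor is reached
and the absolute rule under-selects. qsrr2d therefore applies the rule on
the *relative* scale,

$$\frac{Q^2_{A+1} - Q^2_A}{1 - Q^2_A} > 0.01
  \quad\text{and}\quad Q^2_{A+1} > 0,$$

i.e. a component is kept while it removes more than 1% of the variance
still unexplained (the same rule expressed as a fractional PRESS
reduction). The full Q2/RMSE_CV ladder is stored on the model for audit.

**Variable importance** (VIP) scores are computed from the NIPALS weights;
the squared scores average to 1 by construction, so VIP < 1 marks a
below-average contributor. **Coefficient uncertainty** comes from a
seven-group jackknife: the model is refitted on each leave-one-group-out
subset and the raw-unit coefficient spread is converted to a 95% half-width
with the t quantile on 6 degrees of freedom. Because raw-unit coefficients
are invariant to each submodel's internal scaling, the half-widths are
directly comparable to the coefficients.

**Pruning** (`pruneDescriptors()`) implements three simplification
strategies: drop descriptors whose half-width exceeds their coefficient
(`uncertainty`), drop VIP < 1 (`importance`), or iterate removing the ten
worst offenders and refitting until every survivor passes both criteria
(`stepwise`). The component count is re-selected after every refit. Note
that with few surviving descriptors the VIP < 1 criterion can sacrifice a
genuinely informative but weaker descriptor - the mean-square-1 constraint
makes VIP a *relative* measure.

**Group-local models** (`fitGroupModels()`): compound classes (fluorinated,
chlorinated/brominated, long-chain homologues, remainder) can deviate from
the global structure-retention mapping in ways no descriptor encodes, e.g.
specific stationary-phase interactions of a homologous series. A group with
at least `max(10, 2 x 7)` training members gets its own local PLS model;
prediction dispatches per group and flags global fallbacks. The gain is
largest in the second dimension, where such unmodelled offsets are large
relative to the (small) `t2R` noise.

# Federated local models

An alternative to one global model is to predict each query from a small
regression over its nearest neighbours in a knowledge base
(`buildKnowledgeBase()`, `predictFederated()`). Similarity uses either a
continuous Dice coefficient $2\sum a b / (\sum a^2 + \sum b^2)$ on min-max
rescaled properties (so the coefficient is meaningful on non-negative
vectors) or a Euclidean similarity $1/(1+d)$; ties break lexicographically
by compound id for determinism. On the `k = 25` neighbours, properties
enter a local least-squares model by forward stepwise selection (largest
RSS reduction first), capped at `floor(k/m)` parameters with `m = 4`
compounds per parameter, and stopped when the relative RSS improvement
falls below 1%. Neighbourhoods with constant properties fall back to the
neighbour mean and are flagged. `looFederated()` evaluates the scheme by
leave-one-out over the knowledge base.

# Evaluation, applicability domain, screening

All prediction errors use $\mathrm{RMSE_P} = \sqrt{\sum (y-\hat y)^2/(N-1)}$
(sample convention), alongside average and relative deviations and the 95th
percentile of absolute residuals (`evaluatePredictions()`). Two reference
points calibrate expectations (`benchmarkModels()`): a one-descriptor
least-squares model (boiling point for the first dimension; logKow and its
weight-normalised variant for the second) and the training-mean constant.

The **applicability domain** (`applicabilityDomain()`) is PCA-based: a
query is in-domain when its Hotelling T-squared over the retained
components and its residual distance-to-model are both below calibrated
limits. Two independent 95% checks would keep only ~90% of the training
set, so the per-check levels are Bonferroni-split (97.5% each) and the
limits use lower empirical quantiles (the F-based T-squared limit is
floored by the empirical quantile); the combined rule then keeps at least
95% of the training compounds in-domain by construction.

**Screening** (`filterCandidates()`) eliminates a candidate when, for any
response, its predicted value deviates from the measured value of the
unknown by more than that response's error window - the 95th percentile of
the external-validation residuals (`errorWindows()`). The boundary is
inclusive, and out-of-domain candidates are flagged rather than eliminated,
since for them larger errors must be expected.

# The synthetic study

Because measured GCxGC libraries cannot ship with the package, qsrr2d
includes a generator (`generateDataset()`) whose ground truth mirrors the
physics the workflow assumes; every statistical claim in the test suite is
checked against it. Per compound, three latents are drawn - volatility
$u \in [0,1]$ (with $u = (n-8)/22$ placing alkane C~n~ between the C8 and
C30 anchors), polarity and polarizability - and

* $t_1 = 400 + 2900\,u$ seconds (the alkane anchors), and
* $t_2$ = non-polar baseline at the elution temperature of $t_1$ (under a
  35 degC start, 5 degC/min ramp to 310 degC) + 0.55 x polarity + 0.35 x
  polarizability + 0.25 s for halogenated classes + 0.5 s for the
  long-chain homologous series.

The homologue offset is deliberately *not* encoded in any descriptor: it is
the unmodelled, class-specific stationary-phase interaction that motivates
group-local models. Noise defaults are 30 s on `t1R` and 0.15 s on `t2R`
(4 s and 0.02 s within the nearly deterministic homologous series; 2.5x
`t2R` inflation for fluorinated compounds). Of 150 descriptors, 9 are named
physico-chemical anchors (boiling point, logKow, MW, carbon count and
Abraham-style E/S/A/B/L), 30% are pure noise for pruning to find, and the
rest are noisy linear images of the latents (SD 0.01 on the latent scale -
small against the retention noise, so a noise-recovery experiment measures
the injected noise, not descriptor error). The boiling-point proxy carries
50 s equivalent noise, making the single-descriptor benchmark informative
but clearly inferior to the multivariate model. Reference series are
noiseless, as standards measured in dedicated runs. A PCB-like homologue
family (40% of the chlorinated class, chlorination levels 1-10) exercises
the splitting rule. Everything is a deterministic function of the
configuration seed, and generation never touches the caller's RNG state.

Typical problem sizes - 600 compounds, 150 descriptors, a 46/26/28 split -
are the package's own choice: large enough that cross-validation,
jackknifing and the applicability domain behave as designed, small enough
that the full workflow runs in seconds.

```{r study, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
d <- generateDataset(cfg)
cs <- applySplit(d$compounds,
                 systematicSplit(d$compounds,
                                 runPCA(descriptorValues(d$compounds), 5),
                                 seed = 101))
m <- trainPLS(cs, "t1R", seed = 201)
evaluateOnSet(m, cs, "test")
```

# Limitations

* The generator emulates the *statistical* structure of a GCxGC study
  (latent-driven retention, class offsets, homologue families, noise
  floors), not chromatographic physics; absolute numbers are illustrative.
* Linear models throughout: strong nonlinearity in descriptor-retention
  relationships is only addressed by the transform catalog and local
  models.
* The PEG-2I geometry assumes straight, non-crossing reference lines over
  the modelled `t1` span.
* VIP-based pruning is relative; with few descriptors it can discard weak
  but genuine predictors (see above).
* The applicability domain is a coverage statement about descriptor space,
  not a guarantee of prediction error.
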