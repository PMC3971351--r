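---
title: "Ternary pathway fingerprints: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary pathway fingerprints: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerprintr)
```

## The model

`fingerprintr` represents a single expression profile as a ternary vector
over a gene-set collection. The construction has three stages, each with a
specific statistical role.

**1. Mean squared rank.** Within one sample, genes are ranked ascending
(`1` to `T`, `T` = genes on the array; ties get average ranks, which keeps
the column rank sum at exactly `T(T+1)/2`). A pathway with `n` represented
genes at ranks `R_1..R_n` scores `En = mean(R_i^2)`. Squaring weights the
top of the ranking: a pathway whose members sit uniformly in the upper tail
separates much further from a mid-ranked pathway than under a plain mean
rank. Because only ranks enter, `En` is invariant under any strictly
monotone transform of the sample — the property that makes scores
computable on any one-channel platform under any within-array
normalization.

**2. Probability of expression (POE).** `En` values are comparable neither
across pathways (sizes and gene-overlap differ) nor across platforms (gene
coverage differs). Both problems are absorbed by a per-pathway,
per-platform null: the distribution of the pathway's scores across a large
set of arrays of the same platform, fitted as a two-component mixture

$$y \sim \pi\,U(lo, hi) + (1-\pi)\,N(\mu, \sigma^2),$$

where the normal core captures unremarkable pathway expression and the
uniform component captures outlying (significantly high or low) scores.
The signed POE of a new score `y` is the posterior probability of the
uniform component, signed by the side of the core mean:
`POE = P(U | y) · sign(y − μ)`. It lies in `(−1, 1)`, is monotone in `y`
on each side of `μ`, and approaches `±1` in the tails where the normal
density vanishes against the flat uniform.

**3. Ternary threshold.** POE is cut at `T = 0.001` (boundary inclusive,
`+1` iff `POE ≥ T`, `−1` iff `POE ≤ −T`). The threshold is deliberately
permissive: at the pathway level the coordinated behavior of tens of genes
makes even subtle score shifts informative, and the benchmark suite
(below) exists precisely to examine this choice — relaxing the threshold
improves classification and retrieval until the curve flattens near
`0.001`, while very stringent thresholds (~0.9) retain only the most
extreme calls.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `threshold` | 0.001 | `ternarize()` | POE magnitude for a ±1 call; unitless in (0,1) |
| `t` | caller-chosen; 0.75 for lineage/signature work | `consensus_fingerprint()` | strict cut on the group mean ternary score |
| `min_genes` | 3 | `pathway_scores()` | members required on the array before a pathway is scored; 1 recovers the strictest single-gene behavior |
| `n_min` | 50 | `fit_uniform_normal_em()` | background arrays required per pathway fit |
| `min_size` | 5 | `map_collection()` | surviving members required after ortholog mapping |

Consensus boundaries are strict (`μ > t`) while ternary boundaries are
inclusive; both conventions are applied exactly as stated and are
configurable at the call sites.

## Numerical choices

* **EM for the uniform–normal mixture.** The uniform support is *fixed* at
  the observed range padded by 0.1% per side: a free-support uniform has an
  unbounded likelihood and the outlier semantics call for covering the
  observed range anyway. With the support fixed, EM over `(π, μ, σ)` is
  standard; initialization is `π = 0.1`, `μ = median`, `σ = 1.4826·MAD`
  (falling back to the SD when the MAD is zero), convergence at `1e-8`
  log-likelihood gain, 1000 iterations cap, and a σ floor of `1e-6` of the
  support width. The fit is deterministic and the log-likelihood is
  asserted non-decreasing in the tests. Constant input and small samples
  are errors, not silent fits.
* **Signing under skew.** POE is signed by `sign(y − μ)` with `μ` the
  fitted normal mean. When the core is skewed the mode and mean differ;
  the mean is used consistently.
* **Missing propagation.** A pathway with too few represented genes, or
  with no background fit, carries `NA` scores and POE; it ternarizes to 0
  and is tracked in an `unmeasured` mask rather than imputed. Distances
  include those zeros by default, keeping the fingerprint a fixed-length
  object; the mask lets users exclude them.
* **Alignment safety.** Backgrounds store a hash of the gene-set
  collection (names, order, memberships). POE against a different or
  reordered collection is an error — a silently misaligned fingerprint is
  the worst possible failure mode. Backgrounds serialize to JSON at 17
  significant digits so a save/load round trip is bit-identical.
* **1-D 2-means.** Survival stratification splits scores at the global
  within-group-sum-of-squares optimum found by scanning every cut between
  distinct sorted values — equivalent to converged 2-means but free of
  initialization nondeterminism.
* **Determinism.** Every stochastic operation (fold assignment, random
  gene sets, bootstrap, permutations, all generators) takes an explicit
  seed and is a pure function of it; seedless calls to the generators are
  errors.

## Distances and retrieval significance

The distance between fingerprints is the normalized Manhattan distance
`Σ|a_i − b_i| / (2N)`, scaling from 0 (all pathway calls match) to 1
(all maximally mismatched). Distance from a consensus is restricted to the
consensus's non-zero coordinates so only the pathways defining the
phenotype count. For ranking a corpus, significance comes from a robust
normal null for the non-matched majority: mean = median of all corpus
distances, SD = IQR/1.349, p = lower tail. The estimate is deliberately
robust to the small contaminating population of true matches; it assumes a
unimodal non-matched bulk, and p-values are not multiplicity-adjusted —
they order and calibrate a retrieval list rather than support formal
discovery claims. Note `Φ((Q1 − median)/(IQR/1.349)) = Φ(−0.6745) ≈ 0.25`
holds exactly only when the quartiles sit symmetrically about the median.

## Benchmarks

Four evaluations, jointly used to study the ternary threshold:
stratified nearest-mean-fingerprint cross-validation (5 folds, 10 repeats,
leave-one-out fallback for small classes); the intra/inter class variance
ratio (inter-class variance is not uniquely defined by its usual verbal
description — here it is the sum over samples of the *mean* squared
Euclidean distance to the other classes' means, which is symmetric and on
the same scale as the intra term); retrieval precision-recall with the
standard `max precision at recall ≥ r` interpolation and MAP; and a
size-matched random-gene-set comparator built by sampling sets (without
replacement, sizes preserved) from the collection's own gene universe, so
any skill it retains reflects gene coverage rather than pathway structure.

## Lineage reconstruction

Consensus fingerprints per cell type (t = 0.75) are treated as discrete
characters and a tree is sought minimizing total Sankoff parsimony cost
with the difference cost `|a − b|` — one step between adjacent states, two
between −1 and +1. The DP is exact per tree; the search hill-climbs from a
neighbor-joining start (on normalized Manhattan distances between the
character rows) through all nearest-neighbor interchanges, accepting the
first strict improvement in a fixed edge order, so the search is
deterministic. It is a local search: only the 4-taxon case is provably
optimal (verified against exhaustive topology enumeration in the tests).
Bootstrap supports resample characters with replacement and report, for
each internal edge of the point-estimate tree, the fraction of replicate
trees containing the same bipartition — supports map onto the point tree,
not onto a consensus of replicates. Unmeasured characters enter as state
0, consistent with fingerprint semantics.

## Signatures and survival

A stem-versus-progenitor signature contains the pathways on which both
stem-cell groups agree with a non-zero consensus call while the progenitor
consensus differs; the consensus-disagreement rule (at t = 0.75, reusing
the lineage consensus threshold) is this package's operational definition
of "differentially expressed" at the fingerprint level, chosen because it
stays within the method's own discrete vocabulary. Signatures intersect
across species by shared pathway and equal sign. A sample's signature
score is the plain sum of its ternary calls over the signature pathways
(a sign-weighted variant is available behind `weighted = TRUE`); cohorts
are stratified by the exact 2-means split of raw (unstandardized) scores
and compared by the standard log-rank test. The permutation background
repeats the whole chain with random same-size pathway sets, reporting the
observed p-value's percentile among the permutation p-values; degenerate
permutations (constant scores, empty groups, no events) are skipped and
counted.

## What the synthetic generator does and does not emulate

`make_corpus()` generates multi-platform, multi-species corpora with known
truth. Baseline expression is `f_p(offset_g + z)` per platform: the
strictly monotone `f_p` emulates platform dynamic-range differences (rank
scoring must be blind to it — that claim is under test, not assumed), and
per-gene offsets emulate gene-specific baselines (the platform background
must absorb them). Class effects act on the rank-quantile scale so "strong"
means the same thing on every platform: planted pathways move member-gene
quantiles by `effect_size` (default 0.8) toward the top or bottom; in
addition every class shifts all non-planted pathways weakly
(`class_modulation`, default 0.2) in class-fixed random directions.
The weak term reflects how real tissues modulate most transcriptional
programs subtly but consistently — without it, non-planted calls at the
permissive threshold are independent coin flips per sample, a noise
structure no real corpus shows, and one that would make permissive
thresholds pointless by construction. Pathway members are drawn from the
cross-species orthologous core so mapped collections keep identical
coordinates; the homology fraction (default 0.9) applies to the remaining
genes. Defaults describe a modest desk-scale study: 2 platforms × (100
class + 100 background) samples, 1000 genes per platform, 50 pathways of
10–30 genes, 4 classes activating 3 pathways each.

Not emulated: probe-level noise and cross-hybridization, batch chemistry,
RNA-seq counts, gene–gene correlation beyond pathway-level shifts, and
multimodal background distributions. Passing tests on this generator
demonstrate the pipeline's internal correctness and its cross-platform /
cross-species invariances; they do not certify performance on any
particular real corpus.

`make_lineage()` evolves a ternary root vector down a tree with a fixed
number of ±1 single-step mutations per edge (clamped to the state space);
`make_survival()` draws exponential event times with hazard
`λ0·exp(β·score)` and censors each sample with probability `censor_rate`
at a uniform time before its event, giving exactly the requested expected
censoring fraction.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which every recovery
property is comfortably away from its noise floor: the default 200-sample
corpus above; mixture recovery at n = 5,000 over 20 replicate fits;
parsimony exactness on ≤5-taxon trees against exhaustive enumeration and a
planted 6-taxon lineage with 120 characters; survival calibration and
power at 500 permutations over 200 samples.

## Design notes and limitations

* Core containers are pathways × samples matrices in light S3 wrappers, as
  is conventional for expression tooling; tabular results (summaries,
  benchmarks, rankings, survival) are tibbles, fitted objects have
  `tidy()`/`glance()` methods, and result types have `autoplot()`/`plot_*`
  functions.
* The consensus rule is implemented as `C = −1` iff `μ < −t`, the mirror
  of the positive rule.
* Many-to-one ortholog collisions collapse to a single target gene before
  the set-size filter.
* The two-component signed mixture is the implemented POE model; a
  three-component variant (separate high/low outlier components) is a
  possible extension.
* The IQR-normal retrieval null is a deliberate oversimplification for
  heterogeneous corpora (disease-biased, potentially multimodal); treat
  retrieval p-values as ranking aids.
* NNI hill-climbing can stop in local optima on conflicted character
  matrices; bootstrap supports are the intended readout of that
  uncertainty.
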