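---
title: "Optimizing neuropsychological test batteries for CDR classification"
author: "npOptim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing neuropsychological test batteries for CDR classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npOptim)
```

## Scope and model

`npOptim` implements a wrapper feature-selection pipeline for staging
dementia severity from neuropsychological test scores. The unit of analysis
is a subjects-by-measures table: one row per subject, one column per
measure (a total score or item-level subscore from one of twelve standard
instruments), plus a Clinical Dementia Rating label in {0, 0.5, 1}. The
three clinical questions are binary: mild vs none (0.5 vs 0), severe vs
none (1 vs 0), and severe vs mild (1 vs 0.5). In every comparison the
higher CDR level is the positive class, so sensitivity always means
detection of (greater) impairment.

The pipeline composes five stages.

**Standardization.** Each measure is z-scored, $z = (x - m)/s$, with $m$
and $s$ estimated with the sample ($n-1$) standard deviation. Where the
fitting population is ambiguous we default to fitting on the outer-training
subjects of each cross-validation round and applying the frozen model to
the held-out subjects — the leakage-free reading. `zscoreScope = "global"`
reproduces the literal whole-sample alternative for comparison; on balanced
data the two differ little, but only the fold-scoped default guarantees
that test subjects never influence the normalizer.

**Reduction.** Two strategies, reflecting two philosophies:

- `strategy = "fdr"` scores each z-scored feature by Fisher's Discriminant
  Ratio, $(\mu_1-\mu_2)^2 / (\sigma_1^2+\sigma_2^2)$, using the population
  ($n$) variance convention of the classical definition
  (`fdrVariance = "sample"` flips it), and retains the top
  $\lceil 0.05\,p \rceil$ features. The ceiling is forced by the printed
  arithmetic of the design the package reimplements: 5% of 131 features
  must retain 7, and $131 \times 0.05 = 6.55$.
- `strategy = "expert"` first restricts the battery to the 32 measures the
  shipped catalog marks as expert-retained (clinically non-redundant,
  independent of the CDR interview, relevant to Alzheimer's disease — the
  judgments are static catalog data, not something the package tries to
  re-derive), then ranks each survivor by the balanced cross-validated
  accuracy it achieves *alone* as classifier input, retaining the top 10.

**Classification.** A soft-margin SVM (solver: libsvm via `e1071`), with
the dual solution exported so the decision function
$y(x) = \sum_n w_n t_n k(x, x_n) + b$ is evaluated by the package's own
kernel code — training and prediction therefore follow two independent code
paths, which the test suite exploits. Four kernels are supported: linear
$x \cdot y$; quadratic $(1 + x \cdot y)^2$ (the historical toolbox
convention for an unparameterized quadratic kernel); Gaussian RBF
$\exp(-\lVert x-y\rVert^2 / 2\sigma^2)$ with default $\sigma = 1$; and the
sigmoid multilayer-perceptron kernel $\tanh(p_1\, x \cdot y + p_2)$ with
default scale $(1, -1)$ — the customary default where the second parameter
is negative. The sigmoid kernel is indefinite, so the solver can fail;
failures are recorded per round in the result's `failures` slot and the
affected rounds carry `NA` metrics rather than crashing the run.

**Nested cross-validation** (`runNestedCV`). Per iteration: the majority
class is undersampled without replacement to the minority size (a fresh
draw each iteration), and the balanced sample is split into 10 stratified
folds — per-fold class counts differ by at most one, and the two classes
place their remainder subjects at opposite ends of one random fold
permutation so total fold sizes also differ by at most one. Per round, one
fold is held out; z-scoring and the reduction are refit on the other nine
(`reductionScope = "global"` gives the fixed-feature-set alternative);
**every** nonempty subset of the reduced features is scored by inner
cross-validation — each of the nine training folds held out in turn, the
SVM trained on the remaining eight, and all inner predictions pooled into
one accuracy (pooling, rather than averaging per-fold accuracies, weights
every subject equally when fold sizes differ). The subset with maximal
inner accuracy is selected, refit on all nine folds, and evaluated on the
held-out fold. The exhaustive enumeration is capped at 20 features
($2^{20}-1$ subsets) with an explicit refusal beyond that.

**Best predictors** (`bestPredictorFrequencies`). With 10 rounds and 100
iterations the run records exactly 1000 optimal subsets; each measure is
ranked by the percentage of those subsets containing it. Frequencies
need not sum to 100% because subsets overlap.

## Deterministic choices

- *Subset tie-break.* Candidate subsets are enumerated by ascending
  cardinality, then lexicographically by catalog position; the first
  maximum wins. Equally accurate subsets therefore resolve to the
  smallest, earliest-in-catalog one — a parsimony-favoring, fully
  reproducible rule.
- *Ranking tie-breaks.* Feature rankings (FDR, single-feature accuracy,
  frequencies) use stable sorts, so ties keep catalog order.
- *Prediction ties.* A decision value of exactly zero is assigned to the
  positive class.
- *Seed scheme.* The master seed seeds one draw of per-iteration seeds;
  each iteration reseeds the generator before balancing and fold
  assignment and records its seed in the result, so any iteration can be
  replayed in isolation and iterations are order-independent.
- *Degenerate features.* A feature constant on the training folds of a
  round cannot be z-scored and is dropped from that round's candidate set;
  `fitZScore` itself refuses constants loudly.
- *Solver tolerance.* libsvm converges to a finite tolerance, so
  quantities that are mathematically equal (e.g. decisions after permuting
  training rows) agree only to about $10^{-3}$; tests assert exact label
  agreement and tolerance-level agreement of decision values.

## The synthetic cohort generator

Real cohorts of this kind live in access-restricted registries, so the
package ships a generator with known ground truth rather than data.
`cohortConfig()` defaults encode the study conditions the pipeline
targets: three CDR groups of 126, 143 and 55 subjects; within-instrument
equicorrelation $\rho = 0.3$ (instrument subscores are redundant, which is
exactly what expert criterion 1 exploits); unit latent noise; and planted
CDR-graded standardized shifts on ten measures that clinically track
severity (logical-memory recall, ADAS-Cog word-recall items and totals,
MMSE total, category fluency, FAQ total), with the mild group roughly
halfway to the severe group — so 1 vs 0 is easiest, 0.5 vs 0 intermediate
and 1 vs 0.5 hardest, the ordering such cohorts show. The shift magnitudes
(0.5–2.0 SD at CDR = 1) are in the range of published case-control effect
sizes for these instruments; they were fixed once as defaults and are fully
overridable.

Latent scores are equicorrelated Gaussians per instrument block, shifted
per group, then mapped to each measure's raw range: polarity flips the
impairment axis for higher-is-better scores, an affine map places $\pm 3$
SD across the catalog range, and values are clipped and rounded to
integers. Binary 0/1 items threshold the latent at zero.

What the generator does **not** emulate: missing visits (generated cohorts
are complete; the reader rejects missing cells unless asked to drop
incomplete rows), demographics (age/gender play no computational role in
the pipeline), longitudinal structure, floor/ceiling pile-ups beyond what
clipping induces, and the true joint distribution of real instrument
scores — the Gaussian-latent block model is a declared stand-in, not a
claim about any registry. Passing tests on synthetic cohorts therefore
demonstrate the *machinery* (selection exactness, calibration at the null,
recovery of known effects), not clinical performance.

## Problem sizes in the test suite

The suite exercises the full 10 × 100 resampling grid once, on a
four-measure cohort with 40 subjects per class and a linear kernel — small
enough to enumerate all 15 subsets per round quickly, large enough to
verify the 1000-subset bookkeeping at full scale. Selection exactness is
checked against brute-force re-evaluation at 5 features (31 subsets) on
identical folds; planted-effect recovery uses one 2.0-SD measure among
nine noise measures from *other* instruments (so block correlation cannot
leak signal into the noise), 60 subjects per group and 5 iterations.
For the null-calibration check the binomial band uses $n = 120$, the
number of distinct balanced subjects, not the number of outer
predictions: iterations re-split the same subjects, so extra predictions
add no independent information and a band based on them would be
spuriously tight.

## Using the pipeline

```{r example, eval = FALSE}
cohort <- generateCohort(cohortConfig(seed = 42))

res <- runNestedCV(cohort, task = "1v0", strategy = "fdr",
                   kernel = kernelConfig("linear"),
                   rounds = 10, iterations = 100, seed = 42)
cvSummary(res)                                  # mean +/- sd metrics
innerOuterByRound(res)                          # per-round optimism view
bestPredictorFrequencies(res, top = 10)         # measure importance
exportRun(res, "results/run1")                  # tsv tables + manifest
```

A full 100-iteration run over the 5%-FDR feature set evaluates roughly
10^6 SVM fits; on one CPU expect on the order of an hour per task and
kernel. The `iterations` argument scales linearly and 5–10 iterations
already give stable frequency rankings on synthetic cohorts.

For shell use, `inst/scripts/run-pipeline.R` wraps simulation,
classification and reporting behind a small command-line interface.

## Known limitations

- The exhaustive inner search is exponential in the number of reduced
  features; the hard cap is 20, practical sizes are 4–10.
- The expert annotation is static data: the package encodes, and cannot
  re-derive, clinical judgments about redundancy and relevance.
- Class balancing discards majority-class subjects; with a 126/55 design,
  about 56% of the larger group sits out each iteration (iterating 100
  times is what recovers the information).
- The indefinite sigmoid kernel may fail to converge on some folds; such
  rounds are logged and excluded from averages rather than imputed.
- Catalog score ranges and polarities follow the standard instrument
  definitions; cohorts scored with non-standard conventions need a custom
  catalog (`readCatalog`).
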