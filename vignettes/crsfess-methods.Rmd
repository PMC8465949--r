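---
title: "Methods: feature selection for sinus-surgery outcome parameters"
author: "crsfess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature selection for sinus-surgery outcome parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsfess)
```

## The question the package answers

Functional endoscopic sinus surgery (FESS) in chronic rhinosinusitis with
nasal polyposis improves endoscopic findings, disease-specific quality of
life and the sense of smell — but which of the many routinely collected
parameters actually *carry* the information that something changed? The
package frames this as a supervised learning problem: each patient
contributes one record before and one record four months after surgery,
each described by d = 37 variables from four categories (nasal
anatomy/pathology, olfaction, quality of life,
demographics/concomitant disease). Classifiers are trained to decide
whether a record was acquired before or after surgery; a variable is
informative exactly to the extent that the classifiers need it for this
task. The output is a short ranked list of outcome criteria rather than a
table of p-values.

## The selection procedure

One knockout iteration consists of:

1. **Monte-Carlo cross-validation.** The 2n records are split
   class-proportionally into 2/3 training and 1/3 test, many times
   (`mc_splits()`).
2. **Drop-one importance.** Per split and classifier, the model is fit
   with all variables (test accuracy `Acc_complete`) and refit with each
   variable withheld (`Acc_reduced`); the importance of a variable is
   `dAcc = Acc_complete - Acc_reduced`.
3. **Computed ABC analysis.** Per split, the positive part of the dAcc
   vector is categorized into subsets A ("important few"), B and C from
   the cumulative-contribution curve (`abc_partition()`); membership in A
   is tallied over splits. Per classifier, the selected set has the modal
   A-size and contains the variables most frequently placed in A.
4. **Weighted consensus.** A-membership counts are combined across the
   eight classifiers with weight
   `w = median balanced accuracy x max(0, CI_low(accuracy) - 50) / 50`,
   so chance-level classifiers are silenced; the weighted sums are again
   ABC-partitioned and subset A is the consensus (`consensus_vote()`).
5. **Category knockout.** The whole category of the top-ranked consensus
   variable is removed and the procedure repeats, until the best
   classifier's accuracy CI on the newly selected variables no longer
   clears 50% (`crs_select()`).

The eight classifiers are a random forest, unpenalized and weakly
ridge-penalized logistic regression, a linear-kernel SVM, kNN (Euclidean,
k = 7), Gaussian naive Bayes, a CART tree, and a rule-generating tree
with entropy splits standing in for hierarchical rule-based classifiers
of the C5.0 family. Heterogeneity is the point: a selection that all of
them agree on does not hinge on one algorithm's inductive bias.
Overfitting is controlled by a negative-control condition in which every
training column is permuted independently within each split
(`permutation_control()`); all classifiers must then drop to about 50%
accuracy.

Defaults follow the full-fidelity configuration (1500 forest trees, 1000
Monte-Carlo runs). Because drop-one importance refits every classifier
d + 1 times per split, the package's tests and examples use documented
scaled-down sizes (50-300 trees, 15-200 runs); the selection is driven by
rank aggregation over runs and is insensitive to these sizes well below
the full configuration.

## The synthetic cohort

The patient data behind the original analysis are available only on
request, so the package ships a generator (`generate_cohort()`) whose
defaults *are* the published study conditions: n = 90 paired patients;
every marginal mean/SD/range (or prevalence count) as published per
occasion; and the paired change directions of the three headline
variables — Lildholdt improved/unchanged/worsened in 84/6/0 of 90 (59
reaching score 0 after surgery), primary nasal symptoms in 86/0/4,
olfactory self-rating #2 in 62/24/4.

Mechanics, and why they were chosen:

* **Discrete scales** (Lildholdt, Lund-Kennedy, eosinophilia grade,
  self-ratings, discrimination/identification counts, the two SF-36 role
  scales on {0, 25, 50, 75, 100}) use minimum-norm probability vectors
  solved by constrained least squares to hit the published mean and SD
  exactly (`match_probs()`).
* **Continuous scales** use truncated-normal margins moment-matched on
  the published range; where the published mean/SD pair is outside the
  truncated-normal family (several skewed SF-36 scales), a moment-matched
  scaled Beta is used instead (`continuous_margin()`).
* **Within-patient pairing** uses a Gaussian copula with correlation 0.5
  by default. Margins are applied through stratified uniforms in the rank
  order of the latents, so dependence and marginal law are controlled
  separately and marginals are recovered almost exactly even at n = 90.
* **Lildholdt and self-rating #2** are drawn from joint pre/post tables
  fitted by iterative proportional fitting to the margins *and* the
  change-direction masses (`couple_margins()`), then quota-sampled, which
  makes both the marginals and the improved/unchanged/worsened fractions
  essentially exact. Both margins and directions are published; both must
  hold at once, which a plain copula cannot guarantee.
* **Binary prevalences** are drawn as fixed counts randomly assigned to
  patients. Several prevalences are rare (1/90); Bernoulli sampling would
  make their recovery noisy at any reasonable n.
* **A shared latent improvement factor** links the change in self-rated
  olfaction to the change in primary nasal symptoms. The loadings (0.75
  on the primary-nasal residual, 0.8 on the rating-pair assignment) were
  calibrated once so the Spearman correlation of the two deltas is about
  -0.48 (squared: ~0.23), the published weak coupling; the primary-nasal
  copula correlation 0.5481 is calibrated so its worsening fraction is
  4/90.
* **Instrument redundancy.** The real instruments are arithmetically
  linked: the SNOT-20 total contains the subscore items, the TDI is the
  sum of its three subtests, the SF-36 summaries weight the eight scales,
  and the two olfactory self-ratings grade the same percept. The
  generator reproduces this with latent block factors (within-block
  correlations roughly 0.6-0.8; self-rating #1 follows the realized
  rating #2 values). This matters for the science: without redundancy,
  drop-one importance spreads over every marginally shifted variable; with
  it, siblings compensate for a dropped variable and importance
  concentrates on the uniquely informative Lildholdt score, which is the
  structure the selection procedure is designed to detect.
* **Demographics** are copied across occasions; age advances by 1/3 year
  (the four-month follow-up). Parosmia/phantosmia remit 1 -> 0 only.

What the generator does *not* emulate: the 67 baseline-only dropouts,
any missing-not-at-random structure (injected missingness is MCAR via
`inject_artifacts()`), item-level SNOT-20/SF-36 responses (subscores are
generated directly), and the arithmetic identity TDI = T + D + I (the
published marginals of the four variables are mutually inconsistent,
presumably due to differing missingness, so each is matched marginally
and tied to the family block factor instead). Passing tests on this
cohort therefore demonstrate that the pipeline recovers structure that is
*planted consistently with the published statistics* — not that it would
behave identically on the raw patient data.

## Preprocessing

`preprocess_cohort()` mirrors a standard clinical-data workflow:
candidate transforms along Tukey's ladder of powers (lambda in {-1, -0.5,
log, 0.5, 1, 2}, order-preserving, shift to positivity where needed) are
scored by the Kolmogorov-Smirnov distance to normality, with the identity
winning ties; outliers are removed per variable by iterated two-sided
Grubbs tests (alpha = 0.05, pooled over both occasions to maximize N;
masked values become missing); missing interval/ordinal cells are imputed
separately within each of the four variable categories, by per-occasion
medians or by an iterated ensemble-of-trees regression (100 trees, up to
10 sweeps, relative change < 1e-3); binary/nominal variables are one-hot
recoded with missing values assigned to the zero condition. Ordinal
clinical grades are exempt from transformation and outlier masking: their
supports are bounded by construction, so extreme values are legitimate
readings, not artifacts.

## Effect sizes and projections

The Impact effect size combines a robust central-tendency difference
(medians over 1.4826 x MAD, pooled) with a distribution-shape difference
(one minus the overlap of Gaussian-kernel densities of the
median-centered samples, Silverman bandwidths, shared 512-point grid),
reporting `sign(CT) x max(|CT|, SHAPE)`. The composition rule is fixed
here as the package's contract; its fidelity requirement — agreement with
Cohen's d within 0.15 on Gaussian location shifts — is enforced by tests.
Confidence intervals are 2.5th/97.5th percentiles over 1000 bootstrap
resamples.

Factor analysis of mixed data standardizes continuous columns
(population SD), scales each categorical indicator by the square root of
its level proportion, centers, and decomposes by SVD with row weight 1/n.
With that normalization the total inertia is the number of continuous
variables plus (levels - 1) per categorical variable, and the classical
"eigenvalue > 1" retention rule is well defined. Degenerate cases follow
fixed conventions: constant columns are dropped with a warning, the first
nonzero loading of each dimension is made positive, and an all-continuous
(or all-categorical) input reduces exactly to standardized PCA (or MCA),
which the tests verify against independent implementations.

## Numerical conventions and tie rules

* ABC analysis: items sorted by decreasing value with stable ties; A|B
  boundary at the curve point closest to (0, 1) (first index on ties);
  B|C at the first later point with discrete slope <= 1, clipped to
  n - 1; zero items always in C.
* Grubbs critical value: `((N-1)/sqrt(N)) sqrt(t^2/(N-2+t^2))` with `t`
  the upper `alpha/(2N)` Student-t quantile, N - 2 df.
* Depth-1 rule extraction: candidate thresholds are midpoints of
  consecutive unique training values; ties in training misclassification
  resolve to the smallest threshold.
* Per-classifier selection ties resolve by mean dAcc, then variable
  name.
* All stochastic steps take explicit seeds; equal seeds give identical
  cohorts, splits, selections and summaries.

## Known limitations

The occasion comparison uses the unpaired Wilcoxon-Mann-Whitney U test
(a paired signed-rank option exists but is not the default), matching the
analysis being reproduced even though the design is paired. The
consensus weight formula fixes one reasonable combination of the three
published weighting ingredients. The depth-1 rule learned on this
synthetic cohort usually cuts at Lildholdt >= 2 rather than the published
>= 1: under the published marginals (post-surgery P(0) = 59/90, mean
0.58, SD 0.96), about 19% of post-surgery records have score 1 versus
about 14% of baseline records at 1, so the >= 2 cut minimizes
training error; the published >= 1 rule reflects the unpublished joint
sample. Bootstrap CIs are percentile-based without bias correction. The
generator emits completers only.
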