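---
title: "Building and validating gene-pair prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating gene-pair prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpair)
```

## The model

`irgpair` builds survival risk scores from *relative expression ordering*.
For an ordered pair of genes (IRG1, IRG2) the pair indicator in sample $s$
is $z(s) = \mathbf{1}\{x_{\mathrm{IRG1},s} > x_{\mathrm{IRG2},s}\}$, and a
fitted signature of $K$ pairs scores a sample as

$$\mathrm{IRGPI}(s) = \sum_{k=1}^{K} z_k(s)\,\beta_k,$$

where the $\beta_k$ are coefficients of an L1-penalized Cox
proportional-hazards model on the binary indicators. The method therefore
assumes proportional hazards on the *pair indicator* scale, not on raw
expression. Its key structural property is rank invariance: any strictly
increasing per-sample transform of the expression values (log scaling,
scaling by a library-size factor, a monotone platform response) leaves
every $z_k$ — and hence the score, the cutoff and the risk groups —
unchanged. Cross-sample perturbations such as per-gene batch shifts are
*not* monotone within a sample and can flip indicators; the simulator
provides both kinds of distortion precisely to separate the guarantee
from its limits.

## Pipeline stages and the parameters that matter

**Gene variability filter.** `mad_filter()` keeps genes whose unscaled
median absolute deviation, $\mathrm{MAD} = \mathrm{median}\,|x -
\mathrm{median}(x)|$, exceeds a threshold (default 0.5, unit-free) in
*every* supplied cohort. Two deliberate choices: the MAD carries no
1.4826 consistency constant, because a fixed threshold is only meaningful
under one stated convention and the unscaled form is the plainest; and
nothing is pooled across cohorts — the statistic is per cohort and the
decision is the intersection, so a gene missing from any cohort is out.
Whether the MAD is computed on raw or log-scale values changes the kept
gene *set* (though never the value of any pair indicator); the filter
takes whatever matrix it is given and documents this rather than
converting.

**Pair construction.** `build_pairs()` forms all $\binom{n}{2}$
combinations, orientation fixed lexicographically. Orientation is pure
bookkeeping at this stage — screening and fitting see both directions
through the 0/1 coding — but a *fitted* signature's orientation is
meaningful and `score_samples()` always uses the signature's own (for the
published signature, its printed table orientation). Comparisons are
strict and ties score 0. Ties are measure-zero for continuous data but
common after rounding; a heavily tied pair simply has a less informative
indicator.

**Pair balance filter.** `filter_pairs()` retains pairs whose frequency
of 1 lies in $[0.2, 0.8]$ by default. A near-constant indicator carries
little contrast and produces unstable Cox fits. The low-variation and
imbalance concerns collapse into this single frequency window (two
separate filters would be redundant: both act on the same Bernoulli
frequency); both bounds are configurable.

**Screening.** `screen_pairs()` computes, per pair, the two-sample
log-rank test and the univariate Cox fit (Efron ties), and selects on the
Cox p-value by default at `alpha = 0.05` (`select_on = "logrank"`
switches the criterion). No multiplicity correction is applied at this
stage: the screen is a pre-filter feeding a penalized model that performs
the actual selection, and correcting twice would doubly shrink the
candidate set. Pairs with monotone likelihood (perfect separation) are
flagged and excluded rather than clipped to an arbitrary large effect.

**Penalized fit.** `fit_lasso_cox()` uses glmnet's Cox lasso with
10-fold cross-validation of the partial-likelihood deviance (the
Verweij–van Houwelingen form). Folds are stratified by event status and
derived from a required, recorded seed, making the path and the chosen
model exactly reproducible. The default `lambda_rule = "min"` minimizes
the CV deviance ("1se" is available). Binary indicators share a common
scale by construction, so no standardization is applied by default. The
reported coefficients are the penalized estimates; there is no
unpenalized refit, so shrinkage is part of the model. glmnet's Cox
partial likelihood uses Breslow tie handling; with continuous simulated
times ties are measure-zero, and the unpenalized limit of the path agrees
with a Breslow `coxph` fit to 1e-4 in the test suite.

**Cutoff selection.** `select_cutoff()` computes the cumulative/dynamic
time-dependent ROC at a fixed horizon (default 1 year, converted via the
clinical table's declared time unit — 365.25 days or 12 months per year).
Cases are samples with an event by the horizon, controls those followed
beyond it; samples censored before the horizon contribute through
inverse-probability-of-censoring weights from a Kaplan–Meier estimate of
the censoring distribution, not by exclusion — dropping them would bias
the curve wherever censoring is informative about follow-up length.
Candidate thresholds are the midpoints between consecutive distinct
scores plus $\pm\infty$ (deterministic and exhaustive, not a grid), the
chosen cutoff minimizes the Euclidean distance to the (FPR 0, TPR 1)
corner, and ties break toward the lower threshold, i.e. the larger
high-risk group. The AUC is the IPCW-weighted case–control concordance
with ties counting one half.

**Risk groups.** `assign_groups()` calls a sample high risk exactly when
its score strictly exceeds the cutoff; a score equal to the cutoff is low
risk. The boundary rule is arbitrary for generic coefficients (exact
equality is measure-zero) but is fixed and documented so group
assignments are reproducible to the bit.

**Evaluation.** `km_logrank()` wraps the product-limit estimator and the
Mantel–Haenszel log-rank test; `td_auc()` reuses the IPCW estimator at
1/3/5-year horizons; `cox_with_covariates()` fits uni-/multivariable Cox
models entering the signature as the binary group by default (flag for
the continuous score) with `stage` treated as ordinal numeric I–IV → 1–4
by default (categorical on request); `binary_roc()` is the ordinary
Mann–Whitney AUC for diagnostic contrasts between sample classes.
P-values are reported exactly; "p < 0.001"-style floors are a display
concern.

## The published signature as packaged data

`published_signature()` returns the 14-pair, 22-gene papillary renal cell
carcinoma signature with its printed coefficients and the risk cutoff
0.184. It is packaged as *fixed truth*, not a fitting target: recovering
the exact pair list would require the original cohorts and the original
cross-validation fold assignment, which are not recoverable from any
seed. Two closed-form anchors follow directly from the coefficients and
are asserted in the tests: a sample winning no pair scores 0 and one
winning every pair scores $\sum_k \beta_k \approx -1.542$ (both called
low risk at 0.184), and every attainable score lies in
$[\sum_k \min(\beta_k, 0), \sum_k \max(\beta_k, 0)] =
[-3.193, 1.651]$.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws gene-wise log-normal expression (log2 values
Normal with per-gene location ~ N(5, 1.5²) and SD ~ U(0.5, 1.5), a
realistic spread for log-scale abundance), plants pair effects
*on the indicators* — survival times are exponential with hazard
$h_0 \exp(\sum_k \beta_k z_k)$, matching the model the pipeline actually
fits — and censors independently with an exponential time whose rate is
calibrated by root-finding on
$E[\theta / (\theta + h_i)]$ so the expected censored fraction hits the
target (default 30%, a typical oncology follow-up loss). The two genes of
a planted pair share a location so the indicator is roughly balanced; a
degenerate (constant) indicator triggers a bounded resample of those two
genes. The default baseline hazard is 0.2 per year with time reported in
years. Distortions are applied *after* survival generation so outcome
labels depend only on the undistorted ranks.

The simulator does **not** emulate negative-binomial read counts,
gene–gene correlation beyond the planted pairs, informative censoring,
or competing risks. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted signal under the stated
generative model — not performance on real tumor cohorts, where
correlated co-expression and non-proportional hazards can degrade both
selection stability and calibration.

## Numerical choices and degenerate inputs

- Duplicate gene symbols on input collapse by per-sample maximum
  (deterministic; favors the better-detected probe/transcript).
- RNA-seq-type input drops genes that are zero in more than half the
  samples; the filter is off for microarray intensities, where zeros are
  not a sparsity signal.
- Threshold ties in cutoff selection break toward the lower threshold;
  floating-point ties are compared with a 1e-12 guard.
- The lasso path is solved to `thresh = 1e-10`; active-set monotonicity
  along the path holds up to this solver tolerance.
- Model JSON serializes coefficients at full precision
  (`digits = NA`), so write–read round-trips are exact.
- Fits with zero events, single-group comparisons, constant covariates,
  empty gene sets and all-filtered pair sets raise immediate, specific
  errors rather than propagating NaN.

## Problem sizes used by the test suite

The suite checks oracle equivalence on small instances (10×20 pair
matrices, 50-sample ROC enumerations, a 10,000-permutation log-rank
null), parameter recovery on 20 seeded cohorts of n = 300 with 2 planted
pairs among 50 noise pairs, null calibration of screening on 200
independent noise pairs, and null AUC at n = 1000 — sizes at which the
Monte-Carlo bounds asserted are comfortably stable while the full suite
runs in about a minute.

## Known limitations

- Pairs are binarized; a continuous rank-difference score is out of scope.
- The screen considers marginal association only; pairs prognostic only
  jointly can be missed before the lasso sees them.
- IPCW weights grow unstable when the censoring survival approaches zero
  near the horizon; the estimator refuses horizons with unbounded weights.
- The published cutoff 0.184 is usable for scoring any cohort, but its
  derivation depended on the original discovery data and is not
  regenerated here.
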