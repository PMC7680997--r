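# irgpair

Rank-based prognostic gene-pair signatures for survival stratification.

Bulk expression values travel badly between platforms: FPKM from RNA-seq
and microarray intensities are not on a common scale, so a risk model
built on one cohort's absolute expression rarely transfers to another. A
gene-*pair* signature sidesteps normalization entirely by looking only at
within-sample relative order. For an ordered pair of immune-related genes
(IRG1, IRG2), the pair's value in sample *s* is

    value(s) = 1  if expr(IRG1, s) > expr(IRG2, s),  else 0

and the immune-related gene-pairs index (IRGPI) of a sample is the sparse
linear score over the selected pairs

    IRGPI(s) = Σ_k value_k(s) · β_k ,

with coefficients β_k from an L1-penalized (lasso) Cox proportional-hazards
model. Because `value` depends only on the within-sample ranking, the score
is unchanged by any strictly increasing per-sample transform of the
expression values — log scaling, library-size factors, monotone platform
effects.

`irgpair` implements the full workflow for building and validating such
signatures from a gene-by-sample expression matrix and a survival table:

- **Gene filtering** — unscaled median absolute deviation (MAD) filter
  across one or more cohorts (`mad_filter()`).
- **Pair construction** — all pairwise binary indicators with strict
  comparisons and ties scored 0 (`build_pairs()`), plus removal of
  low-variation / imbalanced pairs (`filter_pairs()`).
- **Screening** — per-pair log-rank test and univariate Cox fit against
  overall survival (`screen_pairs()`, `logrank_test()`, `univariate_cox()`).
- **Sparse model fitting** — lasso Cox with event-stratified 10-fold
  cross-validation (`fit_lasso_cox()`, via glmnet).
- **Scoring and cutoff** — IRGPI computation (`score_samples()`) and risk
  cutoff chosen as the point of a 1-year time-dependent ROC curve (IPCW,
  cumulative/dynamic) closest to the (FPR 0, TPR 1) corner
  (`select_cutoff()`, `assign_groups()`).
- **Evaluation** — Kaplan-Meier curves + log-rank (`km_logrank()`),
  time-dependent AUC at 1/3/5 years (`td_auc()`), uni-/multivariable Cox
  with clinical covariates (`cox_with_covariates()`), and plain diagnostic
  ROC (`binary_roc()`).
- **Published signature** — the 14-pair, 22-gene signature for papillary
  renal cell carcinoma with its risk cutoff 0.184 ships as packaged data
  (`published_signature()`).
- **Synthetic cohorts** — a seeded simulator with planted pair effects on
  the hazard, calibrated censoring, and monotone/batch distortions for
  invariance testing (`simulate_cohort()`, `distort()`).

Results are tibbles or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods, so everything chains with the pipe and plots with
ggplot2.

## Worked example

Score three synthetic patients with the published signature:

```r
library(irgpair)
sig <- published_signature()
glance(sig)
#>   n_pairs n_genes cutoff min_score max_score
#> 1      14      22  0.184     -3.19      1.65

set.seed(1)
expr <- matrix(2^rnorm(22 * 3, 5, 2), nrow = 22,
               dimnames = list(signature_genes(sig), c("pt1", "pt2", "pt3")))
scores <- score_samples(expr, sig)
assign_groups(scores, signature_cutoff(sig))
#> Risk groups at cutoff 0.184: 1 high, 2 low.
#>   sample_id  irgpi group
#> 1 pt1       -1.86  low
#> 2 pt2       -3.09  low
#> 3 pt3        0.631 high
```

A sample's IRGPI is the sum of the coefficients of the pairs it "wins":
`pt3` scores 0.631 > 0.184 and is called high risk (poorer expected
survival); the attainable score range for this signature is
[−3.193, 1.651].

Fit a fresh signature end-to-end on a simulated cohort with two planted
pairs (log hazard ratios +1 and −1):

```r
cfg <- sim_config(n_samples = 300, n_genes = 12,
                  planted = data.frame(irg1 = c("g001", "g003"),
                                       irg2 = c("g002", "g004"),
                                       log_hr = c(1, -1)),
                  seed = 42)
co  <- simulate_cohort(cfg)
pm  <- filter_pairs(build_pairs(co$expr, rownames(co$expr)))
fit <- fit_lasso_cox(pm, co$clinical, seed = 7)
tidy(fit)
#>   irg1  irg2  coefficient
#> 1 g001  g002       0.918     <- planted +1, recovered with the right sign
#> 3 g003  g004      -1.04      <- planted -1
#> ... (5 small noise terms)

sc  <- score_samples(co$expr, fit$signature)
roc <- select_cutoff(sc, co$clinical, horizon_years = 1)
glance(roc)
#>   horizon   auc cutoff n_cases n_controls
#> 1       1 0.770 -0.177      60        222

grp <- assign_groups(sc, roc$cutoff)
glance(km_logrank(grp, co$clinical))
#>   chi_square  p_value n_total
#> 1       74.1 7.44e-18     300

td_auc(sc, co$clinical)                # AUC at 1/3/5 years: 0.770 0.816 0.810
cox_with_covariates(grp, co$clinical)  # high vs low: HR 3.37 [2.52, 4.52]
```

The planted pairs dominate the fitted signature, the risk groups separate
sharply (log-rank p ≈ 7e-18), and the high-risk group carries a hazard
ratio of about 3.4.

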