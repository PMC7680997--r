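# Frozen oracle values for the published signature, derived by direct
# summation of its printed coefficients before implementation:
SUM_ALL <- -1.542032036
SUM_NEG <- -3.193093497
SUM_POS <- 1.651061461

# expression matrix realizing a chosen indicator for every signature pair
published_expr_with_values <- function(value) {
  sig <- published_signature()
  genes <- signature_genes(sig)
  # ranks chosen so that every pair compares irg1 > irg2 (value 1) or ties (0)
  if (value == 1L) {
    # order genes so each irg1 outranks its irg2: use reverse topological
    # heights via iterative relaxation
    h <- setNames(rep(0, length(genes)), genes)
    for (i in 1:50) {
      for (k in seq_len(nrow(sig))) {
        h[sig$irg1[k]] <- max(h[sig$irg1[k]], h[sig$irg2[k]] + 1)
      }
    }
    m <- matrix(rep(h, 2), ncol = 2, dimnames = list(genes, c("s1", "s2")))
  } else {
    m <- matrix(1, nrow = length(genes), ncol = 2,
                dimnames = list(genes, c("s1", "s2")))
  }
  m
}

test_that("IRGPI of the published signature hits its closed-form extremes", {
  sig <- published_signature()

  expr0 <- published_expr_with_values(0L)
  s0 <- score_samples(expr0, sig)
  expect_equal(s0$irgpi, c(0, 0))
  g0 <- suppressMessages(assign_groups(s0, signature_cutoff(sig)))
  expect_true(all(g0$group == "low"))

  expr1 <- published_expr_with_values(1L)
  # confirm the construction really sets every pair value to 1
  v <- pair_matrix(expr1, sig$irg1, sig$irg2)
  expect_true(all(v == 1L))
  s1 <- score_samples(expr1, sig)
  expect_equal(s1$irgpi, c(SUM_ALL, SUM_ALL), tolerance = 1e-9)
  g1 <- suppressMessages(assign_groups(s1, signature_cutoff(sig)))
  expect_true(all(g1$group == "low"))  # -1.542 < 0.184
})

test_that("scores stay inside the coefficient-sum envelope", {
  sig <- published_signature()
  for (seed in c(21, 22)) {
    set.seed(seed)
    expr <- matrix(2^rnorm(22 * 50, 5, 2), nrow = 22,
                   dimnames = list(signature_genes(sig), paste0("s", 1:50)))
    sc <- score_samples(expr, sig)
    expect_true(all(sc$irgpi >= SUM_NEG - 1e-12))
    expect_true(all(sc$irgpi <= SUM_POS + 1e-12))
  }
})

test_that("scoring is rank-invariant and validates its inputs", {
  sig <- irgp_signature(c("A", "C"), c("B", "D"), c(0.7, -0.4))
  set.seed(8)
  expr <- matrix(2^rnorm(4 * 30, 4, 1.5), nrow = 4,
                 dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:30)))
  sc <- score_samples(expr, sig)
  sc2 <- score_samples(log1p(expr) * 3 + 1, sig)
  expect_identical(sc$irgpi, sc2$irgpi)

  # single pair, value 1 -> score equals the coefficient
  single <- irgp_signature("A", "B", 0.7)
  eA <- matrix(c(2, 1), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  expect_equal(score_samples(eA, single)$irgpi, 0.7)

  expect_error(score_samples(expr[1:3, ], sig), "missing.*D")
  expect_error(score_samples(expr, NULL), "irgp_signature")
})

test_that("select_cutoff separates a perfectly ordered cohort", {
  # cases (event before horizon) all score above controls, no censoring
  cl <- make_clinical(c(0.2, 0.4, 0.6, 2, 3, 4, 5), rep(1, 7))
  sc <- tibble::tibble(sample_id = cl$sample_id,
                       irgpi = c(5, 4.5, 4, 1, 0.8, 0.5, 0.2))
  roc <- select_cutoff(sc, cl, horizon_years = 1)
  expect_equal(roc$auc, 1)
  expect_gt(roc$cutoff, 1)
  expect_lt(roc$cutoff, 4)
  expect_true(roc$cutoff %in% roc$thresholds)
})

test_that("select_cutoff equals exhaustive enumeration on simulated cohorts", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    n <- 50
    t_event <- rexp(n, 0.5)
    t_cens <- rexp(n, 0.25)
    cl <- make_clinical(pmin(t_event, t_cens), as.integer(t_event <= t_cens))
    sc <- tibble::tibble(sample_id = cl$sample_id, irgpi = rnorm(n))
    roc <- select_cutoff(sc, cl, horizon = 1)
    oracle <- oracle_td_roc(sc$irgpi, cl$time, cl$event, 1)
    expect_equal(roc$cutoff, oracle$cutoff)
    expect_equal(roc$auc, oracle$auc, tolerance = 1e-12)
    expect_equal(roc$tpr, oracle$tpr, tolerance = 1e-12)
    expect_equal(roc$fpr, oracle$fpr, tolerance = 1e-12)
  }
})

test_that("ROC coordinates are monotone and the object tidies cleanly", {
  set.seed(44)
  n <- 80
  cl <- make_clinical(rexp(n, 0.4), rbinom(n, 1, 0.8))
  sc <- tibble::tibble(sample_id = cl$sample_id, irgpi = rnorm(n))
  roc <- select_cutoff(sc, cl, horizon = 1)
  expect_true(all(diff(roc$tpr) <= 1e-12))
  expect_true(all(diff(roc$fpr) <= 1e-12))
  td <- tidy(roc)
  expect_equal(nrow(td), length(roc$thresholds))
  expect_equal(glance(roc)$auc, roc$auc)
  expect_error(select_cutoff(sc, make_clinical(rep(10, n), rep(1, n)),
                             horizon = 1),
               "No events before")
})

test_that("assign_groups uses a strict boundary and partitions samples", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"),
                       irgpi = c(0.184, 0.5, -1))
  g <- suppressMessages(assign_groups(sc, 0.184))
  expect_equal(as.character(g$group), c("low", "high", "low"))
  expect_equal(sort(table(g$group))[["high"]], 1L)
  expect_equal(nrow(g), 3L)
  expect_error(assign_groups(sc, NA_real_), "finite")
})
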