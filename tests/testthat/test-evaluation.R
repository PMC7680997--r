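test_that("Kaplan-Meier curves match the product-limit hand computation", {
  cl <- make_clinical(c(1, 2, 3), c(1, 1, 1))
  km <- km_curves(cl)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # censored-only group stays flat at 1
  cl_c <- make_clinical(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_curves(cl_c)$survival == 1))

  # with no censoring the estimator is the empirical survival function
  set.seed(12)
  tt <- sort(rexp(25, 0.3))
  cl_n <- make_clinical(tt, rep(1, 25))
  km_n <- km_curves(cl_n)
  ecdf_surv <- 1 - seq_along(tt) / 25
  expect_equal(km_n$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("km_logrank separates planted risk groups decisively", {
  eff <- sim_binary_cox(300, beta = 1.5, seed = 77, cens_rate = 0.3)
  assign <- tibble::tibble(
    sample_id = eff$clinical$sample_id,
    irgpi = eff$x,
    group = factor(ifelse(eff$x == 1, "high", "low"), c("low", "high"))
  )
  km <- km_logrank(assign, eff$clinical)
  expect_lt(km$p_value, 0.001)
  expect_s3_class(tidy(km), "tbl_df")
  expect_equal(glance(km)$n_total, 300)
  # survival is non-increasing within each group
  for (g in unique(km$curves$group)) {
    expect_true(all(diff(km$curves$survival[km$curves$group == g]) <= 1e-12))
  }

  assign$group <- factor("low", levels = c("low", "high"))
  expect_error(km_logrank(assign, eff$clinical), "two non-empty")
})

test_that("time-dependent AUC is exact on perfect ordering and matches the
           pairwise concordance oracle", {
  cl <- make_clinical(c(0.3, 0.6, 2, 3, 4), rep(1, 5))
  sc <- tibble::tibble(sample_id = cl$sample_id, irgpi = c(9, 8, 3, 2, 1))
  res <- td_auc(sc, cl, horizons_years = 1)
  expect_equal(res$auc, 1)

  set.seed(91)
  n <- 60
  t_event <- rexp(n, 0.5)
  t_cens <- rexp(n, 0.3)
  cl2 <- make_clinical(pmin(t_event, t_cens), as.integer(t_event <= t_cens))
  sc2 <- tibble::tibble(sample_id = cl2$sample_id,
                        irgpi = round(rnorm(n), 1))  # rounding forces ties
  res2 <- td_auc(sc2, cl2, horizons_years = 1)
  oracle <- oracle_td_roc(sc2$irgpi, cl2$time, cl2$event, 1)
  expect_equal(res2$auc, oracle$auc, tolerance = 1e-12)
})

test_that("multivariable Cox matches the univariate fit and flags collinearity", {
  eff <- sim_binary_cox(250, beta = 0.8, seed = 55)
  assign <- tibble::tibble(
    sample_id = eff$clinical$sample_id,
    irgpi = eff$x,
    group = factor(ifelse(eff$x == 1, "high", "low"), c("low", "high"))
  )
  uni <- univariate_cox(eff$clinical, eff$x)
  multi <- cox_with_covariates(assign, eff$clinical)
  expect_equal(multi$hazard_ratio[multi$term == "risk"], uni$hazard_ratio,
               tolerance = 1e-10)
  expect_equal(multi$p_value[multi$term == "risk"], uni$p_value,
               tolerance = 1e-10)

  cl <- eff$clinical
  cl$dup1 <- rnorm(250)
  cl$dup2 <- cl$dup1
  expect_error(cox_with_covariates(assign, cl, c("dup1", "dup2")),
               "Collinear")
})

test_that("an independent covariate leaves the signature hazard ratio stable", {
  eff <- sim_binary_cox(400, beta = 1, seed = 66)
  cl <- eff$clinical
  set.seed(67)
  cl$noise <- rnorm(400)
  assign <- tibble::tibble(
    sample_id = cl$sample_id, irgpi = eff$x,
    group = factor(ifelse(eff$x == 1, "high", "low"), c("low", "high"))
  )
  uni <- cox_with_covariates(assign, cl)
  multi <- cox_with_covariates(assign, cl, "noise")
  hr_u <- uni$hazard_ratio[uni$term == "risk"]
  hr_m <- multi$hazard_ratio[multi$term == "risk"]
  expect_lt(abs(hr_m - hr_u) / hr_u, 0.10)
})

test_that("a planted confounder attenuates the signature hazard ratio", {
  set.seed(68)
  n <- 400
  conf <- rnorm(n)
  x <- as.integer(conf + rnorm(n, sd = 0.8) > 0)  # score correlated with conf
  t_event <- rexp(n, 0.2 * exp(0.5 * x + 0.8 * conf))
  cl <- make_clinical(t_event, rep(1, n))
  cl$conf <- conf
  assign <- tibble::tibble(
    sample_id = cl$sample_id, irgpi = x,
    group = factor(ifelse(x == 1, "high", "low"), c("low", "high"))
  )
  uni <- cox_with_covariates(assign, cl)
  multi <- cox_with_covariates(assign, cl, "conf")
  expect_lt(multi$hazard_ratio[multi$term == "risk"],
            uni$hazard_ratio[uni$term == "risk"])
})

test_that("stage covariates can enter as ordinal or categorical", {
  eff <- sim_binary_cox(200, beta = 0.8, seed = 58)
  cl <- eff$clinical
  set.seed(59)
  cl$stage <- sample(c("Stage I", "Stage II", "III", "IV"), 200, replace = TRUE)
  assign <- tibble::tibble(
    sample_id = cl$sample_id, irgpi = eff$x,
    group = factor(ifelse(eff$x == 1, "high", "low"), c("low", "high"))
  )
  ord <- cox_with_covariates(assign, cl, "stage")
  expect_true("stage" %in% ord$term)  # single ordinal slope
  cat_fit <- cox_with_covariates(assign, cl, "stage",
                                 stage_as = "categorical")
  expect_equal(sum(grepl("^stage", cat_fit$term)), 3L)  # 4 levels - ref
})

test_that("binary ROC equals the rank-sum identity and its symmetries", {
  set.seed(71)
  score <- round(rnorm(30), 1)
  labels <- rbinom(30, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  res <- binary_roc(score, labels)
  w <- wilcox.test(score[labels == 1], score[labels == 0], exact = FALSE)
  u_auc <- unname(w$statistic) / (sum(labels == 1) * sum(labels == 0))
  expect_equal(res$auc, u_auc, tolerance = 1e-12)

  # complement symmetry and monotone invariance
  res_neg <- binary_roc(-score, labels)
  expect_equal(res_neg$auc, 1 - res$auc, tolerance = 1e-12)
  res_tr <- binary_roc(exp(score), labels)
  expect_equal(res_tr$auc, res$auc, tolerance = 1e-12)

  # labels derived from the scores give perfect discrimination
  lab2 <- as.integer(score > median(score))
  expect_equal(binary_roc(score, lab2)$auc, 1, tolerance = 0.02)

  expect_error(binary_roc(score, rep(1, 30)), "non-empty")
})

test_that("binary ROC is null-calibrated on independent labels", {
  set.seed(72)
  score <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_gt(binary_roc(score, labels)$auc, 0.47)
  expect_lt(binary_roc(score, labels)$auc, 0.53)
})
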