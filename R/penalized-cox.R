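#' Fit an L1-penalized Cox model over screened gene pairs
#'
#' Lasso Cox regression on the binary pair indicators with k-fold
#' cross-validation of the partial-likelihood deviance
#' (Verweij-van Houwelingen form, as computed by [glmnet::cv.glmnet()]).
#' Folds are stratified by event status and drawn from the supplied seed,
#' so the whole path and the chosen model are reproducible. The returned
#' signature contains exactly the pairs with non-zero coefficients at the
#' chosen penalty; coefficients are the penalized estimates (no
#' unpenalized refit). Binary pair indicators share a common scale by
#' construction, so they are not standardized by default.
#'
#' @param pm A (typically screened) `pair_matrix` with >= 2 pairs.
#' @param clinical Clinical tibble covering all samples of `pm`.
#' @param n_folds Number of cross-validation folds. Default 10.
#' @param seed Integer seed for the fold assignment (required, recorded in
#'   the signature metadata).
#' @param lambda_rule `"min"` (default) takes the penalty minimizing the
#'   cross-validated deviance; `"1se"` the largest penalty within one
#'   standard error of that minimum.
#' @param standardize Standardize columns before penalization? Default
#'   `FALSE`.
#' @param lambda Optional decreasing penalty sequence to use instead of the
#'   automatic one (may include 0 for the unpenalized limit).
#' @return A list of class `irgp_lasso_fit`: `signature` (an
#'   [irgp_signature()], possibly with zero rows reported via a warning and
#'   a `NULL` signature), and `path` (class `irgp_lasso_path`: `lambdas`,
#'   `coefficients` pairs-x-lambdas matrix, `cv_mean`, `cv_se`,
#'   `chosen_lambda`, `lambda_rule`, `foldid`).
#' @export
fit_lasso_cox <- function(pm, clinical, n_folds = 10L, seed,
                          lambda_rule = c("min", "1se"),
                          standardize = FALSE, lambda = NULL) {
  stopifnot(inherits(pm, "pair_matrix"))
  lambda_rule <- match.arg(lambda_rule)
  if (nrow(pm) < 2L) abort("Need at least two pairs to fit the lasso.")
  if (missing(seed)) abort("`seed` is required for reproducible folds.")
  cl <- clinical[match(colnames(pm), clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id)) abort("Pair-matrix samples missing from clinical table.")
  n_events <- sum(cl$event)
  if (n_events == 0L) abort("No events: cannot fit a Cox model.")
  if (n_events < n_folds) {
    abort(sprintf("Need at least %d events for %d-fold cross-validation.",
                  n_folds, n_folds))
  }

  x <- t(unclass(pm))
  y <- survival::Surv(cl$time, cl$event)
  foldid <- with_seed(seed, stratified_folds(cl$event, n_folds))

  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                             type.measure = "deviance",
                             standardize = standardize, lambda = lambda,
                             thresh = 1e-10)
  chosen <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- as.matrix(glmnet::coef.glmnet(cvfit$glmnet.fit))
  path <- structure(
    list(
      lambdas = cvfit$lambda,
      coefficients = beta,
      cv_mean = cvfit$cvm,
      cv_se = cvfit$cvsd,
      chosen_lambda = chosen,
      lambda_rule = lambda_rule,
      foldid = foldid
    ),
    class = "irgp_lasso_path"
  )

  b <- as.numeric(glmnet::coef.glmnet(cvfit, s = chosen))
  active <- which(b != 0)
  if (length(active) == 0L) {
    warn("All coefficients are zero at the chosen penalty: empty signature.")
    sig <- NULL
  } else {
    sig <- irgp_signature(
      irg1 = attr(pm, "irg1")[active],
      irg2 = attr(pm, "irg2")[active],
      coefficient = b[active],
      meta = list(seed = seed, n_folds = n_folds, lambda = chosen,
                  lambda_rule = lambda_rule, n = nrow(cl),
                  n_events = n_events)
    )
  }
  structure(list(signature = sig, path = path), class = "irgp_lasso_fit")
}

# deterministic event-stratified fold labels (call inside with_seed)
stratified_folds <- function(event, n_folds) {
  foldid <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' @export
print.irgp_lasso_fit <- function(x, ...) {
  n_active <- if (is.null(x$signature)) 0L else nrow(x$signature)
  cat(sprintf("<irgp_lasso_fit> %d active pair(s) at lambda = %.4g (%s rule)\n",
              n_active, x$path$chosen_lambda, x$path$lambda_rule))
  invisible(x)
}

#' @rdname fit_lasso_cox
#' @param x An `irgp_lasso_fit`.
#' @param ... Unused.
#' @method tidy irgp_lasso_fit
#' @export
tidy.irgp_lasso_fit <- function(x, ...) {
  if (is.null(x$signature)) {
    return(tibble::tibble(irg1 = character(), irg2 = character(),
                          coefficient = numeric()))
  }
  tidy(x$signature)
}

#' @rdname fit_lasso_cox
#' @method glance irgp_lasso_fit
#' @export
glance.irgp_lasso_fit <- function(x, ...) {
  i <- which.min(abs(x$path$lambdas - x$path$chosen_lambda))
  tibble::tibble(
    n_pairs = if (is.null(x$signature)) 0L else nrow(x$signature),
    lambda = x$path$chosen_lambda,
    lambda_rule = x$path$lambda_rule,
    cv_deviance = x$path$cv_mean[i],
    cv_se = x$path$cv_se[i]
  )
}

#' Tidy a lasso path
#'
#' @param x An `irgp_lasso_path`.
#' @param ... Unused.
#' @return A tibble with one row per lambda: `lambda`, `n_active`,
#'   `cv_deviance`, `cv_se`.
#' @method tidy irgp_lasso_path
#' @export
tidy.irgp_lasso_path <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambdas,
    n_active = unname(colSums(x$coefficients != 0)),
    cv_deviance = x$cv_mean,
    cv_se = x$cv_se
  )
}

#' Plot the cross-validation curve of a lasso path
#'
#' @param object An `irgp_lasso_path`.
#' @param ... Unused.
#' @return A ggplot of cross-validated deviance (+/- 1 SE) against
#'   log(lambda), with the chosen penalty marked.
#' @method autoplot irgp_lasso_path
#' @export
autoplot.irgp_lasso_path <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda),
                                   y = .data$cv_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_deviance - .data$cv_se,
                                      ymax = .data$cv_deviance + .data$cv_se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$chosen_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "CV partial-likelihood deviance")
}
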