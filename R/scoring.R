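#' Compute IRGPI risk scores
#'
#' The immune-related gene-pairs index (IRGPI) of a sample is the sum of
#' the signature coefficients over the pairs whose first gene is expressed
#' strictly above the second in that sample:
#' IRGPI(s) = sum_k value_k(s) * coef_k with value_k(s) = 1 iff
#' expr[irg1_k, s] > expr[irg2_k, s], else 0. Pair orientation is the
#' signature's own (for the published signature, the printed table order).
#' Only within-sample ranks enter, so the score is invariant under any
#' strictly increasing per-sample transform of the expression values.
#'
#' @param expr Expression matrix (genes x samples) containing every
#'   signature gene.
#' @param sig An [irgp_signature()].
#' @return A tibble with columns `sample_id`, `irgpi`.
#' @export
#' @examples
#' sig <- published_signature()
#' expr <- matrix(1, nrow = 22, ncol = 2,
#'                dimnames = list(signature_genes(sig), c("s1", "s2")))
#' score_samples(expr, sig)  # all comparisons tie -> every value 0
score_samples <- function(expr, sig) {
  if (is.null(sig) || !inherits(sig, "irgp_signature")) {
    abort("`sig` must be a non-empty irgp_signature.")
  }
  missing <- setdiff(signature_genes(sig), rownames(expr))
  if (length(missing)) {
    abort(sprintf("Signature gene(s) missing from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  v <- pair_matrix(expr, sig$irg1, sig$irg2)
  irgpi <- colSums(unclass(v) * sig$coefficient)
  tibble::tibble(
    sample_id = colnames(expr) %||% as.character(seq_len(ncol(expr))),
    irgpi = unname(irgpi)
  )
}

# Cumulative/dynamic time-dependent ROC at a horizon with Kaplan-Meier
# inverse-probability-of-censoring weights. Cases: event <= horizon;
# controls: follow-up beyond the horizon; samples censored before the
# horizon enter through the censoring-distribution weights, not exclusion.
td_roc_compute <- function(score, time, event, horizon) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case)) abort("No events before the horizon.")
  if (!any(is_ctrl)) abort("No at-risk samples beyond the horizon.")

  # Kaplan-Meier estimate of the censoring survival G(t) = P(C > t)
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  surv_step <- c(1, sf$surv)
  g_right <- function(q) surv_step[findInterval(q, sf$time) + 1L]
  g_left <- function(q) {
    surv_step[findInterval(q, sf$time, left.open = TRUE) + 1L]
  }
  w_case <- 1 / g_left(time[is_case])
  w_ctrl <- rep(1 / g_right(horizon), sum(is_ctrl))
  if (any(!is.finite(c(w_case, w_ctrl)))) {
    abort("Censoring weights are unbounded at the horizon; choose an earlier horizon.")
  }
  s_case <- score[is_case]
  s_ctrl <- score[is_ctrl]
  W1 <- sum(w_case)
  W0 <- sum(w_ctrl)

  s_distinct <- sort(unique(c(s_case, s_ctrl)))
  mids <- if (length(s_distinct) > 1L) {
    (s_distinct[-1L] + s_distinct[-length(s_distinct)]) / 2
  } else {
    numeric()
  }
  thresholds <- c(-Inf, mids, Inf)
  tpr <- vapply(thresholds, function(c) sum(w_case[s_case > c]) / W1, 0)
  fpr <- vapply(thresholds, function(c) sum(w_ctrl[s_ctrl > c]) / W0, 0)

  # weighted case/control concordance (ties count half)
  cmp <- outer(s_case, s_ctrl, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- as.numeric(w_case %*% cmp %*% w_ctrl) / (W1 * W0)

  d2 <- fpr^2 + (1 - tpr)^2
  best <- which(d2 <= min(d2) + 1e-12)[1L]  # ties -> lower threshold
  list(horizon = horizon, thresholds = thresholds, tpr = tpr, fpr = fpr,
       auc = auc, cutoff = thresholds[best],
       n_cases = sum(is_case), n_controls = sum(is_ctrl))
}

#' Choose a risk cutoff by time-dependent ROC
#'
#' Computes the cumulative/dynamic time-dependent ROC of the risk score at
#' a fixed horizon (cases: event by the horizon; controls: follow-up past
#' it), using Kaplan-Meier inverse-probability-of-censoring weights, and
#' picks the score threshold whose (FPR, TPR) point is closest (Euclidean)
#' to the ideal corner (0, 1). Candidate thresholds are the midpoints
#' between consecutive distinct scores plus the two infinities; threshold
#' ties are broken toward the lower threshold (larger high-risk group).
#'
#' @param scores Tibble from [score_samples()] (columns `sample_id`,
#'   `irgpi`).
#' @param clinical Clinical tibble covering all scored samples.
#' @param horizon_years Horizon in years (default 1), converted with the
#'   clinical table's declared time unit.
#' @param horizon Horizon directly in the table's time units; overrides
#'   `horizon_years` when given.
#' @return An object of class `td_roc`: `horizon`, `thresholds`, `tpr`,
#'   `fpr`, `auc`, `cutoff`, `n_cases`, `n_controls`. Use [tidy()] for the
#'   curve, [glance()] for the summary, [autoplot()] to plot.
#' @export
select_cutoff <- function(scores, clinical, horizon_years = 1,
                          horizon = NULL) {
  al <- align_scores(scores, clinical)
  h <- horizon %||% horizon_in_units(horizon_years, clinical)
  out <- td_roc_compute(al$irgpi, al$time, al$event, h)
  structure(out, class = "td_roc")
}

#' Time-dependent AUC at fixed horizons
#'
#' @param scores Tibble from [score_samples()].
#' @param clinical Clinical tibble covering all scored samples.
#' @param horizons_years Numeric vector of horizons in years (default
#'   1, 3, 5), converted with the table's declared time unit.
#' @return A tibble with columns `horizon_years`, `horizon`, `auc`,
#'   `n_cases`, `n_controls`.
#' @export
td_auc <- function(scores, clinical, horizons_years = c(1, 3, 5)) {
  al <- align_scores(scores, clinical)
  purrr::map_dfr(horizons_years, function(hy) {
    h <- horizon_in_units(hy, clinical)
    r <- td_roc_compute(al$irgpi, al$time, al$event, h)
    tibble::tibble(horizon_years = hy, horizon = h, auc = r$auc,
                   n_cases = r$n_cases, n_controls = r$n_controls)
  })
}

#' Assign high/low risk groups
#'
#' A sample is high risk exactly when its score strictly exceeds the
#' cutoff (a score equal to the cutoff is low risk).
#'
#' @param scores Tibble from [score_samples()].
#' @param cutoff Single finite risk threshold (e.g.
#'   `signature_cutoff(published_signature())` or `select_cutoff()$cutoff`).
#' @return A tibble with `sample_id`, `irgpi` and `group` (factor
#'   low/high). Group sizes are reported with a message.
#' @export
assign_groups <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    abort("`cutoff` must be a single finite number.")
  }
  out <- tibble::tibble(
    sample_id = scores$sample_id,
    irgpi = scores$irgpi,
    group = factor(ifelse(scores$irgpi > cutoff, "high", "low"),
                   levels = c("low", "high"))
  )
  inform(sprintf("Risk groups at cutoff %g: %d high, %d low.",
                 cutoff, sum(out$group == "high"), sum(out$group == "low")))
  out
}

# join scores to clinical rows, erroring on unmatched samples
align_scores <- function(scores, clinical) {
  if (!all(c("sample_id", "irgpi") %in% colnames(scores))) {
    abort("`scores` needs columns sample_id and irgpi.")
  }
  idx <- match(scores$sample_id, clinical$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("Scored sample(s) absent from clinical table: %s",
                  paste(head(scores$sample_id[is.na(idx)], 5L), collapse = ", ")))
  }
  tibble::tibble(irgpi = scores$irgpi,
                 time = clinical$time[idx],
                 event = clinical$event[idx])
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "<td_roc> horizon %g: AUC %.3f, cutoff %g (%d cases, %d controls)\n",
    x$horizon, x$auc, x$cutoff, x$n_cases, x$n_controls))
  invisible(x)
}

#' @rdname select_cutoff
#' @param x A `td_roc`.
#' @param ... Unused.
#' @method tidy td_roc
#' @export
tidy.td_roc <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' @rdname select_cutoff
#' @method glance td_roc
#' @export
glance.td_roc <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, auc = x$auc, cutoff = x$cutoff,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' Plot a time-dependent ROC curve
#'
#' @param object A `td_roc` from [select_cutoff()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chosen cutoff marked.
#' @method autoplot td_roc
#' @export
autoplot.td_roc <- function(object, ...) {
  df <- tidy(object)
  chosen <- df[df$threshold == object$cutoff, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = chosen, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate",
      title = sprintf("Time-dependent ROC (horizon %g), AUC = %.3f",
                      object$horizon, object$auc)
    )
}
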