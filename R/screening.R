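#' Two-sample log-rank test
#'
#' Mantel-Haenszel log-rank comparison of overall survival between two
#' groups, with the p-value from a chi-square distribution on 1 df.
#' Invariant under relabeling of the two groups.
#'
#' @param clinical Clinical tibble with `time` and `event` columns (see
#'   [read_clinical()]).
#' @param group Vector with exactly two distinct values (e.g. 0/1 or
#'   high/low), aligned with the rows of `clinical`.
#' @return One-row tibble: `chi_square`, `p_value`, `n_events`.
#' @export
logrank_test <- function(clinical, group) {
  if (length(group) != nrow(clinical)) {
    abort("`group` must align with the clinical rows.")
  }
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    abort("Need exactly two non-empty groups.")
  }
  n_events <- sum(clinical$event)
  if (n_events == 0L) {
    warn("No events observed; log-rank test is uninformative.")
    return(tibble::tibble(chi_square = 0, p_value = 1, n_events = 0L))
  }
  sd <- survival::survdiff(
    survival::Surv(clinical$time, clinical$event) ~ g
  )
  chi <- unname(sd$chisq)
  tibble::tibble(
    chi_square = chi,
    p_value = pchisq(chi, df = 1L, lower.tail = FALSE),
    n_events = as.integer(n_events)
  )
}

#' Univariate Cox proportional-hazards association
#'
#' Partial-likelihood fit of a single covariate against overall survival,
#' with Efron tie handling and a Wald confidence interval. Fits with
#' monotone likelihood (perfect separation, unbounded coefficient) are
#' flagged rather than reported as estimates.
#'
#' @param clinical Clinical tibble with `time` and `event`.
#' @param x Numeric or binary covariate aligned with `clinical`.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return One-row tibble: `hazard_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `flagged` (TRUE when the fit is unreliable).
#' @export
univariate_cox <- function(clinical, x, conf_level = 0.95) {
  if (length(x) != nrow(clinical)) abort("`x` must align with the clinical rows.")
  x <- as.numeric(x)
  if (length(unique(x)) < 2L) abort("Covariate is constant.")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(clinical$time, clinical$event) ~ x,
                    ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) flagged <- TRUE
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = pchisq((beta / se)^2, df = 1L, lower.tail = FALSE),
    flagged = flagged
  )
}

#' Screen gene pairs for association with overall survival
#'
#' Runs, for every pair, the two-sample log-rank test and the univariate
#' Cox fit of the binary pair indicator, then keeps the pairs whose
#' p-value (Cox by default, log-rank on request) falls below `alpha`.
#' P-values are raw: screening feeds a penalized model that handles
#' selection, so no multiplicity correction is applied here. Pairs with a
#' constant indicator or an unstable (flagged) Cox fit are excluded.
#'
#' @param pm A `pair_matrix` whose samples all appear in `clinical`.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param alpha Retention threshold on the selection p-value. Default 0.05.
#' @param select_on `"cox"` (default) or `"logrank"`: which p-value the
#'   `alpha` threshold applies to.
#' @return A tibble of the retained pairs sorted by the selection p-value:
#'   `irg1`, `irg2`, `hazard_ratio`, `ci_low`, `ci_high`, `chi_square`,
#'   `logrank_p`, `p_value` (the selection p). The full per-pair table
#'   (including excluded pairs, with a `flagged` column) is in attribute
#'   `"all_results"`.
#' @export
screen_pairs <- function(pm, clinical, alpha = 0.05,
                         select_on = c("cox", "logrank")) {
  stopifnot(inherits(pm, "pair_matrix"))
  select_on <- match.arg(select_on)
  missing <- setdiff(colnames(pm), clinical$sample_id)
  if (length(missing)) {
    abort(sprintf("Pair-matrix sample(s) absent from clinical table: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  cl <- clinical[match(colnames(pm), clinical$sample_id), , drop = FALSE]

  rows <- purrr::map(seq_len(nrow(pm)), function(i) {
    z <- pm[i, ]
    if (length(unique(z)) < 2L) {
      return(tibble::tibble(hazard_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, cox_p = NA_real_,
                            chi_square = NA_real_, logrank_p = NA_real_,
                            flagged = TRUE))
    }
    cox <- univariate_cox(cl, z)
    lr <- suppressWarnings(logrank_test(cl, z))
    tibble::tibble(hazard_ratio = cox$hazard_ratio, ci_low = cox$ci_low,
                   ci_high = cox$ci_high, cox_p = cox$p_value,
                   chi_square = lr$chi_square, logrank_p = lr$p_value,
                   flagged = cox$flagged)
  })
  res <- dplyr::bind_cols(
    tibble::tibble(irg1 = attr(pm, "irg1"), irg2 = attr(pm, "irg2")),
    dplyr::bind_rows(rows)
  )
  res$p_value <- if (select_on == "cox") res$cox_p else res$logrank_p

  out <- res |>
    dplyr::filter(!.data$flagged, .data$p_value < alpha) |>
    dplyr::arrange(.data$p_value) |>
    dplyr::select("irg1", "irg2", "hazard_ratio", "ci_low", "ci_high",
                  "chi_square", "logrank_p", "p_value")
  attr(out, "all_results") <- res
  attr(out, "alpha") <- alpha
  attr(out, "select_on") <- select_on
  out
}
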