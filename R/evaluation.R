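#' Kaplan-Meier curves for arbitrary groupings
#'
#' Product-limit survival estimates per group (a single group is allowed;
#' for the two-group comparison with a log-rank test use [km_logrank()]).
#'
#' @param clinical Clinical tibble with `time` and `event`.
#' @param group Optional grouping vector aligned with `clinical`; `NULL`
#'   pools all samples.
#' @return A tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curves <- function(clinical, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(clinical))
  if (length(group) != nrow(clinical)) {
    abort("`group` must align with the clinical rows.")
  }
  g <- factor(group)
  purrr::map_dfr(levels(g), function(lev) {
    sub <- clinical[g == lev, , drop = FALSE]
    sf <- survival::survfit(survival::Surv(sub$time, sub$event) ~ 1)
    tibble::tibble(group = lev, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, survival = sf$surv)
  })
}

#' Compare survival between risk groups
#'
#' Kaplan-Meier curves per risk group plus the two-sample log-rank test.
#'
#' @param assign Risk assignment tibble from [assign_groups()] (columns
#'   `sample_id`, `group`).
#' @param clinical Clinical tibble covering the assigned samples.
#' @return An object of class `irgp_km`: `curves` (tibble as from
#'   [km_curves()]), `chi_square`, `p_value`, `n` (samples per group).
#'   [tidy()] returns the curves, [glance()] the test summary,
#'   [autoplot()] draws the step curves.
#' @export
km_logrank <- function(assign, clinical) {
  idx <- match(assign$sample_id, clinical$sample_id)
  if (anyNA(idx)) abort("Assigned sample(s) absent from clinical table.")
  cl <- clinical[idx, , drop = FALSE]
  g <- factor(assign$group)
  g <- droplevels(g)
  if (nlevels(g) != 2L) abort("Need exactly two non-empty risk groups.")
  lr <- logrank_test(cl, g)
  structure(
    list(curves = km_curves(cl, g),
         chi_square = lr$chi_square,
         p_value = lr$p_value,
         n = table(g)),
    class = "irgp_km"
  )
}

#' @export
print.irgp_km <- function(x, ...) {
  cat(sprintf("<irgp_km> log-rank chi-square %.3f, p = %.3g (%s)\n",
              x$chi_square, x$p_value,
              paste(sprintf("%s n=%d", names(x$n), as.integer(x$n)),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname km_logrank
#' @param x An `irgp_km`.
#' @param ... Unused.
#' @method tidy irgp_km
#' @export
tidy.irgp_km <- function(x, ...) x$curves

#' @rdname km_logrank
#' @method glance irgp_km
#' @export
glance.irgp_km <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, p_value = x$p_value,
                 n_total = sum(x$n))
}

#' Plot Kaplan-Meier curves
#'
#' @param object An `irgp_km` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of the per-group survival step functions.
#' @method autoplot irgp_km
#' @export
autoplot.irgp_km <- function(object, ...) {
  df <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(time = c(0, .data$time), survival = c(1, .data$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Risk",
                  subtitle = sprintf("log-rank p = %.3g", object$p_value))
}

#' Cox regression of the risk signature with clinical covariates
#'
#' Fits a Cox proportional-hazards model (Efron ties) of overall survival
#' on the risk signature — entered as the binary high/low group by default,
#' or as the continuous score — together with any clinical covariates.
#' Character/factor covariates are modelled against their first level as
#' reference; a covariate named `stage` given as Roman numerals (I-IV,
#' optionally prefixed "Stage ") is treated as ordinal numeric by default.
#'
#' @param assign Risk tibble from [assign_groups()] (needs `sample_id` and
#'   `group` and/or `irgpi`).
#' @param clinical Clinical tibble holding the covariate columns.
#' @param covariates Character vector of clinical column names to adjust
#'   for (default none: univariable model of the signature).
#' @param use `"group"` (default) enters the binary risk group (high vs
#'   low); `"score"` enters the continuous IRGPI.
#' @param stage_as `"ordinal"` (default) or `"categorical"` handling of a
#'   `stage` covariate.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (log-HR), `hazard_ratio`, `ci_low`, `ci_high`, `p_value`; attributes
#'   `n` and `n_events`.
#' @export
cox_with_covariates <- function(assign, clinical, covariates = character(),
                                use = c("group", "score"),
                                stage_as = c("ordinal", "categorical"),
                                conf_level = 0.95) {
  use <- match.arg(use)
  stage_as <- match.arg(stage_as)
  idx <- match(assign$sample_id, clinical$sample_id)
  if (anyNA(idx)) abort("Assigned sample(s) absent from clinical table.")
  cl <- clinical[idx, , drop = FALSE]
  miss <- setdiff(covariates, colnames(cl))
  if (length(miss)) {
    abort(sprintf("Covariate(s) not in clinical table: %s",
                  paste(miss, collapse = ", ")))
  }

  df <- data.frame(time = cl$time, event = cl$event)
  df$risk <- if (use == "group") {
    as.integer(assign$group == "high")
  } else {
    assign$irgpi
  }
  for (cv in covariates) {
    v <- cl[[cv]]
    if (cv == "stage" && stage_as == "ordinal" && !is.numeric(v)) {
      v <- stage_to_ordinal(v)
    } else if (is.character(v)) {
      v <- factor(v)
    }
    df[[cv]] <- v
  }

  terms <- c("risk", covariates)
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))),
                            data = df)[, -1L, drop = FALSE]
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    abort(sprintf("Collinear covariate term(s): %s",
                  paste(aliased, collapse = ", ")))
  }

  fit <- survival::coxph(fml, data = df, ties = "efron")
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    hazard_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_value = pchisq((unname(beta) / se)^2, df = 1L, lower.tail = FALSE)
  )
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  out
}

# "Stage II"/"II"/2 -> 2, etc.
stage_to_ordinal <- function(v) {
  s <- toupper(trimws(gsub("(?i)^stage\\s*", "", as.character(v), perl = TRUE)))
  map <- c(I = 1, II = 2, III = 3, IV = 4)
  out <- unname(map[s])
  numeric_in <- suppressWarnings(as.numeric(s))
  out[is.na(out)] <- numeric_in[is.na(out)]
  if (anyNA(out)) warn("Unrecognized stage label(s) set to NA.")
  out
}

#' Binary diagnostic ROC AUC
#'
#' Plain (non-survival) ROC area under the curve of a score against a
#' binary class label, with midrank tie handling — equivalently the
#' Mann-Whitney probability that a randomly chosen case scores above a
#' randomly chosen control (ties counting one half).
#'
#' @param scores Numeric score vector, or a tibble with an `irgpi` column.
#' @param labels Binary labels aligned with the scores (1/TRUE = case).
#' @return One-row tibble: `auc`, `n_cases`, `n_controls`.
#' @export
binary_roc <- function(scores, labels) {
  if (is.data.frame(scores)) scores <- scores$irgpi
  lab <- as.integer(as.logical(labels))
  if (length(lab) != length(scores)) abort("`labels` must align with `scores`.")
  if (length(unique(lab)) != 2L) abort("Both classes must be non-empty.")
  r <- pROC::roc(response = lab, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  tibble::tibble(auc = as.numeric(pROC::auc(r)),
                 n_cases = sum(lab == 1L),
                 n_controls = sum(lab == 0L))
}
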