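# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (double loops, exhaustive enumeration) so they cannot share bugs
# with the vectorized implementation they check.

make_clinical <- function(time, event, sample_id = NULL, unit = "years") {
  if (is.null(sample_id)) sample_id <- paste0("s", seq_along(time))
  out <- tibble::tibble(sample_id = sample_id, time = time, event = event)
  attr(out, "time_unit") <- unit
  out
}

random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 5, 2),
              nrow = n_genes, ncol = n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

write_tsv_fixture <- function(df, dir = tempdir(), ext = ".tsv", sep = "\t") {
  path <- tempfile(tmpdir = dir, fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# brute-force pair indicators: explicit loop over pairs and samples
oracle_pair_values <- function(expr, irg1, irg2) {
  out <- matrix(0L, nrow = length(irg1), ncol = ncol(expr))
  for (k in seq_along(irg1)) {
    for (s in seq_len(ncol(expr))) {
      out[k, s] <- if (expr[irg1[k], s] > expr[irg2[k], s]) 1L else 0L
    }
  }
  rownames(out) <- paste(irg1, irg2, sep = "|")
  colnames(out) <- colnames(expr)
  out
}

# naive IPCW time-dependent ROC: loops over candidate thresholds and
# case/control pairs, recomputing every weighted sum from scratch
oracle_td_roc <- function(score, time, event, horizon) {
  km_cens <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(q, strict = FALSE) {
    keep <- if (strict) km_cens$time < q else km_cens$time <= q
    if (!any(keep)) 1 else km_cens$surv[max(which(keep))]
  }
  cases <- which(time <= horizon & event == 1)
  ctrls <- which(time > horizon)
  wc <- vapply(cases, function(i) 1 / G(time[i], strict = TRUE), 0)
  wk <- rep(1 / G(horizon), length(ctrls))

  ss <- sort(unique(score[c(cases, ctrls)]))
  thr <- c(-Inf, if (length(ss) > 1) (ss[-1] + ss[-length(ss)]) / 2, Inf)
  tpr <- fpr <- numeric(length(thr))
  for (j in seq_along(thr)) {
    tpr[j] <- sum(wc * (score[cases] > thr[j])) / sum(wc)
    fpr[j] <- sum(wk * (score[ctrls] > thr[j])) / sum(wk)
  }
  num <- 0
  for (a in seq_along(cases)) {
    for (b in seq_along(ctrls)) {
      si <- score[cases[a]]; sj <- score[ctrls[b]]
      num <- num + wc[a] * wk[b] * ((si > sj) + 0.5 * (si == sj))
    }
  }
  d <- sqrt(fpr^2 + (1 - tpr)^2)
  best <- which(d == min(d))
  list(thresholds = thr, tpr = tpr, fpr = fpr,
       auc = num / (sum(wc) * sum(wk)),
       cutoff = thr[min(best)])
}

# subset a pair_matrix by rowname without touching package internals
subset_pairs_for_test <- function(pm, keys) {
  keep <- rownames(pm) %in% keys
  structure(unclass(pm)[keep, , drop = FALSE],
            irg1 = attr(pm, "irg1")[keep],
            irg2 = attr(pm, "irg2")[keep],
            class = c("pair_matrix", "matrix"))
}

# simulated survival cohort with a binary risk factor, for Cox checks
sim_binary_cox <- function(n, beta, seed, cens_rate = 0.5) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.2 * exp(beta * x))
  t_cens <- rexp(n, rate = cens_rate * 0.2)
  list(x = x,
       clinical = make_clinical(pmin(t_event, t_cens),
                                as.integer(t_event <= t_cens)))
}
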