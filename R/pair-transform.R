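#' Filter genes by median absolute deviation
#'
#' Keeps the genes whose across-sample variability exceeds a threshold in
#' every supplied cohort. Variability is the unscaled median absolute
#' deviation, MAD = median(|x - median(x)|), with no consistency constant.
#' A gene absent from any cohort is dropped; nothing is pooled across
#' cohorts — the statistic is per cohort, the decision is the intersection.
#'
#' @param exprs A single expression matrix (genes x samples) or a named
#'   list of such matrices, one per cohort.
#' @param genes Character vector of candidate gene symbols (e.g. an immune
#'   gene list).
#' @param threshold Keep genes with MAD strictly greater than this in every
#'   cohort. Default 0.5.
#' @return A tibble with one row per candidate gene: `gene`, one `mad_*`
#'   column per cohort (`NA` where the gene is absent) and logical `kept`.
#' @export
mad_filter <- function(exprs, genes, threshold = 0.5) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  if (is.matrix(exprs)) exprs <- list(cohort = exprs)
  if (!length(exprs)) abort("Supply at least one cohort.")
  if (is.null(names(exprs)) || any(!nzchar(names(exprs)))) {
    names(exprs) <- paste0("cohort", seq_along(exprs))
  }
  genes <- unique(as.character(genes))
  mads <- purrr::map(exprs, function(m) {
    idx <- match(genes, rownames(m))
    out <- rep(NA_real_, length(genes))
    present <- !is.na(idx)
    if (any(present)) {
      out[present] <- apply(m[idx[present], , drop = FALSE], 1L,
                            stats::mad, constant = 1)
    }
    out
  })
  kept <- Reduce(`&`, purrr::map(mads, function(v) !is.na(v) & v > threshold))
  if (!any(kept)) {
    abort(sprintf(
      "No gene passes MAD > %g in every cohort; consider a lower threshold.",
      threshold))
  }
  out <- tibble::tibble(gene = genes)
  for (nm in names(mads)) out[[paste0("mad_", nm)]] <- mads[[nm]]
  out$kept <- kept
  out
}

#' Construct a binary pair-by-sample matrix
#'
#' Low-level constructor for an explicit list of oriented pairs; most users
#' want [build_pairs()]. Each cell is 1 when `irg1`'s expression strictly
#' exceeds `irg2`'s in that sample, 0 otherwise (ties are 0).
#'
#' @param expr Expression matrix (genes x samples).
#' @param irg1,irg2 Character vectors of oriented pair members; all symbols
#'   must be rows of `expr`.
#' @return An integer matrix of class `pair_matrix` (pairs x samples) with
#'   rownames `"IRG1|IRG2"` and attributes `irg1`, `irg2`.
#' @export
pair_matrix <- function(expr, irg1, irg2) {
  irg1 <- as.character(irg1)
  irg2 <- as.character(irg2)
  if (length(irg1) != length(irg2)) abort("`irg1` and `irg2` lengths differ.")
  if (any(irg1 == irg2)) abort("Pairs must involve two distinct genes.")
  missing <- setdiff(unique(c(irg1, irg2)), rownames(expr))
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  key <- paste(irg1, irg2, sep = "|")
  if (anyDuplicated(key)) abort("Duplicate pairs supplied.")
  v <- (expr[irg1, , drop = FALSE] > expr[irg2, , drop = FALSE]) + 0L
  storage.mode(v) <- "integer"
  rownames(v) <- key
  structure(v, irg1 = irg1, irg2 = irg2, class = c("pair_matrix", "matrix"))
}

#' Build all gene-pair indicators from an expression matrix
#'
#' Forms one pair per unordered combination of the supplied genes
#' (choose(n, 2) pairs), orientation fixed by lexicographic symbol order,
#' and evaluates the binary within-sample comparison: value 1 when the
#' first gene's expression strictly exceeds the second's, 0 otherwise.
#' Because only within-sample ranks matter, the result is invariant under
#' any strictly increasing per-sample transform of the expression values —
#' the property that makes the downstream risk score portable across
#' platforms and normalizations.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Character vector (>= 2) of gene symbols, all rows of `expr`.
#' @return A `pair_matrix` (see [pair_matrix()]) with choose(n, 2) rows.
#' @export
build_pairs <- function(expr, genes) {
  genes <- sort(unique(as.character(genes)), method = "radix")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(genes) < 2L) abort("Need at least two genes to form pairs.")
  idx <- utils::combn(length(genes), 2L)
  pair_matrix(expr, genes[idx[1L, ]], genes[idx[2L, ]])
}

#' Remove low-variation and imbalanced pairs
#'
#' Keeps pairs whose across-sample frequency of the value 1 lies inside
#' `[low, high]`; near-constant indicators in either direction carry little
#' prognostic contrast and destabilize downstream model fitting.
#' Idempotent; pair order is preserved.
#'
#' @param pm A `pair_matrix`.
#' @param low,high Frequency window bounds, `0 <= low < high <= 1`.
#'   Defaults 0.2 and 0.8.
#' @return The filtered `pair_matrix`.
#' @export
filter_pairs <- function(pm, low = 0.2, high = 0.8) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!(low >= 0 && low < high && high <= 1)) {
    abort("Require 0 <= low < high <= 1.")
  }
  f <- rowMeans(pm)
  keep <- f >= low & f <= high
  if (!any(keep)) abort("All pairs removed by the frequency filter.")
  subset_pairs(pm, keep)
}

# subset a pair_matrix keeping its pair attributes in sync
subset_pairs <- function(pm, keep) {
  v <- unclass(pm)[keep, , drop = FALSE]
  structure(v,
            irg1 = attr(pm, "irg1")[keep],
            irg2 = attr(pm, "irg2")[keep],
            class = c("pair_matrix", "matrix"))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d pairs x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Tidy a pair matrix into long form
#'
#' @param x A `pair_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `irg1`, `irg2`, `sample_id`, `value`.
#' @method tidy pair_matrix
#' @export
tidy.pair_matrix <- function(x, ...) {
  tibble::tibble(
    irg1 = rep(attr(x, "irg1"), times = ncol(x)),
    irg2 = rep(attr(x, "irg2"), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.integer(x)
  )
}

#' Write a pair matrix to TSV for audit
#'
#' @param pm A `pair_matrix`.
#' @param path Output path. Rows are `"IRG1|IRG2"`, cells are 0/1.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pm, path) {
  stopifnot(inherits(pm, "pair_matrix"))
  df <- data.frame(pair = rownames(pm), unclass(pm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
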