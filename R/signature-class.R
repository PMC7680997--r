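#' Construct a fitted gene-pair signature
#'
#' An `irgp_signature` is a tibble with one row per ordered gene pair
#' (columns `irg1`, `irg2`, `coefficient`) plus an optional risk-score
#' cutoff and free-form metadata stored as attributes. The pair orientation
#' is meaningful: the pair's binary value is 1 in a sample exactly when the
#' expression of `irg1` exceeds that of `irg2`.
#'
#' @param irg1,irg2 Character vectors of gene symbols; within a row the two
#'   symbols must differ, and the ordered (irg1, irg2) tuples must be unique.
#' @param coefficient Numeric vector of per-pair regression coefficients;
#'   finite and non-zero.
#' @param cutoff Optional single finite numeric risk-score threshold.
#' @param meta Optional named list of provenance metadata.
#'
#' @return A tibble of class `irgp_signature` with columns `irg1`, `irg2`,
#'   `coefficient` and attributes `cutoff` and `meta`.
#' @export
#' @examples
#' sig <- irgp_signature(c("A", "B"), c("C", "D"), c(0.5, -1.2), cutoff = 0.1)
#' signature_genes(sig)
irgp_signature <- function(irg1, irg2, coefficient, cutoff = NULL,
                           meta = list()) {
  irg1 <- as.character(irg1)
  irg2 <- as.character(irg2)
  coefficient <- as.numeric(coefficient)
  n <- length(irg1)
  if (length(irg2) != n || length(coefficient) != n) {
    abort("`irg1`, `irg2` and `coefficient` must have equal length.")
  }
  if (n == 0L) abort("A signature needs at least one pair.")
  if (any(irg1 == irg2)) abort("Each pair must involve two distinct genes.")
  if (anyDuplicated(paste(irg1, irg2, sep = "\r"))) {
    abort("Ordered pairs must be unique.")
  }
  if (any(!is.finite(coefficient)) || any(coefficient == 0)) {
    abort("Coefficients must be finite and non-zero.")
  }
  if (!is.null(cutoff)) {
    cutoff <- as.numeric(cutoff)
    if (length(cutoff) != 1L || !is.finite(cutoff)) {
      abort("`cutoff` must be a single finite number.")
    }
  }
  out <- tibble::tibble(irg1 = irg1, irg2 = irg2, coefficient = coefficient)
  attr(out, "cutoff") <- cutoff
  attr(out, "meta") <- meta
  class(out) <- c("irgp_signature", class(out))
  out
}

#' Genes used by a signature
#'
#' @param sig An [irgp_signature()].
#' @return Character vector of the distinct gene symbols, in order of first
#'   appearance.
#' @export
signature_genes <- function(sig) {
  stopifnot(inherits(sig, "irgp_signature"))
  unique(c(rbind(sig$irg1, sig$irg2)))
}

#' Risk cutoff stored on a signature
#'
#' @param sig An [irgp_signature()].
#' @return The cutoff, or `NULL` when none has been set.
#' @export
signature_cutoff <- function(sig) {
  stopifnot(inherits(sig, "irgp_signature"))
  attr(sig, "cutoff")
}

#' @export
print.irgp_signature <- function(x, ...) {
  cutoff <- attr(x, "cutoff")
  cat(sprintf(
    "<irgp_signature> %d pairs, %d genes, cutoff %s\n",
    nrow(x), length(signature_genes(x)),
    if (is.null(cutoff)) "unset" else format(cutoff)
  ))
  NextMethod()
}

#' @rdname irgp_signature
#' @param x An `irgp_signature`.
#' @param ... Unused.
#' @method tidy irgp_signature
#' @export
tidy.irgp_signature <- function(x, ...) {
  tibble::tibble(irg1 = x$irg1, irg2 = x$irg2, coefficient = x$coefficient)
}

#' @rdname irgp_signature
#' @method glance irgp_signature
#' @export
glance.irgp_signature <- function(x, ...) {
  cutoff <- attr(x, "cutoff")
  tibble::tibble(
    n_pairs = nrow(x),
    n_genes = length(signature_genes(x)),
    cutoff = if (is.null(cutoff)) NA_real_ else cutoff,
    min_score = sum(pmin(x$coefficient, 0)),
    max_score = sum(pmax(x$coefficient, 0))
  )
}
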