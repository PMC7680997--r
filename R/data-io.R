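#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text file whose first column holds gene symbols and
#' whose remaining columns hold one sample each (header row = sample ids).
#' Duplicate gene rows are collapsed by the per-sample maximum. For
#' RNA-seq-type input (`drop_zero_genes = TRUE`, the default) genes that are
#' zero in more than half of the samples are removed; set it to `FALSE` for
#' microarray intensities, where zeros are not a sparsity signal.
#'
#' @param path Path to a TSV/CSV file.
#' @param fmt `"auto"` (by extension, default tab), `"tsv"` or `"csv"`.
#' @param drop_zero_genes Apply the sparse-gene filter (see above)?
#' @return A numeric matrix (genes x samples) with unique rownames (gene
#'   symbols) and unique colnames (sample ids); all values finite and >= 0.
#' @export
read_expression <- function(path, fmt = c("auto", "tsv", "csv"),
                            drop_zero_genes = TRUE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sep <- switch(fmt,
    tsv = "\t",
    csv = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  )
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("Expression file needs a gene column plus at least one sample column.")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("Duplicate sample ids: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  genes <- trimws(as.character(df[[1L]]))
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("Non-numeric expression values in column(s): %s",
                  paste(sample_ids[bad], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyNA(m) || any(!is.finite(m))) abort("Expression values must be finite.")
  if (any(m < 0)) abort("Expression values must be non-negative.")

  if (anyDuplicated(genes)) {
    m <- collapse_duplicate_genes(m)
  }
  if (drop_zero_genes) {
    zero_frac <- rowMeans(m == 0)
    m <- m[zero_frac <= 0.5, , drop = FALSE]
  }
  if (nrow(m) == 0L) abort("No genes left after filtering.")
  m
}

# per-sample maximum over rows sharing a symbol
collapse_duplicate_genes <- function(m) {
  g <- factor(rownames(m), levels = unique(rownames(m)))
  out <- rowsum(m, g, reorder = FALSE)  # placeholder shape; refilled below
  for (lev in levels(g)[table(g) > 1L]) {
    rows <- which(rownames(m) == lev)
    out[lev, ] <- apply(m[rows, , drop = FALSE], 2L, max)
  }
  single <- levels(g)[table(g) == 1L]
  out[single, ] <- m[match(single, rownames(m)), , drop = FALSE]
  out
}

#' Read a clinical/survival table
#'
#' Requires columns `sample_id`, `time` and `event`; any further columns are
#' kept as clinical covariates. Rows with missing follow-up (`NA` time or
#' event) are dropped with a message; rows with non-positive time or an
#' event flag outside \{0, 1\} are dropped with a warning.
#'
#' @param path Path to a TSV/CSV file (delimiter by extension).
#' @param time_unit Unit of the `time` column: `"days"`, `"months"` or
#'   `"years"`. Stored as an attribute and used to convert year-based
#'   horizons downstream; times themselves are never converted.
#' @return A tibble with columns `sample_id` (character, unique), `time`
#'   (positive), `event` (0/1) and any covariates, with attribute
#'   `time_unit`.
#' @export
read_clinical <- function(path, time_unit = c("days", "months", "years")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "event")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols)) {
    abort(sprintf("Clinical table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  n0 <- nrow(df)
  incomplete <- is.na(df$time) | is.na(df$event)
  if (any(incomplete)) {
    inform(sprintf("Dropped %d sample(s) without complete follow-up.",
                   sum(incomplete)))
    df <- df[!incomplete, , drop = FALSE]
  }
  invalid <- df$time <= 0 | !(df$event %in% c(0, 1))
  if (any(invalid)) {
    warn(sprintf("Dropped %d sample(s) with non-positive time or event not in {0,1}.",
                 sum(invalid)))
    df <- df[!invalid, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort("No usable clinical rows.")
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample ids in clinical table.")
  out <- tibble::as_tibble(df)
  out <- dplyr::relocate(out, "sample_id", "time", "event")
  attr(out, "time_unit") <- time_unit
  out
}

#' Read a gene set (one symbol per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique, whitespace-trimmed symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("Gene set file is empty.")
  unique(lines)
}

#' Convert a year-based horizon to clinical-table time units
#'
#' @param years Horizon in years.
#' @param clinical A clinical tibble carrying a `time_unit` attribute
#'   (`"days"`, `"months"` or `"years"`; missing attribute means days).
#' @return The horizon in the table's units (365.25 days or 12 months per
#'   year).
#' @export
horizon_in_units <- function(years, clinical) {
  unit <- attr(clinical, "time_unit") %||% "days"
  years * switch(unit, days = 365.25, months = 12, years = 1,
                 abort(sprintf("Unknown time unit '%s'.", unit)))
}
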