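#' Simulation settings for a synthetic survival-expression cohort
#'
#' Bundles and validates the generative settings used by
#' [simulate_cohort()]. The generator emulates the statistical structure
#' the gene-pair pipeline assumes: log-scale expression with gene-specific
#' location and dispersion, a small set of planted gene pairs whose binary
#' within-sample indicators act multiplicatively on the hazard
#' (proportional hazards), independent exponential right-censoring
#' calibrated to a target rate, and optional per-sample monotone or batch
#' distortions for rank-invariance checks.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_genes Number of genes.
#' @param planted Tibble/data frame with columns `irg1`, `irg2`, `log_hr`:
#'   planted pairs and their log hazard ratios. Empty (default) plants
#'   nothing. Gene names are `g001`, `g002`, ... up to `n_genes`.
#' @param baseline_hazard Baseline exponential event rate per year.
#'   Default 0.2.
#' @param censoring_rate Target fraction of censored samples in `[0, 1)`.
#'   Default 0.3; 0 disables censoring.
#' @param location_mean,location_sd Mean and SD of the per-gene log2
#'   expression means. Defaults 5 and 1.5.
#' @param scale_range Range of the per-gene log2 SDs. Default c(0.5, 1.5).
#' @param distortion `"none"` (default), `"monotone"` or `"batch"`,
#'   applied to the expression matrix after survival generation so labels
#'   depend only on the undistorted ranks.
#' @param seed Integer seed (required).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_genes, planted = NULL,
                       baseline_hazard = 0.2, censoring_rate = 0.3,
                       location_mean = 5, location_sd = 1.5,
                       scale_range = c(0.5, 1.5),
                       distortion = c("none", "monotone", "batch"),
                       seed) {
  distortion <- match.arg(distortion)
  if (missing(seed)) abort("`seed` is required.")
  if (n_samples < 2L) abort("`n_samples` must be >= 2.")
  if (n_genes < 2L) abort("`n_genes` must be >= 2.")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must be in [0, 1).")
  }
  genes <- sim_gene_names(n_genes)
  if (is.null(planted)) {
    planted <- tibble::tibble(irg1 = character(), irg2 = character(),
                              log_hr = numeric())
  }
  planted <- tibble::as_tibble(planted)
  if (nrow(planted)) {
    stopifnot(all(c("irg1", "irg2", "log_hr") %in% colnames(planted)))
    bad <- setdiff(c(planted$irg1, planted$irg2), genes)
    if (length(bad)) {
      abort(sprintf("Planted gene(s) outside the simulated gene set: %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(planted$irg1 == planted$irg2)) abort("Planted pairs need distinct genes.")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         genes = genes, planted = planted,
         baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
         location_mean = location_mean, location_sd = location_sd,
         scale_range = scale_range, distortion = distortion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_gene_names <- function(n) sprintf("g%03d", seq_len(n))

#' Simulate a survival-expression cohort with planted pair effects
#'
#' Expression is drawn gene-wise log-normal (log2 values Normal with
#' gene-specific mean and SD); the two genes of each planted pair share
#' one location so their binary comparison is roughly balanced. Pair
#' indicators are evaluated with the strict-inequality rule, survival
#' times are exponential with hazard
#' `baseline_hazard * exp(sum_k log_hr_k * z_k)`, and independent
#' exponential censoring is calibrated by root-finding so the expected
#' censored fraction matches the target. A planted pair whose indicator
#' is constant across samples is resampled (fresh expression for its two
#' genes) up to 10 times, then an error is raised. Any distortion is
#' applied after survival generation.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort`: `expr` (genes x samples matrix),
#'   `clinical` (tibble `sample_id`, `time`, `event`, time unit years),
#'   `truth` (list: `planted` tibble, `indicators` matrix, `linear_predictor`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    genes <- cfg$genes
    sample_ids <- sprintf("s%04d", seq_len(n))

    mu <- rnorm(cfg$n_genes, cfg$location_mean, cfg$location_sd)
    sdv <- runif(cfg$n_genes, cfg$scale_range[1L], cfg$scale_range[2L])
    names(mu) <- names(sdv) <- genes
    # shared location within a planted pair keeps its indicator balanced
    if (nrow(cfg$planted)) {
      mu[cfg$planted$irg2] <- mu[cfg$planted$irg1]
    }
    log2x <- matrix(rnorm(cfg$n_genes * n, mean = mu, sd = sdv),
                    nrow = cfg$n_genes, ncol = n,
                    dimnames = list(genes, sample_ids))
    expr <- 2^log2x

    z <- NULL
    if (nrow(cfg$planted)) {
      for (try in seq_len(10L)) {
        z <- unclass(pair_matrix(expr, cfg$planted$irg1, cfg$planted$irg2))
        degenerate <- apply(z, 1L, function(v) length(unique(v)) < 2L)
        if (!any(degenerate)) break
        if (try == 10L) abort("Planted pair indicator degenerate after 10 resamples.")
        redraw <- unique(c(cfg$planted$irg1[degenerate],
                           cfg$planted$irg2[degenerate]))
        expr[redraw, ] <- 2^rnorm(length(redraw) * n, mean = mu[redraw],
                                  sd = sdv[redraw])
      }
      lp <- as.numeric(crossprod(z, cfg$planted$log_hr))
    } else {
      lp <- rep(0, n)
    }

    hazard <- cfg$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    if (cfg$censoring_rate > 0) {
      theta <- censoring_rate_root(hazard, cfg$censoring_rate)
      t_cens <- rexp(n, rate = theta)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    if (cfg$distortion != "none") {
      expr <- distort(expr, kind = cfg$distortion,
                      seed = cfg$seed + 1000000L)
    }

    clinical <- tibble::tibble(sample_id = sample_ids, time = time,
                               event = event)
    attr(clinical, "time_unit") <- "years"
    list_out <- list(
      expr = expr,
      clinical = clinical,
      truth = list(planted = cfg$planted, indicators = z,
                   linear_predictor = lp)
    )
    structure(list_out, class = "sim_cohort")
  })
}

# exponential censoring rate theta with E[censored fraction] = target:
# P(C < T_i) = theta / (theta + h_i), averaged over samples
censoring_rate_root <- function(hazard, target) {
  f <- function(log_theta) mean(exp(log_theta) / (exp(log_theta) + hazard)) - target
  r <- uniroot(f, interval = c(-30, 30), tol = 1e-10)
  exp(r$root)
}

#' Distort an expression matrix
#'
#' `"monotone"` applies an independent strictly increasing map to each
#' sample (`a * x^p + b` with `a, p > 0`, `b >= 0`), which preserves every
#' within-sample rank and therefore every gene-pair indicator. `"batch"`
#' adds a per-gene positive shift to a random half of the samples — a
#' cross-sample perturbation that can change within-sample orderings, the
#' negative control for the rank-invariance property. `"identity"`
#' returns the matrix unchanged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param kind `"monotone"`, `"batch"` or `"identity"`.
#' @param seed Integer seed.
#' @return The distorted matrix, same dimensions and dimnames.
#' @export
distort <- function(expr, kind = c("monotone", "batch", "identity"), seed) {
  kind <- match.arg(kind)
  if (kind == "identity") return(expr)
  with_seed(seed, {
    if (kind == "monotone") {
      a <- runif(ncol(expr), 0.5, 2)
      p <- runif(ncol(expr), 0.5, 2)
      b <- runif(ncol(expr), 0, 1)
      out <- sweep(sweep(expr, 2L, p, `^`), 2L, a, `*`)
      out <- sweep(out, 2L, b, `+`)
    } else {
      shift <- abs(rnorm(nrow(expr))) * apply(expr, 1L, median)
      half <- sample(ncol(expr), floor(ncol(expr) / 2))
      out <- expr
      out[, half] <- out[, half] + shift
    }
    out
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d genes x %d samples, %d planted pair(s), %.0f%% censored\n",
    nrow(x$expr), ncol(x$expr), nrow(x$truth$planted),
    100 * mean(x$clinical$event == 0)))
  invisible(x)
}
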