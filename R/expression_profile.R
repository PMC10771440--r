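#' Construct an expression profile
#'
#' An `expression_profile` holds one gene's expression values on an explicit
#' time grid (hours), together with a scale flag. Microarray time courses are
#' typically published on the log2 scale; the kinetic model operates on the
#' linear (original-read) scale, so the scale is tracked explicitly and
#' converted with [delog_expression()].
#'
#' @param gene_id Character scalar identifying the gene (or regulator).
#' @param times Numeric vector of time points in hours, strictly increasing.
#' @param values Numeric vector of expression values, same length as `times`.
#' @param scale Either `"log2"` or `"linear"`. Linear-scale values must be
#'   non-negative.
#' @return An object of class `expression_profile`.
#' @examples
#' p <- expression_profile("SCO3356", 0:5, c(1, 2, 4, 8, 4, 2), scale = "linear")
#' p
#' @export
expression_profile <- function(gene_id, times, values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.character(gene_id) || length(gene_id) != 1L)
    stop("`gene_id` must be a single character string")
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length")
  if (length(times) == 0L)
    stop("profile must contain at least one time point")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("`times` and `values` must be finite")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale values must be non-negative")
  structure(
    list(gene_id = gene_id, times = times, values = values, scale = scale),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf(
    "<expression_profile> %s: %d points, %.4g-%.4g h, %s scale\n",
    x$gene_id, length(x$times), min(x$times), max(x$times), x$scale
  ))
  invisible(x)
}

#' @rdname expression_profile
#' @param x Object to test.
#' @export
is_expression_profile <- function(x) inherits(x, "expression_profile")

stopifnot_profile <- function(p, arg = deparse(substitute(p))) {
  if (!is_expression_profile(p)) stop(sprintf("`%s` must be an expression_profile", arg))
  invisible(p)
}

stopifnot_shared_grid <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("profiles must share the same time grid")
  invisible(NULL)
}

#' The 32-point fermentor time grid
#'
#' Hour grid of the public single-replicate *S. coelicolor* fermentor
#' expression time course used throughout: hourly sampling from 20 to 44 h
#' (with 25 and 45 h absent) and 2-hourly sampling from 46 to 60 h, giving 32
#' time points without replicates.
#'
#' @return Numeric vector of 32 hours.
#' @export
fermentor_time_grid <- function() {
  c(20:24, 26:44, seq(46, 60, by = 2))
}

#' Exponentiate a log2 profile back to the linear scale
#'
#' Published microarray values on the log2 scale are exponentiated
#' (`v -> 2^v`) to recover original-read units before kinetic modeling.
#'
#' @param p An `expression_profile` with `scale == "log2"`.
#' @return The profile on the linear scale.
#' @export
delog_expression <- function(p) {
  stopifnot_profile(p)
  if (p$scale != "log2") stop("profile is already on the linear scale")
  expression_profile(p$gene_id, p$times, 2^p$values, scale = "linear")
}

#' Log2-transform a linear-scale profile
#'
#' Inverse of [delog_expression()]; values must be strictly positive.
#'
#' @param p An `expression_profile` with `scale == "linear"`.
#' @return The profile on the log2 scale.
#' @export
log_expression <- function(p) {
  stopifnot_profile(p)
  if (p$scale != "linear") stop("profile is already on the log2 scale")
  if (any(p$values <= 0)) stop("values must be strictly positive to take log2")
  expression_profile(p$gene_id, p$times, log2(p$values), scale = "log2")
}

#' Savitzky-Golay smoothing of an expression profile
#'
#' Single-replicate time courses are noisy; a Savitzky-Golay filter (local
#' least-squares polynomial) extracts the trend while reproducing polynomials
#' up to `polyorder` exactly.
#'
#' @param p An `expression_profile`.
#' @param window Odd filter window length in points (default 9).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Smoothed profile on the same grid and scale. Linear-scale output is
#'   clamped at zero (the filter can slightly undershoot near sharp features).
#' @export
smooth_profile <- function(p, window = 9L, polyorder = 3L) {
  stopifnot_profile(p)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("`window` must be odd")
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`")
  if (window > length(p$values)) stop("`window` exceeds the number of time points")
  sm <- as.numeric(signal::sgolayfilt(p$values, p = polyorder, n = window))
  if (p$scale == "linear") sm <- pmax(sm, 0)
  expression_profile(p$gene_id, p$times, sm, scale = p$scale)
}

#' Resample a profile onto a uniform grid
#'
#' Linear interpolation onto a uniform grid running from the first to the last
#' observed time at the stated interval (default 24 minutes, the resolution
#' used for the Euler integration). Endpoints are preserved; with a 20-60 h
#' span the default interval yields 101 grid points.
#'
#' @param p An `expression_profile` with at least two points.
#' @param interval_minutes Grid interval in minutes (> 0), default 24.
#' @return Profile on the uniform grid.
#' @export
resample_profile <- function(p, interval_minutes = 24) {
  stopifnot_profile(p)
  if (length(p$times) < 2L) stop("resampling needs at least two time points")
  if (!is.numeric(interval_minutes) || interval_minutes <= 0)
    stop("`interval_minutes` must be positive")
  dt <- interval_minutes / 60
  grid <- seq(p$times[1L], p$times[length(p$times)], by = dt)
  # include the final time even when the span is not a multiple of the interval
  if (grid[length(grid)] < p$times[length(p$times)] - 1e-9)
    grid <- c(grid, p$times[length(p$times)])
  vals <- stats::approx(p$times, p$values, xout = grid, rule = 2)$y
  expression_profile(p$gene_id, grid, vals, scale = p$scale)
}

#' Normalize a profile to zero mean and unit standard deviation
#'
#' Used for display and correlation; a profile whose variability is below
#' machine tolerance is mapped to all zeros rather than dividing by ~0.
#'
#' @param p An `expression_profile` with at least two points.
#' @return Normalized profile (scale flag preserved).
#' @export
normalize_profile <- function(p) {
  stopifnot_profile(p)
  if (length(p$values) < 2L) stop("normalization needs at least two points")
  s <- stats::sd(p$values)
  v <- if (!is.finite(s) || s < 1e-12 * max(1, abs(mean(p$values)))) {
    rep(0, length(p$values))
  } else {
    (p$values - mean(p$values)) / s
  }
  out <- p
  out$values <- v
  # normalized values can be negative even for a linear-scale input
  out$scale <- "linear"
  class(out) <- "expression_profile"
  out
}

#' Within-profile variability (coefficient of variation)
#'
#' Standard deviation of the mean-scaled profile. Flat profiles — the group
#' that cannot be attributed to any regulator — have low values on this
#' statistic; it is the quantity thresholded by [assign_group()].
#'
#' @param p A linear-scale `expression_profile` with positive mean.
#' @return Non-negative scalar; 0 for a constant profile. The population
#'   (divide-by-n) standard deviation is used so the two-point profile
#'   `(1, 3)` gives exactly 0.5.
#' @export
profile_variability <- function(p) {
  stopifnot_profile(p)
  if (p$scale != "linear") stop("variability is defined on linear-scale profiles")
  m <- mean(p$values)
  if (m <= 0) stop("profile mean must be positive")
  n <- length(p$values)
  sd_pop <- sqrt(sum((p$values - m)^2) / n)
  sd_pop / m
}

#' Pearson correlation between a target and a regulator profile
#'
#' @param target,regulator `expression_profile`s on a shared time grid.
#' @return Pearson correlation in `[-1, 1]`; 0 (with a warning) when either
#'   profile is constant.
#' @export
correlate_with_regulator <- function(target, regulator) {
  stopifnot_profile(target)
  stopifnot_profile(regulator)
  stopifnot_shared_grid(target, regulator)
  if (stats::sd(target$values) < 1e-12 || stats::sd(regulator$values) < 1e-12) {
    warning("constant profile: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(target$values, regulator$values)
}

#' Assign a profile to a regulator group
#'
#' Reproduces the three-way partition of chromatin-immunoprecipitation-derived
#' target genes: (A) profiles correlated with the alternative sigma factor,
#' (B) profiles correlated with the housekeeping sigma factor HrdB, (C) flat
#' profiles with low within-profile variability. Profiles matching neither
#' regulator but clearly expressed fall into `"other"`.
#'
#' @param target Target gene profile (linear scale, preprocessed).
#' @param sigE,hrdB Regulator profiles on the same grid.
#' @param r_threshold Minimum Pearson correlation to call a profile
#'   regulator-correlated (default 0.7).
#' @param flat_threshold Coefficient-of-variation threshold below which a
#'   profile is called flat (default 0.1).
#' @return A one-row data frame with columns `gene_id`, `group`
#'   (`A_sigE`/`B_hrdB`/`C_flat`/`other`), `r_sigE`, `r_hrdB`, `variability`.
#' @export
assign_group <- function(target, sigE, hrdB, r_threshold = 0.7, flat_threshold = 0.1) {
  stopifnot_profile(target)
  if (!is.numeric(r_threshold) || r_threshold < -1 || r_threshold > 1)
    stop("`r_threshold` must be in [-1, 1]")
  if (!is.numeric(flat_threshold) || flat_threshold < 0)
    stop("`flat_threshold` must be non-negative")
  cv <- profile_variability(target)
  if (cv < flat_threshold) {
    r_se <- r_hb <- 0
    grp <- "C_flat"
  } else {
    r_se <- suppressWarnings(correlate_with_regulator(target, sigE))
    r_hb <- suppressWarnings(correlate_with_regulator(target, hrdB))
    grp <- if (r_se >= r_threshold && r_se >= r_hb) "A_sigE"
           else if (r_hb >= r_threshold) "B_hrdB"
           else "other"
  }
  data.frame(
    gene_id = target$gene_id, group = grp,
    r_sigE = r_se, r_hrdB = r_hb, variability = cv,
    stringsAsFactors = FALSE
  )
}

#' Preprocess a published log2 profile for kinetic modeling
#'
#' Convenience wrapper applying the canonical order: exponentiate from log2,
#' Savitzky-Golay smooth, resample to a uniform grid.
#'
#' @param p An `expression_profile` (log2 scale; a linear-scale input skips
#'   the exponentiation step).
#' @inheritParams smooth_profile
#' @inheritParams resample_profile
#' @return Linear-scale profile on the uniform grid.
#' @export
preprocess_profile <- function(p, window = 9L, polyorder = 3L, interval_minutes = 24) {
  stopifnot_profile(p)
  if (p$scale == "log2") p <- delog_expression(p)
  resample_profile(smooth_profile(p, window, polyorder), interval_minutes)
}

#' Classify a cohort of profiles against two regulators
#'
#' Applies [preprocess_profile()] to every target and both regulators, then
#' [assign_group()] per target.
#'
#' @param targets Named list of `expression_profile`s.
#' @param sigE,hrdB Regulator profiles on the targets' observation grid.
#' @inheritParams assign_group
#' @inheritParams preprocess_profile
#' @return Data frame with one row per target.
#' @export
classify_cohort <- function(targets, sigE, hrdB,
                            r_threshold = 0.7, flat_threshold = 0.1,
                            window = 9L, polyorder = 3L, interval_minutes = 24) {
  sigE_p <- preprocess_profile(sigE, window, polyorder, interval_minutes)
  hrdB_p <- preprocess_profile(hrdB, window, polyorder, interval_minutes)
  rows <- lapply(targets, function(p) {
    assign_group(preprocess_profile(p, window, polyorder, interval_minutes),
                 sigE_p, hrdB_p, r_threshold, flat_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
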