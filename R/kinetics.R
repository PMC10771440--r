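#' Kinetic model parameters
#'
#' Parameters of the regulator-driven expression model
#' \deqn{dz/dt = k_1\,\sigma(b + \sum_i w_i y_i(t)) - k_2 z,\qquad
#'       \sigma(x) = 1/(1+e^{-x})}
#' where `z` is target expression, `y_i` the regulator profiles, `k1` the
#' maximal synthesis rate (expression units/hour), `k2` the first-order mRNA
#' degradation rate (1/hour), `b` a regulation bias, and `w` the signed
#' regulatory weights — `w > 0` means the regulator stimulates the target,
#' `w < 0` that it represses it.
#'
#' @param k1,k2 Non-negative synthesis and degradation rates.
#' @param b Regulation bias (dimensionless).
#' @param w Numeric vector of regulatory weights, one per regulator.
#' @param z0 Non-negative initial target expression.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k2, b, w, z0) {
  if (!is.numeric(k1) || k1 < 0) stop("`k1` must be non-negative")
  if (!is.numeric(k2) || k2 < 0) stop("`k2` must be non-negative")
  if (!is.numeric(b) || length(b) != 1L) stop("`b` must be a numeric scalar")
  if (!is.numeric(w) || length(w) < 1L) stop("`w` must be a non-empty numeric vector")
  if (!is.numeric(z0) || z0 < 0) stop("`z0` must be non-negative")
  structure(list(k1 = k1, k2 = k2, b = b, w = as.numeric(w), z0 = z0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> k1=%.4g k2=%.4g b=%.4g w=(%s) z0=%.4g\n",
              x$k1, x$k2, x$b, paste(signif(x$w, 4), collapse = ", "), x$z0))
  invisible(x)
}

# Regulator values interpolated onto the fine integration grid.
regulators_on_grid <- function(regulators, fine_times) {
  vapply(regulators, function(r) {
    stats::approx(r$times, r$values, xout = fine_times, rule = 2)$y
  }, numeric(length(fine_times)))
}

#' Integrate the kinetic model by forward Euler
#'
#' Solves the regulator-driven expression ODE with a simple forward-Euler
#' scheme at step `dt`, linearly interpolating regulator profiles between
#' their grid points, and returns the solution sampled on the regulators'
#' observation grid.
#'
#' @param params A [kinetic_params()] object.
#' @param regulators List of linear-scale `expression_profile`s on a common
#'   time grid (may be empty only if `length(params$w) == 0`; normally one
#'   profile per weight).
#' @param dt Euler step in hours; must not exceed the smallest observation
#'   gap. For stability/positivity keep `dt < 1/k2`.
#' @return Linear-scale `expression_profile` of the simulated target on the
#'   observation grid.
#' @export
integrate_model <- function(params, regulators, dt) {
  if (!inherits(params, "kinetic_params")) stop("`params` must be kinetic_params")
  if (length(regulators) != length(params$w))
    stop("need one regulator profile per weight in `w`")
  for (r in regulators) stopifnot_profile(r)
  for (r in regulators[-1]) stopifnot_shared_grid(regulators[[1]], r)
  obs_times <- regulators[[1]]$times
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  if (length(obs_times) >= 2 && dt > min(diff(obs_times)) + 1e-9)
    stop("`dt` must not exceed the smallest observation gap")
  span <- range(obs_times)
  fine <- seq(span[1], span[2], by = dt)
  if (fine[length(fine)] < span[2] - 1e-9) fine <- c(fine, span[2])
  reg_fine <- regulators_on_grid(regulators, fine)
  z <- euler_kinetic_cpp(params$k1, params$k2, params$b, params$w, params$z0,
                         reg_fine, dt)
  z_obs <- stats::approx(fine, z, xout = obs_times, rule = 2)$y
  expression_profile("simulated", obs_times, pmax(z_obs, 0), scale = "linear")
}

#' Sum of squared errors between two profiles
#'
#' @param trajectory,observed `expression_profile`s on a shared grid.
#' @return Non-negative scalar \eqn{\sum_t (z_t - x_t)^2}.
#' @export
sse <- function(trajectory, observed) {
  stopifnot_profile(trajectory)
  stopifnot_profile(observed)
  stopifnot_shared_grid(trajectory, observed)
  sum((trajectory$values - observed$values)^2)
}

#' Simulated annealing over a box
#'
#' Reference annealer: Gaussian proposals clipped to the box, Metropolis
#' acceptance, geometric cooling, best-seen bookkeeping. The kinetic fit uses
#' a compiled implementation of this exact algorithm (same random-draw order),
#' so the two can be cross-checked draw for draw.
#'
#' Draw order under a given seed: when `t0` is `NULL`, 24 uniform vectors to
#' calibrate the initial temperature; then `runif(npar)` for the start point;
#' then per iteration `rnorm(npar)` for the proposal and `runif(1)` for the
#' acceptance test.
#'
#' @param objective Function mapping a parameter vector to a finite scalar.
#' @param lower,upper Finite numeric bounds (equal length, `lower <= upper`).
#' @param seed Integer seed; the run is deterministic given it.
#' @param n_iter Number of annealing iterations (default 500).
#' @param t0 Initial temperature; `NULL` calibrates it to the spread of the
#'   objective over random points in the box.
#' @param cooling Geometric cooling factor per iteration (default 0.97).
#' @param prop_scale Proposal standard deviation as a fraction of each
#'   parameter's box width (default 0.1).
#' @return List with `par` (best-seen point), `value` (its objective) and
#'   `best_trace` (best-seen objective after each iteration, non-increasing).
#' @export
anneal <- function(objective, lower, upper, seed, n_iter = 500L,
                   t0 = NULL, cooling = 0.97, prop_scale = 0.1) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  npar <- length(lower)
  if (npar == 0L || length(upper) != npar) stop("`lower`/`upper` must be non-empty and equal length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("bounds must be finite with lower <= upper")
  set.seed(as.integer(seed))
  width <- upper - lower
  if (is.null(t0)) {
    probe <- replicate(24, objective(lower + stats::runif(npar) * width))
    t0 <- max(stats::sd(probe), 1e-8)
  }
  prop_sd <- prop_scale * width
  cur <- lower + stats::runif(npar) * width
  f_cur <- objective(cur)
  best <- cur; f_best <- f_cur
  trace <- numeric(n_iter)
  temp <- t0
  for (it in seq_len(n_iter)) {
    prop <- pmin(pmax(cur + stats::rnorm(npar) * prop_sd, lower), upper)
    f_prop <- objective(prop)
    u <- stats::runif(1)
    if (f_prop <= f_cur || u < exp(-(f_prop - f_cur) / temp)) {
      cur <- prop; f_cur <- f_prop
      if (f_cur < f_best) { best <- cur; f_best <- f_cur }
    }
    trace[it] <- f_best
    temp <- temp * cooling
  }
  list(par = best, value = f_best, best_trace = trace)
}

#' Default plausibility bounds for the kinetic fit
#'
#' Box constraints keeping fitted models biologically plausible: synthesis
#' capped at ten times the observed maximum, degradation between 0.1 and
#' 5 per hour, and bias/weights within +/-10 (the sigmoid saturates well
#' before those magnitudes).
#'
#' @param obs_max Maximum of the observed target profile.
#' @param n_regulators Number of regulators (length of `w`).
#' @return List with numeric `lower` and `upper` over `(k1, k2, b, w...)`.
#' @export
default_kinetic_bounds <- function(obs_max, n_regulators) {
  list(
    lower = c(k1 = 1e-6, k2 = 0.1, b = -10, rep(-10, n_regulators)),
    upper = c(k1 = 10 * max(obs_max, 1e-6), k2 = 5, b = 10, rep(10, n_regulators))
  )
}

derive_seed_num <- function(h, x) ((h * 69069) %% 2147483629 + x) %% 2147483629

#' Derive a stream-specific seed from a master seed
#'
#' Counter-style derivation: each (stream label, index) pair maps to a fixed
#' 31-bit seed, so adding entities to a simulation never perturbs the random
#' numbers of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param stream Character label of the random stream.
#' @param index Non-negative integer counter within the stream.
#' @return Integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(master_seed, stream, index = 0L) {
  h <- as.numeric(master_seed) %% 2147483629
  for (ch in utf8ToInt(stream)) h <- derive_seed_num(h, ch)
  h <- derive_seed_num(h, as.numeric(index) %% 2147483629)
  as.integer(h %% 2147483628) + 1L
}

# Shared driver behind the single-/dual-regulator fits: multi-restart
# annealing of (k1, k2, b, w...) with z0 pinned to the first observation.
fit_kinetic_model <- function(target, regulators, n_restarts = 256L,
                              master_seed = 1L, bounds = NULL,
                              fit_threshold = 0.2, n_iter = 500L,
                              cooling = 0.97, prop_scale = 0.1) {
  stopifnot_profile(target)
  for (r in regulators) {
    stopifnot_profile(r)
    stopifnot_shared_grid(target, r)
    if (r$scale != "linear") stop("regulator profiles must be linear scale")
  }
  if (target$scale != "linear") stop("target profile must be linear scale")
  n_restarts <- as.integer(n_restarts)
  if (is.na(n_restarts) || n_restarts < 1L) stop("`n_restarts` must be >= 1")
  gaps <- diff(target$times)
  if (max(gaps) - min(gaps) > 1e-6)
    stop("fitting expects a uniform time grid; resample the profiles first")
  dt <- gaps[1]
  obs <- target$values
  z0 <- obs[1]
  nr <- length(regulators)
  if (nr < 1L) stop("at least one regulator profile is required")
  if (is.null(bounds)) bounds <- default_kinetic_bounds(max(obs), nr)
  lower <- as.numeric(bounds$lower); upper <- as.numeric(bounds$upper)
  if (length(lower) != 3 + nr || length(upper) != 3 + nr)
    stop("bounds must cover (k1, k2, b) plus one weight per regulator")
  if (any(lower > upper)) stop("empty bound box: lower > upper")
  reg_fine <- vapply(regulators, function(r) r$values, numeric(length(obs)))
  obs_idx <- seq_along(obs)
  width <- upper - lower
  prop_sd <- prop_scale * width

  # temperature calibrated once per gene to the objective spread over the box
  set.seed(derive_seed(master_seed, "t0"))
  probe <- replicate(24, {
    p <- lower + stats::runif(length(lower)) * width
    sum((euler_kinetic_cpp(p[1], p[2], p[3], p[4:(3 + nr)], z0, reg_fine, dt) - obs)^2)
  })
  t0 <- max(stats::sd(probe), 1e-8)

  best <- NULL
  for (i in seq_len(n_restarts)) {
    set.seed(derive_seed(master_seed, "restart", i))
    res <- sa_fit_kinetic_cpp(reg_fine, obs, obs_idx, dt, z0, lower, upper,
                              as.integer(n_iter), t0, cooling, prop_sd)
    if (is.null(best) || res$sse < best$sse) { best <- res; best$restart <- i }
  }

  par <- best$par
  params <- kinetic_params(par[1], par[2], par[3], par[4:(3 + nr)], z0)
  traj_vals <- euler_kinetic_cpp(params$k1, params$k2, params$b, params$w, z0,
                                 reg_fine, dt)
  trajectory <- expression_profile(paste0(target$gene_id, "_fit"), target$times,
                                   pmax(traj_vals, 0), scale = "linear")
  fit_sse <- sum((traj_vals - obs)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  normalized_sse <- if (ss_tot > 0) fit_sse / ss_tot else if (fit_sse == 0) 0 else Inf
  structure(list(
    gene_id = target$gene_id,
    params = params,
    sse = fit_sse,
    normalized_sse = normalized_sse,
    trajectory = trajectory,
    verdict = if (normalized_sse < fit_threshold) "regulation_possible" else "regulation_disproved",
    fit_threshold = fit_threshold,
    n_restarts = n_restarts,
    best_restart = best$restart,
    master_seed = master_seed
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: sse=%.4g (normalized %.4g), %s, w=(%s)\n",
              x$gene_id, x$sse, x$normalized_sse, x$verdict,
              paste(signif(x$params$w, 4), collapse = ", ")))
  invisible(x)
}

#' Fit the kinetic model with a single regulator
#'
#' Multi-restart simulated-annealing fit of `(k1, k2, b, w)` (initial value
#' `z0` pinned to the first observation). Each restart draws a fresh random
#' start inside the plausibility box; the minimum-SSE model over all restarts
#' is returned. Regulation is called `"regulation_possible"` when the
#' normalized SSE (SSE over the target's total sum of squares) falls below
#' `fit_threshold`, and `"regulation_disproved"` otherwise. The sign of the
#' fitted weight `w` distinguishes stimulation (`w > 0`) from repression
#' (`w < 0`).
#'
#' @param target Preprocessed linear-scale target profile on a uniform grid.
#' @param regulator Regulator profile on the same grid.
#' @param n_restarts Number of annealing restarts (default 256).
#' @param master_seed Integer seed; restart seeds are derived from it.
#' @param bounds Optional list `lower`/`upper` over `(k1, k2, b, w)`;
#'   defaults via [default_kinetic_bounds()].
#' @param fit_threshold Normalized-SSE threshold for the verdict (default 0.2).
#' @param n_iter,cooling,prop_scale Annealing schedule, see [anneal()].
#' @return A `kinetic_fit` object.
#' @export
fit_single_regulator <- function(target, regulator, n_restarts = 256L,
                                 master_seed = 1L, bounds = NULL,
                                 fit_threshold = 0.2, n_iter = 500L,
                                 cooling = 0.97, prop_scale = 0.1) {
  fit_kinetic_model(target, list(regulator), n_restarts, master_seed, bounds,
                    fit_threshold, n_iter, cooling, prop_scale)
}

#' Fit the kinetic model with an activator and a repressor
#'
#' Two-regulator variant of [fit_single_regulator()] with `w` of length 2
#' (activator first). With `constrain_signs = TRUE` the weight boxes are
#' restricted to `w_activator >= 0` and `w_repressor <= 0`, the combined
#' model used when a housekeeping activator and a candidate repressor act on
#' the same promoter.
#'
#' @param target,activator,repressor Linear-scale profiles on a shared
#'   uniform grid.
#' @param constrain_signs Enforce `w1 >= 0`, `w2 <= 0` (default `FALSE`).
#' @inheritParams fit_single_regulator
#' @return A `kinetic_fit` with a length-2 weight vector.
#' @export
fit_dual_regulator <- function(target, activator, repressor,
                               constrain_signs = FALSE, n_restarts = 256L,
                               master_seed = 1L, bounds = NULL,
                               fit_threshold = 0.2, n_iter = 500L,
                               cooling = 0.97, prop_scale = 0.1) {
  if (is.null(bounds)) {
    bounds <- default_kinetic_bounds(max(target$values), 2L)
    if (constrain_signs) {
      bounds$lower[4] <- 0    # activator weight
      bounds$upper[5] <- 0    # repressor weight
    }
  }
  if (any(bounds$lower > bounds$upper)) stop("empty constraint box")
  fit_kinetic_model(target, list(activator, repressor), n_restarts,
                    master_seed, bounds, fit_threshold, n_iter, cooling,
                    prop_scale)
}

#' Screen candidate activators against a fixed repressor
#'
#' Fits one dual-regulator model per candidate activator (sign-constrained:
#' candidate stimulating, fixed regulator repressing) and ranks the fits by
#' SSE, ascending. Ties keep the candidates' input order.
#'
#' @param target Target profile.
#' @param candidate_activators Named list of candidate activator profiles.
#' @param fixed_repressor Repressor profile shared by all models.
#' @inheritParams fit_single_regulator
#' @return List with `fits` (ranked list of `kinetic_fit`s) and `ranking`
#'   (data frame: candidate, sse, normalized_sse, w_activator, w_repressor,
#'   verdict).
#' @export
screen_regulators <- function(target, candidate_activators, fixed_repressor,
                              n_restarts = 256L, master_seed = 1L,
                              fit_threshold = 0.2, n_iter = 500L,
                              cooling = 0.97, prop_scale = 0.1) {
  if (length(candidate_activators) == 0L) stop("no candidate activators given")
  nms <- names(candidate_activators)
  if (is.null(nms))
    nms <- vapply(candidate_activators, function(p) p$gene_id, character(1))
  fits <- lapply(seq_along(candidate_activators), function(i) {
    fit_dual_regulator(target, candidate_activators[[i]], fixed_repressor,
                       constrain_signs = TRUE, n_restarts = n_restarts,
                       master_seed = derive_seed(master_seed, "screen", i),
                       fit_threshold = fit_threshold, n_iter = n_iter,
                       cooling = cooling, prop_scale = prop_scale)
  })
  sses <- vapply(fits, function(f) f$sse, numeric(1))
  ord <- order(sses)  # stable: ties keep input order
  ranking <- data.frame(
    candidate = nms[ord],
    sse = sses[ord],
    normalized_sse = vapply(fits[ord], function(f) f$normalized_sse, numeric(1)),
    w_activator = vapply(fits[ord], function(f) f$params$w[1], numeric(1)),
    w_repressor = vapply(fits[ord], function(f) f$params$w[2], numeric(1)),
    verdict = vapply(fits[ord], function(f) f$verdict, character(1)),
    stringsAsFactors = FALSE
  )
  list(fits = fits[ord], ranking = ranking)
}
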