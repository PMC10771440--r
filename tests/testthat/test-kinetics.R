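make_pulse <- function(times = fermentor_time_grid()) {
  expression_profile("reg", times, 0.5 + 3 * exp(-(times - 38)^2 / 40), "linear")
}

test_that("Euler integration matches the pure-decay closed form", {
  times <- seq(0, 5, by = 0.5)
  reg <- expression_profile("r", times, rep(1, length(times)), "linear")
  par <- kinetic_params(0, 1, 0, 0.5, 4)  # k1 = 0: pure exponential decay
  z <- integrate_model(par, list(reg), dt = 0.001)
  expect_equal(z$values, 4 * exp(-times), tolerance = 2e-3)
  expect_error(integrate_model(par, list(reg), dt = 1), "observation gap")
})

test_that("zero-weight model converges to k1/(2 k2)", {
  times <- seq(0, 30, by = 0.5)
  reg <- expression_profile("r", times, runif(length(times)), "linear")
  par <- kinetic_params(2, 1, 0, 0, 5)
  z <- integrate_model(par, list(reg), dt = 0.05)
  expect_equal(z$values[length(times)], 1.0, tolerance = 1e-3)
})

test_that("Euler error halves with the step against a Runge-Kutta oracle", {
  library(deSolve)
  reg <- make_pulse()
  set.seed(11)
  for (i in 1:3) {
    k1 <- runif(1, 1, 4); k2 <- runif(1, 0.5, 2)
    w <- runif(1, -4, 4); b <- runif(1, -2, 2); z0 <- runif(1, 0.5, 3)
    fn <- function(t, z, p) {
      y <- approx(reg$times, reg$values, t, rule = 2)$y
      list(k1 * plogis(b + w * y) - k2 * z)
    }
    ref <- deSolve::ode(z0, reg$times, fn, NULL, method = "ode45")[, 2]
    par <- kinetic_params(k1, k2, b, w, z0)
    err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
      max(abs(integrate_model(par, list(reg), dt)$values - ref))
    }, numeric(1))
    ratios <- err[-3] / err[-1]
    expect_true(all(ratios > 1.6 & ratios < 2.5))
  }
})

test_that("sse is the symmetric squared-difference sum on a shared grid", {
  a <- linear_profile(c(1, 2, 3, 4, 5))
  b <- linear_profile(c(2, 3, 4, 5, 6))
  expect_equal(sse(a, a), 0)
  expect_equal(sse(a, b), 5)
  expect_equal(sse(a, b), sse(b, a))
  expect_error(sse(a, linear_profile(1:4)), "grid")
})

test_that("annealing finds a 1-D quadratic minimum and keeps its books", {
  obj <- function(x) (x - 0)^2
  res <- anneal(obj, -10, 10, seed = 3, n_iter = 1500)
  expect_lt(abs(res$par), 1e-2)
  res2 <- anneal(obj, -10, 10, seed = 3, n_iter = 1500)
  expect_identical(res$par, res2$par)
  expect_true(all(diff(res$best_trace) <= 0))
  expect_error(anneal(obj, numeric(0), numeric(0), seed = 1), "non-empty")
})

test_that("R and compiled annealers agree draw for draw on the kinetic objective", {
  reg <- make_pulse()
  cfg <- simulation_config(master_seed = 7, noise_sd_log2 = 0.1)
  par <- kinetic_params(3, 1, -2, 4, 1)
  obs <- preprocess_profile(simulate_target_expression(list(reg), par, cfg, seed = 5))
  reg_p <- resample_profile(smooth_profile(reg))
  reg_fine <- matrix(reg_p$values, ncol = 1)
  obsv <- obs$values
  dt <- diff(obs$times)[1]
  lower <- c(1e-6, 0.1, -10, -10)
  upper <- c(10 * max(obsv), 5, 10, 10)
  obj <- function(p) {
    sum((sigrekin:::euler_kinetic_cpp(p[1], p[2], p[3], p[4], obsv[1],
                                      reg_fine, dt) - obsv)^2)
  }
  ra <- anneal(obj, lower, upper, seed = 99, n_iter = 300, t0 = 5)
  set.seed(99)
  ca <- sigrekin:::sa_fit_kinetic_cpp(reg_fine, obsv, seq_along(obsv), dt,
                                      obsv[1], lower, upper, 300L, 5, 0.97,
                                      0.1 * (upper - lower))
  expect_identical(ra$par, as.numeric(ca$par))
  expect_identical(ra$value, ca$sse)
})

test_that("noise-free model targets are refit with the correct weight sign", {
  reg <- make_pulse()
  reg_u <- resample_profile(reg)
  mid <- mean(range(reg$values))
  for (w_true in c(5, -5)) {
    par <- kinetic_params(3, 1, -w_true * mid, w_true,
                          3 * plogis(-w_true * mid + w_true * reg$values[1]))
    target <- resample_profile(integrate_model(par, list(reg), dt = 0.05))
    target$gene_id <- "t"
    fit <- fit_single_regulator(target, reg_u, n_restarts = 64, master_seed = 2)
    expect_equal(sign(fit$params$w[1]), sign(w_true))
    expect_lt(fit$normalized_sse, 0.01)
    expect_equal(fit$verdict, "regulation_possible")
  }
})

test_that("stored sse equals the recomputed trajectory error", {
  reg <- make_pulse()
  cfg <- simulation_config(master_seed = 9, noise_sd_log2 = 0.2)
  par <- kinetic_params(2, 1, -4, 3, 1)
  tgt <- preprocess_profile(simulate_target_expression(list(reg), par, cfg, 3))
  fit <- fit_single_regulator(tgt, resample_profile(smooth_profile(reg)),
                              n_restarts = 16, master_seed = 4)
  expect_equal(fit$sse, sse(fit$trajectory, tgt), tolerance = 1e-9)
})

test_that("best SSE is non-increasing in the number of restarts", {
  reg <- make_pulse()
  cfg <- simulation_config(master_seed = 13, noise_sd_log2 = 0.2)
  par <- kinetic_params(2, 1, -4, 3, 1)
  tgt <- preprocess_profile(simulate_target_expression(list(reg), par, cfg, 8))
  reg_p <- resample_profile(smooth_profile(reg))
  sses <- vapply(c(4L, 8L, 16L, 32L), function(n) {
    fit_single_regulator(tgt, reg_p, n_restarts = n, master_seed = 21)$sse
  }, numeric(1))
  expect_true(all(diff(sses) <= 0))
})

test_that("white-noise targets are overwhelmingly disproved", {
  cfg <- simulation_config(master_seed = 3, noise_sd_log2 = 0.2)
  reg <- simulate_regulator_profile(cfg, "pulse", 11)
  reg_p <- resample_profile(smooth_profile(reg))
  disproved <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    vals <- 2^(2 + rnorm(32, 0, 1))
    tgt <- expression_profile(paste0("wn", s), fermentor_time_grid(), vals,
                              "linear")
    fit <- fit_single_regulator(preprocess_profile(tgt), reg_p,
                                n_restarts = 64, master_seed = s)
    disproved <- disproved + (fit$verdict == "regulation_disproved")
  }
  expect_gte(disproved / 20, 0.9)
})

test_that("dual fit with a pinned zero weight matches the single fit", {
  reg <- make_pulse()
  cfg <- simulation_config(master_seed = 17, noise_sd_log2 = 0.1)
  par <- kinetic_params(2, 1, -4, 3, 1)
  tgt <- preprocess_profile(simulate_target_expression(list(reg), par, cfg, 5))
  reg_p <- resample_profile(smooth_profile(reg))
  single <- fit_single_regulator(tgt, reg_p, n_restarts = 64, master_seed = 6)
  bounds <- default_kinetic_bounds(max(tgt$values), 2L)
  bounds$lower[5] <- 0; bounds$upper[5] <- 0  # second regulator pinned off
  dual <- fit_dual_regulator(tgt, reg_p, reg_p, bounds = bounds,
                             n_restarts = 64, master_seed = 6)
  expect_lt(abs(dual$sse - single$sse) / single$sse, 0.2)
  expect_error(
    fit_dual_regulator(tgt, reg_p, reg_p,
                       bounds = list(lower = c(1, 1, 1, 1, 1),
                                     upper = c(0, 0, 0, 0, 0))),
    "empty"
  )
})

test_that("dual fits are deterministic under a fixed master seed", {
  cfg <- simulation_config(master_seed = 19, noise_sd_log2 = 0.1)
  act <- simulate_regulator_profile(cfg, "ramp", 4)
  rep_ <- simulate_regulator_profile(cfg, "pulse", 5)
  par <- kinetic_params(3, 1, -8, c(4, -4), 0.5)
  tgt <- preprocess_profile(simulate_target_expression(list(act, rep_), par, cfg, 6))
  ap <- resample_profile(smooth_profile(act))
  rp <- resample_profile(smooth_profile(rep_))
  f1 <- fit_dual_regulator(tgt, ap, rp, n_restarts = 32, master_seed = 77)
  f2 <- fit_dual_regulator(tgt, ap, rp, n_restarts = 32, master_seed = 77)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
})

test_that("regulator screening ranks the true activator first", {
  cfg <- simulation_config(master_seed = 23, noise_sd_log2 = 0)
  t <- cfg$time_grid
  true_act <- expression_profile("act", t, 0.5 + 3 / (1 + exp(-(t - 30) / 2)),
                                 "linear")
  repressor <- expression_profile("rep", t,
                                  0.5 + 3 * exp(-(t - 46)^2 / 32), "linear")
  set.seed(31)
  decoys <- lapply(1:4, function(i) {
    simulate_regulator_profile(cfg, "biphasic", 100 + i,
                               gene_id = paste0("decoy", i))
  })
  par <- kinetic_params(3, 1, -3.5 * max(true_act$values) + 1, c(3.5, -4),
                        0.5)
  tgt <- preprocess_profile(
    simulate_target_expression(list(true_act, repressor), par, cfg, 9))
  cands <- c(list(act = resample_profile(smooth_profile(true_act))),
             setNames(lapply(decoys, function(d)
               resample_profile(smooth_profile(d))),
               paste0("decoy", 1:4)))
  rp <- resample_profile(smooth_profile(repressor))
  scr <- screen_regulators(tgt, cands, rp, n_restarts = 64, master_seed = 3)
  expect_equal(scr$ranking$candidate[1], "act")
  expect_true(all(diff(scr$ranking$sse) >= 0))
  # stable under candidate reordering
  scr2 <- screen_regulators(tgt, rev(cands), rp, n_restarts = 64,
                            master_seed = 3)
  expect_equal(scr2$ranking$candidate[1], "act")
  expect_error(screen_regulators(tgt, list(), rp), "no candidate")
})

test_that("derived seeds are stable, bounded and counter-independent", {
  s1 <- derive_seed(1, "fit", 5)
  expect_identical(s1, derive_seed(1, "fit", 5))
  expect_true(s1 >= 1 && s1 < 2^31)
  expect_false(s1 == derive_seed(1, "fit", 6))
  expect_false(s1 == derive_seed(2, "fit", 5))
  expect_false(derive_seed(1, "a", 0) == derive_seed(1, "b", 0))
})
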