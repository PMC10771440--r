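test_that("profile construction enforces its invariants", {
  expect_error(expression_profile("g", c(1, 2), c(1, 2, 3)), "same length")
  expect_error(expression_profile("g", c(2, 1), c(1, 2)), "strictly increasing")
  expect_error(expression_profile("g", c(1, 2), c(-1, 2), scale = "linear"),
               "non-negative")
  p <- log2_profile(c(-1, 0, 1))
  expect_s3_class(p, "expression_profile")
})

test_that("delog exponentiates from log2 and round-trips", {
  p <- log2_profile(c(3, 0, -1))
  d <- delog_expression(p)
  expect_equal(d$values, c(8, 1, 0.5))
  expect_equal(d$scale, "linear")
  expect_equal(log_expression(d)$values, p$values, tolerance = 1e-15)
  expect_error(delog_expression(d), "already")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and denoises", {
  t <- 1:21
  const <- linear_profile(rep(5, 21), t)
  expect_equal(smooth_profile(const)$values, rep(5, 21))
  quad <- linear_profile(0.5 * t^2 - 3 * t + 50, t)
  expect_equal(smooth_profile(quad, window = 9, polyorder = 3)$values,
               quad$values, tolerance = 1e-9)
  # seeded noisy sine: smoothing reduces deviation from the clean signal
  set.seed(4)
  clean <- sin(seq(0, 2 * pi, length.out = 41)) + 2
  noisy <- clean + rnorm(41, 0, 0.2)
  sm <- smooth_profile(linear_profile(noisy, 1:41), 9, 3)$values
  expect_lt(sum((sm - clean)^2), sum((noisy - clean)^2))
  expect_error(smooth_profile(const, window = 8), "odd")
  expect_error(smooth_profile(const, window = 9, polyorder = 9), "smaller")
  expect_error(smooth_profile(linear_profile(1:5), window = 9), "exceeds")
})

test_that("resampling the 20-60 h grid at 24 min gives 101 points", {
  p <- log2_profile(rnorm(32, 8), fermentor_time_grid())
  r <- resample_profile(p, 24)
  expect_length(r$times, 101)
  expect_equal(r$times[1], 20)
  expect_equal(r$times[101], 60)
  # input already on the target grid is unchanged
  u <- linear_profile(runif(11), seq(0, 4, by = 0.4))
  expect_equal(resample_profile(u, 24)$values, u$values)
  # linear-in-time signals interpolate exactly
  lin <- linear_profile(2 * fermentor_time_grid() + 1, fermentor_time_grid())
  r2 <- resample_profile(lin, 24)
  expect_equal(r2$values, 2 * r2$times + 1, tolerance = 1e-12)
  expect_error(resample_profile(p, 0), "positive")
})

test_that("normalization gives zero mean unit sd, degenerate to zeros", {
  p <- linear_profile(c(1, 5, 2, 8, 3))
  n <- normalize_profile(p)
  expect_equal(mean(n$values), 0, tolerance = 1e-12)
  expect_equal(sd(n$values), 1, tolerance = 1e-12)
  expect_equal(normalize_profile(linear_profile(rep(4, 6)))$values, rep(0, 6))
  # affine invariance for positive scalings
  p2 <- linear_profile(3 * c(1, 5, 2, 8, 3) + 7)
  expect_equal(normalize_profile(p2)$values, n$values, tolerance = 1e-12)
})

test_that("variability is the coefficient of variation and scale-free", {
  expect_equal(profile_variability(linear_profile(rep(3, 8))), 0)
  expect_equal(profile_variability(linear_profile(c(1, 3))), 0.5)
  p <- linear_profile(c(2, 4, 3, 6, 5))
  expect_equal(profile_variability(p),
               profile_variability(linear_profile(10 * p$values)))
  expect_error(profile_variability(linear_profile(rep(0, 4))), "positive")
  expect_error(profile_variability(log2_profile(1:4)), "linear")
})

test_that("correlation handles identical, negated, orthogonal and flat input", {
  v <- c(1, 4, 2, 6, 3, 8)
  p <- linear_profile(v)
  expect_equal(correlate_with_regulator(p, p), 1)
  neg <- p; neg$values <- max(v) + 1 - v
  expect_equal(correlate_with_regulator(linear_profile(neg$values), p), -1)
  # explicit orthogonalization: residuals of a regression on the profile
  set.seed(8)
  y <- rnorm(6)
  res <- residuals(lm(y ~ v))
  orth <- expression_profile("o", 1:6, res, scale = "log2")
  expect_equal(correlate_with_regulator(orth, p), 0, tolerance = 1e-12)
  expect_warning(r <- correlate_with_regulator(linear_profile(rep(2, 6)), p),
                 "constant")
  expect_equal(r, 0)
  expect_error(correlate_with_regulator(p, linear_profile(1:5)), "grid")
})

test_that("group assignment reproduces the three-way partition", {
  t <- fermentor_time_grid()
  sigE <- linear_profile(1 + 3 * exp(-(t - 38)^2 / 50), t, "sigE")
  hrdB <- linear_profile(1 + 3 / (1 + exp(-(t - 40) / 3)), t, "hrdB")
  set.seed(6)
  near_sigE <- linear_profile(sigE$values * exp(rnorm(32, 0, 0.05)), t, "a")
  expect_equal(assign_group(near_sigE, sigE, hrdB)$group, "A_sigE")
  flat <- linear_profile(rep(5, 32), t, "c")
  expect_equal(assign_group(flat, sigE, hrdB)$group, "C_flat")
  expect_equal(assign_group(hrdB, sigE, hrdB, r_threshold = 0.5)$group, "B_hrdB")
  expect_error(assign_group(flat, sigE, hrdB, r_threshold = 2), "r_threshold")
  # totality: every profile gets exactly one of the four labels
  for (s in 1:10) {
    set.seed(s)
    p <- linear_profile(2^(rnorm(32, 3, s %% 3)), t)
    g <- assign_group(p, sigE, hrdB)$group
    expect_true(g %in% c("A_sigE", "B_hrdB", "C_flat", "other"))
  }
})

test_that("repeated smoothing never increases variability", {
  for (s in 1:8) {
    set.seed(s)
    p <- linear_profile(2^(rnorm(32, 3, 0.5)), fermentor_time_grid())
    once <- smooth_profile(p)
    twice <- smooth_profile(once)
    expect_lte(profile_variability(twice), profile_variability(once) + 1e-12)
  }
})

test_that("cohort classification recovers known drivers at noise 0.3", {
  cfg <- simulation_config(master_seed = 5, noise_sd_log2 = 0.3)
  coh <- simulate_expression_cohort(cfg, 9, 3, 8, 6)
  cl <- classify_cohort(coh$targets, coh$sigE, coh$hrdB)
  expect_equal(cl$gene_id, coh$truth$gene_id)
  acc <- mean(cl$group == coh$truth$expected_group)
  expect_gte(acc, 0.9)
})
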