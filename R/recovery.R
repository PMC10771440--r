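#' Single-regulator parameter-recovery battery
#'
#' Simulation study validating that the multi-restart annealing fit recovers
#' the sign of the regulatory weight. Targets are generated from the kinetic
#' model driven by a pulsed regulator, with parameters drawn per gene
#' (`k1 ~ U(1,6)`, `k2 ~ U(0.5,2)`, `|w| ~ U(2,6)` with random sign, bias
#' centred so the sigmoid spans its responsive range, start at steady
#' state), observed through the full preprocessing chain (log2 + noise,
#' exponentiation, smoothing, resampling) and refitted.
#'
#' @param n_genes Number of synthetic genes (default 50).
#' @param noise_sd_log2 Log2-scale noise standard deviation.
#' @param n_restarts Annealing restarts per fit (default 256).
#' @param master_seed Integer seed controlling every draw.
#' @return List with `sign_recovery` (fraction of genes whose fitted `w` has
#'   the true sign), `results` (per-gene data frame: true and fitted
#'   parameters, normalized SSE, verdict) and `n_genes`.
#' @export
recovery_battery_single <- function(n_genes = 50L, noise_sd_log2 = 0.1,
                                    n_restarts = 256L, master_seed = 1L) {
  cfg <- simulation_config(master_seed = master_seed,
                           noise_sd_log2 = noise_sd_log2)
  reg <- simulate_regulator_profile(cfg, "pulse",
                                    derive_seed(master_seed, "battery_reg"))
  reg_p <- resample_profile(smooth_profile(reg))
  mid <- mean(range(reg$values))
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    set.seed(derive_seed(master_seed, "battery_params", i))
    k1 <- stats::runif(1, 1, 6)
    k2 <- stats::runif(1, 0.5, 2)
    w <- stats::runif(1, 2, 6) * sample(c(-1, 1), 1)
    b <- -w * mid + stats::runif(1, -0.5, 0.5)
    z0 <- k1 * stats::plogis(b + w * reg$values[1]) / k2
    par <- kinetic_params(k1, k2, b, w, z0)
    tgt <- simulate_target_expression(list(reg), par, cfg,
                                      derive_seed(master_seed, "battery_noise", i),
                                      gene_id = sprintf("R%04d", i))
    fit <- fit_single_regulator(preprocess_profile(tgt), reg_p,
                                n_restarts = n_restarts,
                                master_seed = derive_seed(master_seed, "battery_fit", i))
    rows[[i]] <- data.frame(
      gene_id = sprintf("R%04d", i), w_true = w, w_fit = fit$params$w[1],
      k1_true = k1, k1_fit = fit$params$k1, k2_true = k2,
      k2_fit = fit$params$k2, normalized_sse = fit$normalized_sse,
      verdict = fit$verdict, sign_ok = sign(fit$params$w[1]) == sign(w),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, rows)
  list(sign_recovery = mean(results$sign_ok), results = results,
       n_genes = n_genes)
}

#' Dual-regulator (activator + repressor) recovery battery
#'
#' Emulates the combined-regulation scenario — a housekeeping activator that
#' has reached its plateau plus a stress sigma factor pulsing afterwards as a
#' repressor, carving a visible dip into the target profile. The activator is
#' a logistic ramp rising around 30 h; the repressor a Gaussian pulse centred
#' at 46 h. Weights are `w_act ~ U(2,6)`, `w_rep ~ -U(2,6)`; the bias places
#' the post-ramp operating point just above the sigmoid midpoint so the
#' repressor pulse sweeps the responsive range downward. Fits are
#' unconstrained in sign; recovery means `w_act > 0` and `w_rep < 0`.
#'
#' @inheritParams recovery_battery_single
#' @return List with `sign_recovery`, `results` and `n_genes`.
#' @export
recovery_battery_dual <- function(n_genes = 50L, noise_sd_log2 = 0.1,
                                  n_restarts = 256L, master_seed = 1L) {
  cfg <- simulation_config(master_seed = master_seed,
                           noise_sd_log2 = noise_sd_log2)
  t <- cfg$time_grid
  activator <- expression_profile("activator", t,
                                  0.5 + 3 / (1 + exp(-(t - 30) / 2)), "linear")
  repressor <- expression_profile("repressor", t,
                                  0.5 + 3 * exp(-(t - 46)^2 / (2 * 4^2)), "linear")
  act_p <- resample_profile(smooth_profile(activator))
  rep_p <- resample_profile(smooth_profile(repressor))
  act_high <- max(activator$values)
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    set.seed(derive_seed(master_seed, "dual_params", i))
    k1 <- stats::runif(1, 1, 6)
    k2 <- stats::runif(1, 0.5, 2)
    w1 <- stats::runif(1, 2, 6)
    w2 <- -stats::runif(1, 2, 6)
    b <- -w1 * act_high + stats::runif(1, 0.5, 1.5)
    z0 <- k1 * stats::plogis(b + w1 * activator$values[1] +
                             w2 * repressor$values[1]) / k2
    par <- kinetic_params(k1, k2, b, c(w1, w2), z0)
    tgt <- simulate_target_expression(list(activator, repressor), par, cfg,
                                      derive_seed(master_seed, "dual_noise", i),
                                      gene_id = sprintf("D%04d", i))
    fit <- fit_dual_regulator(preprocess_profile(tgt), act_p, rep_p,
                              n_restarts = n_restarts,
                              master_seed = derive_seed(master_seed, "dual_fit", i))
    rows[[i]] <- data.frame(
      gene_id = sprintf("D%04d", i), w1_true = w1, w1_fit = fit$params$w[1],
      w2_true = w2, w2_fit = fit$params$w[2],
      normalized_sse = fit$normalized_sse, verdict = fit$verdict,
      sign_ok = fit$params$w[1] > 0 && fit$params$w[2] < 0,
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, rows)
  list(sign_recovery = mean(results$sign_ok), results = results,
       n_genes = n_genes)
}
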