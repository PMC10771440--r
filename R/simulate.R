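#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the observation time
#' grid, the log2-scale noise level, and the promoter-sequence regime
#' (GC content, sequence count/length, spacer-length distribution, fraction
#' of sequences receiving a planted site). Defaults emulate the study
#' conditions: the 32-point fermentor hour grid, single-replicate microarray
#' noise, GC-rich (72%) promoter windows of 100 bp, and the observed
#' 16/17/18/19 bp spacer usage (9/11/59/21%).
#'
#' @param master_seed Integer master seed; per-entity seeds are derived from
#'   it with [derive_seed()].
#' @param time_grid Strictly increasing observation times in hours.
#' @param noise_sd_log2 Standard deviation of additive Gaussian noise on the
#'   log2 scale (multiplicative log-normal on reads); default 0.2.
#' @param gc_content Background GC fraction in (0, 1); default 0.72.
#' @param n_sequences,seq_length Promoter set size and per-sequence length.
#' @param spacer_distribution Named probabilities over spacer lengths
#'   `16:19`, summing to 1.
#' @param planting_rate Fraction of sequences receiving one planted site
#'   (zero-or-one occurrence per sequence); default 0.9.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(master_seed = 1L,
                              time_grid = fermentor_time_grid(),
                              noise_sd_log2 = 0.2,
                              gc_content = 0.72,
                              n_sequences = 200L,
                              seq_length = 100L,
                              spacer_distribution = c(`16` = 0.09, `17` = 0.11,
                                                      `18` = 0.59, `19` = 0.21),
                              planting_rate = 0.9) {
  if (length(time_grid) < 1L || any(diff(time_grid) <= 0))
    stop("`time_grid` must be non-empty and strictly increasing")
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0)
    stop("`noise_sd_log2` must be non-negative")
  if (!is.numeric(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("`gc_content` must be in (0, 1)")
  if (n_sequences < 1L) stop("`n_sequences` must be positive")
  if (seq_length < 1L) stop("`seq_length` must be positive")
  sd_names <- names(spacer_distribution)
  if (is.null(sd_names) || !setequal(sd_names, as.character(16:19)))
    stop("`spacer_distribution` must be named with spacers 16..19")
  if (any(spacer_distribution < 0) || any(spacer_distribution > 1))
    stop("spacer probabilities must lie in [0, 1]")
  if (abs(sum(spacer_distribution) - 1) > 1e-9)
    stop("spacer probabilities must sum to 1")
  if (!is.numeric(planting_rate) || planting_rate < 0 || planting_rate > 1)
    stop("`planting_rate` must be in [0, 1]")
  structure(list(
    master_seed = as.integer(master_seed),
    time_grid = as.numeric(time_grid),
    noise_sd_log2 = noise_sd_log2,
    gc_content = gc_content,
    n_sequences = as.integer(n_sequences),
    seq_length = as.integer(seq_length),
    spacer_distribution = spacer_distribution[as.character(16:19)],
    planting_rate = planting_rate
  ), class = "simulation_config")
}

#' Simulate a regulator expression profile
#'
#' Smooth, strictly positive linear-scale stand-ins for measured sigma-factor
#' profiles: a `pulse` (transient induction peaking strictly inside the time
#' span), a `ramp` (monotone rise, the typical growth-associated housekeeping
#' pattern), or a `biphasic` double pulse. Amplitudes, centres and widths are
#' jittered per seed.
#'
#' @param config A [simulation_config()].
#' @param shape One of `"pulse"`, `"ramp"`, `"biphasic"`.
#' @param seed Integer seed; the profile is a pure function of
#'   `(config, shape, seed)`.
#' @param gene_id Identifier for the profile (default the shape name).
#' @return Linear-scale `expression_profile` on the config time grid.
#' @export
simulate_regulator_profile <- function(config, shape = c("pulse", "ramp", "biphasic"),
                                       seed, gene_id = NULL) {
  shape <- match.arg(shape)
  t <- config$time_grid
  span <- max(t) - min(t)
  if (span <= 0 && shape != "ramp") span <- 1
  set.seed(as.integer(seed))
  baseline <- stats::runif(1, 0.3, 0.7)
  amp <- stats::runif(1, 2, 4)
  vals <- switch(shape,
    pulse = {
      centre <- min(t) + stats::runif(1, 0.3, 0.7) * span
      width <- stats::runif(1, 0.10, 0.18) * span
      baseline + amp * exp(-(t - centre)^2 / (2 * width^2))
    },
    ramp = {
      mid <- min(t) + stats::runif(1, 0.35, 0.65) * span
      tau <- stats::runif(1, 0.08, 0.15) * span
      baseline + amp / (1 + exp(-(t - mid) / tau))
    },
    biphasic = {
      c1 <- min(t) + stats::runif(1, 0.2, 0.3) * span
      c2 <- min(t) + stats::runif(1, 0.65, 0.8) * span
      width <- stats::runif(1, 0.06, 0.10) * span
      baseline + amp * (exp(-(t - c1)^2 / (2 * width^2)) +
                        stats::runif(1, 0.6, 1) * exp(-(t - c2)^2 / (2 * width^2)))
    }
  )
  expression_profile(gene_id %||% shape, t, vals, scale = "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a target gene's observed (log2) expression
#'
#' Forward model of the kinetic ODE: integrates the model driven by the given
#' regulators, samples the trajectory on the config time grid, and corrupts
#' it with additive Gaussian noise on the log2 scale. With
#' `noise_sd_log2 = 0` the de-logged output reproduces the deterministic
#' integrator exactly.
#'
#' @param regulators List of linear-scale regulator profiles on the config
#'   time grid.
#' @param params [kinetic_params()] including the initial value `z0`.
#' @param config A [simulation_config()] (supplies grid and noise level).
#' @param seed Integer seed for the noise draw.
#' @param gene_id Identifier for the simulated gene.
#' @param dt Euler step in hours for the fine-grained forward integration
#'   (default 0.1).
#' @return Log2-scale `expression_profile` with an attribute
#'   `"ground_truth"`: a list of the true parameters and the noiseless
#'   linear trajectory.
#' @export
simulate_target_expression <- function(regulators, params, config, seed,
                                       gene_id = "target", dt = 0.1) {
  for (r in regulators) {
    stopifnot_profile(r)
    if (length(r$times) != length(config$time_grid) ||
        max(abs(r$times - config$time_grid)) > 1e-9)
      stop("regulators must be on the config time grid")
  }
  traj <- integrate_model(params, regulators, dt)
  z <- pmax(traj$values, 1e-12)
  set.seed(as.integer(seed))
  noisy_log2 <- log2(z) + stats::rnorm(length(z), 0, config$noise_sd_log2)
  out <- expression_profile(gene_id, config$time_grid, noisy_log2, scale = "log2")
  attr(out, "ground_truth") <- list(params = params, noiseless = traj)
  out
}

#' Simulate a cohort of target genes driven by two regulators
#'
#' Generates the expression side of a full synthetic study: a pulsed
#' alternative sigma factor (sigE-like), a ramping housekeeping factor
#' (HrdB-like), and four gene classes with known ground truth —
#' sigE-stimulated, sigE-repressed, HrdB-driven, and flat. Driven genes draw
#' kinetic parameters per derived seed (`k1 ~ U(1,6)`, `k2 ~ U(0.5,2)`,
#' `|w| ~ U(2,6)`, bias centred so the sigmoid spans its dynamic range) and
#' start at their steady state. Flat genes are constants observed with a
#' quarter of the cohort noise, emulating the low within-profile variability
#' of the flat cluster.
#'
#' @param config A [simulation_config()].
#' @param n_activated,n_repressed Numbers of sigE-stimulated (`w > 0`) and
#'   sigE-repressed (`w < 0`) genes.
#' @param n_hrdb Number of HrdB-driven genes.
#' @param n_flat Number of flat genes.
#' @return List with `sigE`, `hrdB` (linear-scale regulator profiles),
#'   `targets` (named list of log2 profiles) and `truth` (data frame:
#'   gene_id, role, expected_group, k1, k2, b, w). The `expected_group`
#'   column gives the label the correlation classifier should produce;
#'   repressed genes anti-correlate with sigE and are expected in `other`
#'   (their repression is recovered by the kinetic fit's negative weight).
#' @export
simulate_expression_cohort <- function(config, n_activated = 9L, n_repressed = 3L,
                                       n_hrdb = 8L, n_flat = 6L) {
  ms <- config$master_seed
  sigE <- simulate_regulator_profile(config, "pulse",
                                     derive_seed(ms, "regulator", 1L), "sigE")
  hrdB <- simulate_regulator_profile(config, "ramp",
                                     derive_seed(ms, "regulator", 2L), "hrdB")
  roles <- c(rep("activated", n_activated), rep("repressed", n_repressed),
             rep("hrdb", n_hrdb), rep("flat", n_flat))
  expected <- c(activated = "A_sigE", repressed = "other",
                hrdb = "B_hrdB", flat = "C_flat")
  targets <- list()
  truth <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    role <- roles[i]
    gid <- sprintf("G%04d", i)
    par_seed <- derive_seed(ms, "gene_params", i)
    noise_seed <- derive_seed(ms, "gene_noise", i)
    if (role == "flat") {
      set.seed(par_seed)
      level <- stats::runif(1, 1, 8)
      set.seed(noise_seed)
      vals <- log2(level) + stats::rnorm(length(config$time_grid),
                                         0, 0.25 * config$noise_sd_log2)
      targets[[gid]] <- expression_profile(gid, config$time_grid, vals, "log2")
      truth[[i]] <- data.frame(gene_id = gid, role = role,
                               expected_group = expected[[role]],
                               k1 = NA_real_, k2 = NA_real_, b = NA_real_,
                               w = NA_real_, stringsAsFactors = FALSE)
    } else {
      reg <- if (role == "hrdb") hrdB else sigE
      set.seed(par_seed)
      k1 <- stats::runif(1, 1, 6)
      k2 <- stats::runif(1, 0.5, 2)
      w_mag <- stats::runif(1, 2, 6)
      w <- if (role == "repressed") -w_mag else w_mag
      mid <- (max(reg$values) + min(reg$values)) / 2
      b <- -w * mid + stats::runif(1, -0.5, 0.5)
      z0 <- k1 * stats::plogis(b + w * reg$values[1]) / k2
      par <- kinetic_params(k1, k2, b, w, z0)
      targets[[gid]] <- simulate_target_expression(list(reg), par, config,
                                                   noise_seed, gid)
      truth[[i]] <- data.frame(gene_id = gid, role = role,
                               expected_group = expected[[role]],
                               k1 = k1, k2 = k2, b = b, w = w,
                               stringsAsFactors = FALSE)
    }
  }
  list(sigE = sigE, hrdB = hrdB, targets = targets,
       truth = do.call(rbind, truth))
}

#' Generate a promoter sequence set with planted bipartite sites
#'
#' Background sequences are drawn i.i.d. at the configured GC content
#' (complement-symmetric: A=T, C=G). A fraction `planting_rate` of them
#' receive exactly one composite -35/spacer/-10 site at a uniform random
#' position and strand, with the spacer length drawn from the configured
#' distribution. Site bases are sampled from the PWM columns
#' (`site_model = "pwm"`) or set to the consensus (`"consensus"`).
#'
#' @param config A [simulation_config()].
#' @param motif_family List with elements `pwm35` and `pwm10` (see
#'   [sige_motif_family()]).
#' @param seed Integer seed.
#' @param site_model `"pwm"` (default) or `"consensus"`.
#' @return List with `sequences` (named character vector) and `ground_truth`
#'   (data frame: seq_id, planted, position (0-based start of the site on
#'   the forward strand), strand, spacer).
#' @export
generate_promoter_set <- function(config, motif_family = sige_motif_family(),
                                  seed = config$master_seed,
                                  site_model = c("pwm", "consensus")) {
  site_model <- match.arg(site_model)
  pwm35 <- motif_family$pwm35
  pwm10 <- motif_family$pwm10
  max_width <- pwm_width(pwm35) + 19L + pwm_width(pwm10)
  if (config$seq_length < max_width)
    stop(sprintf("`seq_length` must be at least %d for the longest spacer", max_width))
  bases <- c("A", "C", "G", "T")
  bg <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
          G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  set.seed(as.integer(seed))
  seqs <- character(config$n_sequences)
  gt <- vector("list", config$n_sequences)
  spacers <- as.integer(names(config$spacer_distribution))
  for (i in seq_len(config$n_sequences)) {
    s <- sample(bases, config$seq_length, replace = TRUE, prob = bg)
    plant <- stats::runif(1) < config$planting_rate
    if (plant) {
      spacer <- sample(spacers, 1, prob = config$spacer_distribution)
      site35 <- emit_site(pwm35, site_model)
      site10 <- emit_site(pwm10, site_model)
      gap <- sample(bases, spacer, replace = TRUE, prob = bg)
      site <- c(site35, gap, site10)
      w <- length(site)
      pos0 <- sample.int(config$seq_length - w + 1L, 1) - 1L
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      if (strand == "-") site <- rev(chartr("ACGT", "TGCA", site))
      s[(pos0 + 1L):(pos0 + w)] <- site
      gt[[i]] <- data.frame(seq_id = sprintf("seq%04d", i), planted = TRUE,
                            position = pos0, strand = strand, spacer = spacer,
                            stringsAsFactors = FALSE)
    } else {
      gt[[i]] <- data.frame(seq_id = sprintf("seq%04d", i), planted = FALSE,
                            position = NA_integer_, strand = NA_character_,
                            spacer = NA_integer_, stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("seq%04d", seq_len(config$n_sequences))
  list(sequences = seqs, ground_truth = do.call(rbind, gt))
}

# Sample one site realization (character vector) from a PWM.
emit_site <- function(pwm, site_model) {
  bases <- c("A", "C", "G", "T")
  if (site_model == "consensus") {
    bases[apply(pwm$probs, 1, which.max)]
  } else {
    apply(pwm$probs, 1, function(p) sample(bases, 1, prob = p))
  }
}

#' Generate a gene-to-functional-class annotation table
#'
#' Each gene receives exactly one class label, drawn from the given class
#' fractions; any remaining probability mass goes to `"unclassified"`.
#'
#' @param n_genes Number of genes (IDs `gene0001`...).
#' @param class_fractions Named non-negative fractions summing to at most 1.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `class`.
#' @export
generate_annotation_table <- function(n_genes, class_fractions, seed) {
  if (any(class_fractions < 0)) stop("class fractions must be non-negative")
  if (sum(class_fractions) > 1 + 1e-9) stop("class fractions must sum to at most 1")
  if (is.null(names(class_fractions)) || any(names(class_fractions) == ""))
    stop("class fractions must be named")
  n_genes <- as.integer(n_genes)
  if (n_genes == 0L)
    return(data.frame(gene_id = character(), class = character(),
                      stringsAsFactors = FALSE))
  probs <- c(class_fractions, unclassified = max(0, 1 - sum(class_fractions)))
  set.seed(as.integer(seed))
  cls <- sample(names(probs), n_genes, replace = TRUE, prob = probs)
  data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)), class = cls,
             stringsAsFactors = FALSE)
}
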