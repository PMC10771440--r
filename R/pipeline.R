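#' Pipeline configuration
#'
#' Validated bundle of every stage parameter of the end-to-end analysis. In
#' `"synthetic"` mode all inputs are generated with known ground truth; in
#' `"user_data"` mode they are read from the given paths.
#'
#' @param mode `"synthetic"` or `"user_data"`.
#' @param master_seed Master seed fanned out to per-stage seeds via
#'   [derive_seed()].
#' @param simulation A [simulation_config()] (synthetic mode).
#' @param n_activated,n_repressed,n_hrdb,n_flat Cohort composition
#'   (synthetic mode).
#' @param r_threshold,flat_threshold Classification thresholds, see
#'   [assign_group()].
#' @param n_restarts Annealing restarts per kinetic fit (default 256).
#' @param fit_threshold Normalized-SSE threshold for the regulation verdict.
#' @param p_threshold Motif-scan p-value threshold (default 0.05).
#' @param spacer_range Spacer lengths for the composite motif (default
#'   `16:19`).
#' @param motif_width10,motif_width35 Half-site widths for motif discovery.
#' @param focal_class,focal_fraction Annotation class emulating the
#'   membrane-protein (periplasmic/exported/lipoprotein) group and its
#'   genome-wide incidence (default 16.8%).
#' @param paths Named list of input paths (user_data mode): `expression_tsv`,
#'   `sigE_gene`, `hrdB_gene`, `peaks_narrowpeak`, `genome_fasta`,
#'   `annotation_tsv`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "user_data"),
                            master_seed = 1L,
                            simulation = simulation_config(master_seed = master_seed),
                            n_activated = 9L, n_repressed = 3L,
                            n_hrdb = 8L, n_flat = 6L,
                            r_threshold = 0.7, flat_threshold = 0.1,
                            n_restarts = 256L, fit_threshold = 0.2,
                            p_threshold = 0.05, spacer_range = 16:19,
                            motif_width10 = 7L, motif_width35 = 7L,
                            focal_class = "membrane", focal_fraction = 0.168,
                            paths = list()) {
  mode <- match.arg(mode)
  if (mode == "user_data") {
    needed <- c("expression_tsv", "sigE_gene", "hrdB_gene")
    missing <- setdiff(needed, names(paths))
    if (length(missing) > 0)
      stop("user_data mode needs paths: ", paste(missing, collapse = ", "))
  }
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1")
  if (p_threshold <= 0 || p_threshold > 1) stop("`p_threshold` must be in (0, 1]")
  structure(list(
    mode = mode, master_seed = as.integer(master_seed), simulation = simulation,
    n_activated = n_activated, n_repressed = n_repressed, n_hrdb = n_hrdb,
    n_flat = n_flat, r_threshold = r_threshold, flat_threshold = flat_threshold,
    n_restarts = as.integer(n_restarts), fit_threshold = fit_threshold,
    p_threshold = p_threshold, spacer_range = spacer_range,
    motif_width10 = as.integer(motif_width10),
    motif_width35 = as.integer(motif_width35),
    focal_class = focal_class, focal_fraction = focal_fraction,
    paths = paths
  ), class = "pipeline_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$simulation <- unclass(out$simulation)
  out$simulation$spacer_distribution <- as.list(out$simulation$spacer_distribution)
  out$spacer_range <- as.integer(out$spacer_range)
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  simulation <- simulation_config(
    master_seed = sim$master_seed, time_grid = unlist(sim$time_grid),
    noise_sd_log2 = sim$noise_sd_log2, gc_content = sim$gc_content,
    n_sequences = sim$n_sequences, seq_length = sim$seq_length,
    spacer_distribution = unlist(sim$spacer_distribution),
    planting_rate = sim$planting_rate
  )
  pipeline_config(
    mode = raw$mode, master_seed = raw$master_seed, simulation = simulation,
    n_activated = raw$n_activated, n_repressed = raw$n_repressed,
    n_hrdb = raw$n_hrdb, n_flat = raw$n_flat,
    r_threshold = raw$r_threshold, flat_threshold = raw$flat_threshold,
    n_restarts = raw$n_restarts, fit_threshold = raw$fit_threshold,
    p_threshold = raw$p_threshold, spacer_range = unlist(raw$spacer_range),
    motif_width10 = raw$motif_width10, motif_width35 = raw$motif_width35,
    focal_class = raw$focal_class, focal_fraction = raw$focal_fraction,
    paths = raw$paths %||% list()
  )
}

#' Derive bipartite promoter motifs from peak-window sequences
#'
#' The two-stage discovery used for sigma-factor promoters: (1) find the
#' best ungapped motif in the windows with the zero-or-one-per-sequence EM
#' and call it the -10 element; (2) extract fixed-length segments a fixed
#' distance upstream of each -10 site and run the EM again for the -35
#' element; (3) join the two half-sites across each allowed spacer length
#' into composite motifs.
#'
#' @param seqs Named character vector of (peak-window) sequences.
#' @param width10,width35 Half-site widths (defaults 7).
#' @param offset Upstream distance from the -10 site start at which the
#'   -35 segment begins; the default `width35 + max(spacer_range)` makes the
#'   segment cover the full -35 element for every allowed spacer.
#' @param seg_length Length of the upstream segment searched for the -35
#'   element (default 10).
#' @param spacer_range Spacer lengths for the composites (default `16:19`).
#' @param seed Integer seed for the EM restarts.
#' @details An ungapped motif discovered on both strands is strand-ambiguous:
#' the EM may return the reverse complement of the biological -10. The
#' orientation is resolved by attempting the -35 discovery upstream of both
#' orientations and keeping the one with the higher per-segment likelihood —
#' only the true orientation has a conserved element on its upstream side.
#' @return List with `pwm10`, `pwm35`, `sites10` (the oriented -10 site
#'   table) and `composites` (one composite motif per spacer).
#' @export
derive_promoter_motifs <- function(seqs, width10 = 7L, width35 = 7L,
                                   offset = NULL, seg_length = 10L,
                                   spacer_range = 16:19, seed = 1L) {
  offset <- offset %||% (width35 + max(spacer_range))
  d10 <- discover_motif_zoops(seqs, width10, revcomp = TRUE,
                              seed = derive_seed(seed, "minus10"))
  flip <- function(sites) {
    sites$strand <- ifelse(sites$strand == "+", "-", "+")
    sites
  }
  orientations <- list(
    list(pwm10 = d10$pwm, sites = d10$sites),
    list(pwm10 = reverse_complement_pwm(d10$pwm), sites = flip(d10$sites))
  )
  best <- NULL
  for (ori in orientations) {
    segments <- suppressWarnings(
      extract_upstream_segments(seqs, ori$sites, offset = offset,
                                length = seg_length)
    )
    if (length(segments) < 2L) next
    d35 <- discover_motif_zoops(segments, width35, revcomp = FALSE,
                                seed = derive_seed(seed, "minus35"))
    score <- d35$loglik / length(segments)
    if (is.null(best) || score > best$score)
      best <- list(score = score, d35 = d35, ori = ori)
  }
  if (is.null(best))
    stop("too few upstream segments to discover a -35 element")
  composites <- lapply(spacer_range, function(sp) {
    build_composite_motif(best$d35$pwm, best$ori$pwm10, sp, spacer_range)
  })
  names(composites) <- as.character(spacer_range)
  list(pwm10 = best$ori$pwm10, pwm35 = best$d35$pwm,
       sites10 = best$ori$sites, composites = composites)
}

best_hit_per_sequence <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- vapply(split(seq_len(nrow(hits)), hits$seq_id), function(ix) {
    h <- hits[ix, ]
    ix[order(h$p_value, h$offset, match(h$strand, c("+", "-")))[1]]
  }, integer(1))
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full regulon-inference pipeline
#'
#' Executes the stages in order — generate or ingest inputs, preprocess the
#' expression profiles, classify them against the two regulators, fit the
#' kinetic model per gene (against the housekeeping factor for
#' HrdB-correlated genes, against the alternative sigma factor otherwise),
#' derive and scan the bipartite promoter motif, tally spacers, and compute
#' functional enrichment of the sigma-factor group — writing each stage's
#' tables plus a machine-readable `summary.json` into `outdir`. Reruns with
#' the same config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  ms <- config$master_seed

  if (config$mode == "synthetic") {
    cohort <- simulate_expression_cohort(config$simulation, config$n_activated,
                                         config$n_repressed, config$n_hrdb,
                                         config$n_flat)
    sigE <- cohort$sigE; hrdB <- cohort$hrdB; targets <- cohort$targets
    utils::write.table(cohort$truth, file.path(outdir, "truth_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression_tsv(targets, file.path(outdir, "expression_log2.tsv"))
    promoters <- generate_promoter_set(config$simulation,
                                       seed = derive_seed(ms, "promoters"))
    seqs <- promoters$sequences
    utils::write.table(promoters$ground_truth,
                       file.path(outdir, "truth_promoters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(seqs, file.path(outdir, "promoters.fasta"))
    annotations <- generate_annotation_table(
      length(targets), stats::setNames(config$focal_fraction, config$focal_class),
      seed = derive_seed(ms, "annotation"))
    annotations$gene_id <- names(targets)
  } else {
    profiles <- read_expression_tsv(config$paths$expression_tsv)
    sigE <- delog_expression(profiles[[config$paths$sigE_gene]])
    hrdB <- delog_expression(profiles[[config$paths$hrdB_gene]])
    targets <- profiles[setdiff(names(profiles),
                                c(config$paths$sigE_gene, config$paths$hrdB_gene))]
    seqs <- if (!is.null(config$paths$peaks_narrowpeak)) {
      peaks <- read_narrowpeak(config$paths$peaks_narrowpeak)
      genome <- read_fasta(config$paths$genome_fasta)
      extract_peak_windows(peaks, genome)
    } else if (!is.null(config$paths$promoter_fasta)) {
      read_fasta(config$paths$promoter_fasta)
    } else NULL
    annotations <- if (!is.null(config$paths$annotation_tsv))
      read_annotation_tsv(config$paths$annotation_tsv) else NULL
  }

  # -- classify ---------------------------------------------------------
  groups <- classify_cohort(targets, sigE, hrdB,
                            r_threshold = config$r_threshold,
                            flat_threshold = config$flat_threshold)
  utils::write.table(groups, file.path(outdir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  group_counts <- vapply(c("A_sigE", "B_hrdB", "C_flat", "other"),
                         function(g) sum(groups$group == g), integer(1))

  # -- kinetic fits -----------------------------------------------------
  sigE_p <- preprocess_profile(sigE)
  hrdB_p <- preprocess_profile(hrdB)
  fit_rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups$group[i]
    if (g == "C_flat") next
    gid <- groups$gene_id[i]
    target_p <- preprocess_profile(targets[[gid]])
    regulator <- if (g == "B_hrdB") "hrdB" else "sigE"
    fit <- fit_single_regulator(target_p,
                                if (g == "B_hrdB") hrdB_p else sigE_p,
                                n_restarts = config$n_restarts,
                                master_seed = derive_seed(ms, "fit", i),
                                fit_threshold = config$fit_threshold)
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      gene_id = gid, group = g, regulator = regulator,
      k1 = fit$params$k1, k2 = fit$params$k2, b = fit$params$b,
      w = fit$params$w[1], sse = fit$sse,
      normalized_sse = fit$normalized_sse, verdict = fit$verdict,
      stringsAsFactors = FALSE
    )
  }
  fits <- if (length(fit_rows) > 0) do.call(rbind, fit_rows) else
    data.frame(gene_id = character(), group = character(),
               regulator = character(), k1 = numeric(), k2 = numeric(),
               b = numeric(), w = numeric(), sse = numeric(),
               normalized_sse = numeric(), verdict = character(),
               stringsAsFactors = FALSE)
  utils::write.table(fits, file.path(outdir, "kinetic_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  repressed <- fits$gene_id[fits$regulator == "sigE" &
                            fits$verdict == "regulation_possible" & fits$w < 0]

  # -- promoter motifs --------------------------------------------------
  spacer_tally <- NULL
  if (!is.null(seqs)) {
    motifs <- derive_promoter_motifs(seqs, config$motif_width10,
                                     config$motif_width35,
                                     spacer_range = config$spacer_range,
                                     seed = derive_seed(ms, "motifs"))
    write_meme(motifs$composites, file.path(outdir, "composite_motifs.meme"))
    hits <- scan_sequences(motifs$composites, seqs,
                           p_threshold = config$p_threshold)
    hits <- best_hit_per_sequence(prune_overlapping_hits(hits))
    write_hits_tsv(hits, file.path(outdir, "motif_hits.tsv"))
    spacer_tally <- tally_spacers(hits, config$spacer_range)
  }

  # -- enrichment -------------------------------------------------------
  enrichment <- NULL
  sig_genes <- groups$gene_id[groups$group == "A_sigE"]
  if (!is.null(annotations) && length(sig_genes) > 0 &&
      any(sig_genes %in% annotations$gene_id)) {
    enrichment <- enrichment_report(gene_set("A_sigE", sig_genes), annotations)
    utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    mode = config$mode,
    master_seed = ms,
    n_genes = length(targets),
    group_counts = as.list(group_counts),
    verdicts = fits[, c("gene_id", "group", "regulator", "w", "verdict")],
    repressed_genes = as.character(repressed),
    spacer_tally = if (!is.null(spacer_tally)) as.list(spacer_tally) else NULL,
    enrichment = enrichment
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(summary)
}

#' Regenerate the packaged small test dataset
#'
#' Writes a deterministic bundle — 20 genes plus both regulators on the
#' 32-point hour grid (expression TSV, log2 scale), 50 promoter windows of
#' 100 bp (FASTA), their ground-truth tables, an annotation table and the
#' generating config — suitable as a self-contained fixture.
#'
#' @param dir Output directory.
#' @param seed Master seed (default 42).
#' @return Invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulation_config(master_seed = seed, n_sequences = 50L)
  cohort <- simulate_expression_cohort(sim, n_activated = 7L, n_repressed = 3L,
                                       n_hrdb = 6L, n_flat = 4L)
  profiles <- c(list(sigE = log_expression(cohort$sigE),
                     hrdB = log_expression(cohort$hrdB)),
                cohort$targets)
  paths <- c(
    expression = file.path(dir, "expression_log2.tsv"),
    truth_expression = file.path(dir, "truth_expression.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    truth_promoters = file.path(dir, "truth_promoters.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_expression_tsv(profiles, paths[["expression"]])
  utils::write.table(cohort$truth, paths[["truth_expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  promoters <- generate_promoter_set(sim, seed = derive_seed(seed, "promoters"))
  write_fasta(promoters$sequences, paths[["promoters"]])
  utils::write.table(promoters$ground_truth, paths[["truth_promoters"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- generate_annotation_table(200L, c(membrane = 0.168),
                                   seed = derive_seed(seed, "annotation"))
  utils::write.table(ann, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pipeline_config(pipeline_config(master_seed = seed, simulation = sim),
                        paths[["config"]])
  invisible(paths)
}
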