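test_that("PWM construction from sites follows the pseudocount formula", {
  p <- build_pwm(c("TA", "TA", "TA"), pseudocount = 0)
  expect_equal(unname(p$probs[1, "T"]), 1)
  expect_equal(unname(p$probs[2, "A"]), 1)
  pc <- build_pwm(c("TA", "TA"), pseudocount = 1)
  expect_true(all(pc$probs > 0))
  expect_equal(unname(pc$probs[1, "T"]), (2 + 0.25) / 3)
  # uniform random sites converge to the background
  set.seed(12)
  sites <- vapply(1:4000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
  }, character(1))
  pu <- build_pwm(sites, pseudocount = 0)
  expect_lt(max(abs(pu$probs - 0.25)), 0.03)
  expect_error(build_pwm(c("TA", "TAA")), "equal length")
  expect_error(build_pwm(c("TN", "TA")), "A, C, G, T")
  expect_error(build_pwm("TA"), "at least 2")
})

test_that("composite motifs concatenate half-sites across neutral spacers", {
  fam <- sige_motif_family()
  comp <- build_composite_motif(fam$pwm35, fam$pwm10, 18)
  expect_equal(pwm_width(comp), 7 + 18 + 7)
  # spacer columns contribute exactly zero to every log-odds score
  si <- sigrekin:::int_score_matrix(comp, comp$background, 0.01)
  expect_true(all(si[8:25, ] == 0))
  comps <- lapply(16:19, function(s) build_composite_motif(fam$pwm35, fam$pwm10, s))
  for (comp2 in comps) {
    expect_equal(comp2$probs[1:7, ], comp$probs[1:7, ])
    w <- pwm_width(comp2)
    expect_equal(comp2$probs[(w - 6):w, ], comp$probs[26:32, ])
  }
  expect_error(build_composite_motif(fam$pwm35, fam$pwm10, 21), "spacer")
})

test_that("exact p-value table equals brute-force enumeration at width 5", {
  set.seed(3)
  bg <- c(0.2, 0.3, 0.3, 0.2)
  sites <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE,
                 prob = c(0.5, 0.1, 0.1, 0.3)), collapse = "")
  }, character(1))
  p5 <- build_pwm(sites, pseudocount = 0.5, background = bg)
  tab <- score_pvalue_table(p5, granularity = 0.01)
  words <- as.matrix(expand.grid(rep(list(1:4), 5)))
  sc <- apply(words, 1, function(wd) sum(tab$int_scores[cbind(1:5, wd)]))
  dp <- pvalue_from_table(tab, sc)
  brute <- brute_force_pvalues(tab$int_scores, bg, sc)
  expect_equal(dp, brute, tolerance = 1e-12)
  # tail is monotone non-increasing and reaches 1 at the minimum score
  expect_true(all(diff(tab$tail) <= 1e-15))
  expect_equal(pvalue_from_table(tab, min(sc)), 1)
  expect_error(score_pvalue_table(p5, granularity = 0), "positive")
})

test_that("an uninformative motif scores zero with p = 1 everywhere", {
  bg <- gc_background()
  flat <- pwm(matrix(bg, nrow = 6, ncol = 4, byrow = TRUE), bg)
  tab <- score_pvalue_table(flat)
  expect_equal(length(tab$tail), 1L)
  expect_equal(tab$tail, 1)
  expect_true(all(tab$int_scores == 0))
})

test_that("halving the discretization barely moves any p-value", {
  fam <- sige_motif_family()
  tab1 <- score_pvalue_table(fam$pwm10, granularity = 0.02)
  tab2 <- score_pvalue_table(fam$pwm10, granularity = 0.01)
  words <- as.matrix(expand.grid(rep(list(1:4), 7)))
  p1 <- pvalue_from_table(tab1, apply(words, 1, function(wd)
    sum(tab1$int_scores[cbind(1:7, wd)])))
  p2 <- pvalue_from_table(tab2, apply(words, 1, function(wd)
    sum(tab2$int_scores[cbind(1:7, wd)])))
  expect_lt(max(abs(p1 - p2)), 0.01)
})

test_that("planted consensus sites are recovered at exact coordinates", {
  fam <- sige_motif_family()
  cfg <- simulation_config(master_seed = 3, n_sequences = 200,
                           planting_rate = 1)
  ps <- generate_promoter_set(cfg, fam, seed = 5, site_model = "consensus")
  comps <- lapply(16:19, function(s)
    build_composite_motif(fam$pwm35, fam$pwm10, s))
  hits <- scan_sequences(comps, ps$sequences, 0.05,
                         background = gc_background())
  best <- do.call(rbind, lapply(split(hits, hits$seq_id), function(h) {
    h[order(h$p_value, h$offset)[1], ]
  }))
  m <- merge(ps$ground_truth, best, by = "seq_id")
  exact <- m$position == m$offset & m$strand.x == m$strand.y &
    m$spacer.x == m$spacer.y
  expect_gte(mean(exact), 0.99)
})

test_that("scanning is invariant under reverse-complementing the input", {
  fam <- sige_motif_family()
  cfg <- simulation_config(master_seed = 8, n_sequences = 40,
                           planting_rate = 0.8)
  ps <- generate_promoter_set(cfg, fam, seed = 2)
  comp <- build_composite_motif(fam$pwm35, fam$pwm10, 18)
  fwd <- scan_sequences(comp, ps$sequences, 0.05)
  rc_seqs <- vapply(ps$sequences, sigrekin:::revcomp_string, character(1))
  names(rc_seqs) <- names(ps$sequences)
  rev <- scan_sequences(comp, rc_seqs, 0.05)
  expect_equal(nrow(fwd), nrow(rev))
  w <- pwm_width(comp)
  L <- nchar(ps$sequences[1])
  mirrored <- data.frame(seq_id = rev$seq_id, offset = L - rev$offset - w,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score, p_value = rev$p_value,
                         stringsAsFactors = FALSE)
  ord <- function(d) d[order(d$seq_id, d$offset, d$strand), ]
  expect_equal(ord(mirrored)$offset,
               ord(fwd[, c("seq_id", "offset", "strand", "score", "p_value")])$offset)
  expect_equal(ord(mirrored)$score, ord(fwd)$score, tolerance = 1e-12)
  expect_equal(ord(mirrored)$p_value, ord(fwd)$p_value, tolerance = 1e-12)
})

test_that("background-only hit rates match the p-value threshold", {
  fam <- sige_motif_family(strength35 = 0.6, strength10 = 0.6)
  comp <- build_composite_motif(fam$pwm35, fam$pwm10, 18)
  seqs <- random_sequences(100, 110, gc = 0.72, seed = 14)
  bg <- gc_background()
  npos <- sum(nchar(seqs) - pwm_width(comp) + 1) * 2
  for (thr in c(0.05, 0.001)) {
    hits <- scan_sequences(comp, seqs, thr, background = bg)
    rate <- nrow(hits) / npos
    ci <- 1.96 * sqrt(thr * (1 - thr) / npos)
    expect_lt(abs(rate - thr), ci + 1e-12)
  }
})

test_that("peak windows are summit-centred, edge-aware and strand-symmetric", {
  set.seed(20)
  genome <- c(chr = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                          collapse = ""))
  peaks <- data.frame(contig = "chr", start = 400L, end = 620L,
                      name = "p1", summit = 500L, stringsAsFactors = FALSE)
  win <- extract_peak_windows(peaks, genome, 100)
  expect_equal(nchar(win[["p1"]]), 100)
  expect_equal(win[["p1"]], substr(genome[["chr"]], 451, 550))
  edge <- data.frame(contig = "chr", start = 0L, end = 30L, name = "p2",
                     summit = 10L, stringsAsFactors = FALSE)
  expect_warning(w2 <- extract_peak_windows(edge, genome, 100), "skipped")
  expect_length(w2, 0)
  w3 <- extract_peak_windows(edge, genome, 100, policy = "clip")
  expect_equal(w3[["p2"]], substr(genome[["chr"]], 1, 60))
  # mirrored coordinates on the reverse-complemented genome give the
  # reverse-complemented window
  genome_rc <- c(chr = sigrekin:::revcomp_string(genome[["chr"]]))
  mirrored <- peaks
  mirrored$summit <- 1000L - peaks$summit
  win_rc <- extract_peak_windows(mirrored, genome_rc, 100)
  expect_equal(win_rc[["p1"]], sigrekin:::revcomp_string(win[["p1"]]))
})

test_that("upstream segments honour offsets and strand mirroring", {
  seq1 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  seqs <- c(s1 = seq1)
  sites <- data.frame(seq_id = "s1", start = 40L, strand = "+", width = 7L,
                      stringsAsFactors = FALSE)
  seg <- extract_upstream_segments(seqs, sites, offset = 23, length = 10)
  expect_equal(seg[["s1"]], substr(seq1, 18, 27))
  near_edge <- data.frame(seq_id = "s1", start = 5L, strand = "+",
                          width = 7L, stringsAsFactors = FALSE)
  expect_warning(s0 <- extract_upstream_segments(seqs, near_edge, 23, 10),
                 "skipped")
  expect_length(s0, 0)
  # minus-strand mirroring equals extracting on the reverse complement
  minus <- data.frame(seq_id = "s1", start = 40L, strand = "-", width = 7L,
                      stringsAsFactors = FALSE)
  seg_m <- extract_upstream_segments(seqs, minus, offset = 23, length = 10)
  rc <- sigrekin:::revcomp_string(seq1)
  start_rc <- nchar(seq1) - (40 + 7)   # site start in the mirrored frame
  expected <- substr(rc, start_rc - 23 + 1, start_rc - 23 + 10)
  expect_equal(unname(seg_m[["s1"]]), expected)
})

test_that("best-per-sequence plus pattern filtering works and is order-free", {
  hits <- data.frame(
    seq_id = c("a", "a", "a", "b"),
    offset = c(5L, 20L, 40L, 3L),
    strand = c("+", "-", "+", "+"),
    score = c(5, 7, 3, 4),
    p_value = c(0.01, 0.001, 0.04, 0.02),
    spacer = NA_integer_, width = 10L,
    matched = c("GCTAGGGTAC", "CCCCCCCCCC", "AATAGCGTGG", "GGGGGGGGGG"),
    stringsAsFactors = FALSE
  )
  out <- filter_best_and_pattern(hits, "--TA---T--")
  # best per sequence: a/offset 20, b/offset 3; pattern adds offsets 5 and 40
  expect_setequal(paste(out$seq_id, out$offset), c("a 5", "a 20", "a 40", "b 3"))
  expect_true(matches_pattern("GCTAGGGTAC", "--TA---T--"))
  expect_false(matches_pattern("GCTAGGGAAC", "--TA---T--"))
  one <- hits[4, ]
  expect_equal(filter_best_and_pattern(one, "--TA---T--")$offset, 3L)
  expect_error(filter_best_and_pattern(hits, "--TA--"), "length")
  # ties on minimum p keep the leftmost hit regardless of input order
  ties <- data.frame(seq_id = "a", offset = c(30L, 10L), strand = c("+", "+"),
                     score = c(5, 5), p_value = c(0.01, 0.01),
                     spacer = NA_integer_, width = 10L,
                     matched = c("CCCCCCCCCC", "GGGGGGGGGG"),
                     stringsAsFactors = FALSE)
  o1 <- filter_best_and_pattern(ties, "--------CC")
  o2 <- filter_best_and_pattern(ties[2:1, ], "--------CC")
  expect_equal(o1$offset, o2$offset)
  expect_true(10L %in% o1$offset)
})

test_that("overlap pruning keeps one lowest-p hit per cluster", {
  hits <- data.frame(
    seq_id = c("a", "a", "a"),
    offset = c(10L, 15L, 60L), strand = "+",
    score = c(3, 6, 4), p_value = c(0.03, 0.004, 0.01),
    spacer = c(16L, 18L, 17L), width = c(30L, 32L, 31L),
    matched = "X", stringsAsFactors = FALSE
  )
  pruned <- prune_overlapping_hits(hits)
  expect_equal(pruned$offset, c(15L, 60L))
})

test_that("spacer tallies count retained hits", {
  hits <- data.frame(spacer = c(18L, 18L, 17L))
  expect_equal(tally_spacers(hits),
               c(`16` = 0L, `17` = 1L, `18` = 2L, `19` = 0L))
  expect_equal(sum(tally_spacers(hits)), nrow(hits))
  expect_equal(tally_spacers(data.frame(spacer = integer())),
               c(`16` = 0L, `17` = 0L, `18` = 0L, `19` = 0L))
})

test_that("ZOOPS EM recovers a planted 7-mer and increases its objective", {
  set.seed(9)
  bg <- gc_background()
  seqs <- random_sequences(100, 100, seed = 9)
  planted <- "TTAACGT"
  for (i in 1:90) {
    p <- sample(1:93, 1)
    substr(seqs[i], p, p + 6) <- planted
  }
  z <- discover_motif_zoops(seqs, 7, seed = 2)
  cons <- consensus_string(z$pwm)
  cons_rc <- consensus_string(reverse_complement_pwm(z$pwm))
  expect_true(planted %in% c(cons, cons_rc))
  expect_true(all(diff(z$objective_trace) > -1e-6))
  z2 <- discover_motif_zoops(seqs, 7, seed = 2)
  expect_identical(z$pwm$probs, z2$pwm$probs)
  expect_error(discover_motif_zoops(seqs, 200, seed = 1), "width")
})

test_that("reverse complement of a PWM is an involution", {
  fam <- sige_motif_family()
  rc2 <- reverse_complement_pwm(reverse_complement_pwm(fam$pwm10))
  expect_equal(rc2$probs, fam$pwm10$probs, ignore_attr = TRUE)
  expect_equal(consensus_string(reverse_complement_pwm(fam$pwm10)),
               "TTAGACG")
})
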