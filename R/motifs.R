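DNA_BASES <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  m
}

revcomp_string <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]), collapse = "")
}

#' Position weight matrix
#'
#' A per-position base-probability matrix over A, C, G, T with an associated
#' background distribution. Scores are log-odds in bits:
#' `sum_i log2(p[i, base_i] / background[base_i])`.
#'
#' @param probs Numeric `width x 4` matrix, rows summing to 1, columns in
#'   A, C, G, T order.
#' @param background Length-4 probability vector (default uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("`probs` must have 4 columns (A, C, G, T)")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("each PWM row must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("`background` must be 4 positive probabilities summing to 1")
  colnames(probs) <- DNA_BASES
  structure(list(probs = probs, background = background), class = "pwm")
}

#' @rdname pwm
#' @param x A `pwm` or `composite_motif`.
#' @export
pwm_width <- function(x) nrow(x$probs)

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", pwm_width(x), consensus_string(x)))
  invisible(x)
}

#' @rdname pwm
#' @export
consensus_string <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param x A `pwm`.
#' @return The reverse-complemented `pwm` (column order reversed, bases
#'   complemented).
#' @export
reverse_complement_pwm <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), c(4, 3, 2, 1), drop = FALSE]
  pwm(p, x$background[c(4, 3, 2, 1)])
}

#' Build a PWM from aligned sites
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`: the pseudocount mass is spread according to the
#' background so a positive pseudocount yields a strictly positive matrix.
#'
#' @param sites Character vector of equal-length ACGT sequences (>= 2).
#' @param pseudocount Total pseudocount mass per column (default 0.25).
#' @param background Length-4 background probabilities (default uniform).
#' @return A [pwm()].
#' @export
build_pwm <- function(sites, pseudocount = 0.25, background = rep(0.25, 4)) {
  if (length(sites) < 2L) stop("need at least 2 sites")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L) stop("sites must have equal length")
  w <- widths[1]
  enc <- vapply(sites, encode_dna, integer(w))
  if (anyNA(enc)) stop("sites must contain only A, C, G, T")
  counts <- t(apply(enc, 1, tabulate, nbins = 4))
  if (w == 1L) counts <- matrix(tabulate(enc, 4), nrow = 1)
  probs <- sweep(counts + pseudocount * matrix(background, w, 4, byrow = TRUE),
                 1, length(sites) + pseudocount, "/")
  pwm(probs, background)
}

#' Per-column information content of a PWM
#'
#' @param x A `pwm`.
#' @return Numeric vector of bits per column,
#'   `sum_b p log2(p / background_b)`.
#' @export
pwm_information <- function(x) {
  apply(x$probs, 1, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / x$background[nz]))
  })
}

#' Construct a sharply peaked PWM from a consensus
#'
#' Utility for simulations: the consensus base gets probability `strength`;
#' the remainder is spread over the other bases in proportion to the
#' background.
#'
#' @param consensus ACGT string.
#' @param strength Probability of the consensus base per column (default
#'   0.85).
#' @param background Length-4 background probabilities.
#' @return A [pwm()].
#' @export
make_strong_pwm <- function(consensus, strength = 0.85,
                            background = rep(0.25, 4)) {
  enc <- encode_dna(consensus)
  if (anyNA(enc)) stop("consensus must be an ACGT string")
  probs <- t(vapply(enc, function(b) {
    p <- background
    p[b] <- 0
    p <- p / sum(p) * (1 - strength)
    p[b] <- strength
    p
  }, numeric(4)))
  pwm(probs, background)
}

#' Built-in sigma-E-like bipartite motif family
#'
#' A -35 half-site with the ECF-type consensus `GGAACTT` and an AT-rich
#' extended -10 half-site (`CGTCTAA`), both as sharply peaked PWMs over a
#' GC-rich background — the default planted motif of the promoter-sequence
#' generator. The -10 is more conserved than the -35, mirroring the
#' asymmetry seen in sigma-factor promoters (the -10 is recovered at many
#' more sites than the -35).
#'
#' @param gc_content Background GC fraction (default 0.72).
#' @param strength35,strength10 Consensus-base probabilities of the two
#'   half-sites (defaults 0.8 and 0.9).
#' @return List with elements `pwm35` and `pwm10`.
#' @export
sige_motif_family <- function(gc_content = 0.72, strength35 = 0.8,
                              strength10 = 0.9) {
  bg <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
          (1 - gc_content) / 2)
  list(pwm35 = make_strong_pwm("GGAACTT", strength35, bg),
       pwm10 = make_strong_pwm("CGTCTAA", strength10, bg))
}

#' Join -35 and -10 half-sites across a spacer
#'
#' Concatenates the two half-site PWMs with `spacer` uninformative columns
#' (background frequencies) in between, so the spacer contributes exactly
#' zero to every log-odds score.
#'
#' @param pwm35,pwm10 Half-site [pwm()]s (shared background).
#' @param spacer Spacer length in bp, within `spacer_range`.
#' @param spacer_range Allowed spacer lengths (default `16:19`).
#' @return A `composite_motif` (inherits from `pwm`) with fields `spacer`,
#'   `width35`, `width10`.
#' @export
build_composite_motif <- function(pwm35, pwm10, spacer, spacer_range = 16:19) {
  spacer <- as.integer(spacer)
  if (!spacer %in% spacer_range)
    stop(sprintf("`spacer` must be one of {%s}", paste(spacer_range, collapse = ",")))
  bg <- pwm35$background
  probs <- rbind(pwm35$probs,
                 matrix(bg, nrow = spacer, ncol = 4, byrow = TRUE),
                 pwm10$probs)
  out <- pwm(probs, bg)
  out$spacer <- spacer
  out$width35 <- pwm_width(pwm35)
  out$width10 <- pwm_width(pwm10)
  class(out) <- c("composite_motif", "pwm")
  out
}

#' @export
print.composite_motif <- function(x, ...) {
  cat(sprintf("<composite_motif> -35 width %d | spacer %d | -10 width %d\n",
              x$width35, x$spacer, x$width10))
  invisible(x)
}

#' Estimate a complement-symmetric background from sequences
#'
#' 0-order base frequencies averaged with their reverse complement
#' (A=T, C=G), so double-stranded scanning is invariant under
#' reverse-complementing the input.
#'
#' @param seqs Character vector of sequences.
#' @return Length-4 probability vector over A, C, G, T.
#' @export
estimate_background <- function(seqs) {
  enc <- unlist(lapply(seqs, encode_dna))
  counts <- tabulate(enc[!is.na(enc)], 4)
  if (sum(counts) == 0) stop("no A/C/G/T bases found")
  f <- counts / sum(counts)
  f <- (f + f[c(4, 3, 2, 1)]) / 2
  f / sum(f)
}

# Integer (discretized) log-odds scores: width x 4 matrix of
# round(log2(p/bg) / granularity).
int_score_matrix <- function(motif, background, granularity) {
  lo <- log2(sweep(motif$probs, 2, background, "/"))
  if (any(!is.finite(lo)))
    stop("PWM has zero entries; use a pseudocount before scanning")
  matrix(as.integer(round(lo / granularity)), nrow = nrow(lo))
}

#' Exact score-to-p-value table for a motif
#'
#' Dynamic programming over discretized per-column log-odds scores: the
#' exact distribution of the motif score of a random background word is
#' built column by column, and upper-tail probabilities
#' `p(s) = P(score >= s | background)` are read off. Background columns
#' (e.g. the spacer of a composite motif) score identically zero and do not
#' widen the distribution.
#'
#' @param motif A `pwm` or `composite_motif`.
#' @param background Length-4 background probabilities (default the motif's).
#' @param granularity Score discretization in bits (default 0.01).
#' @return Object of class `score_pvalue_table` with the integer score
#'   matrix, the tail vector and its score offset.
#' @export
score_pvalue_table <- function(motif, background = NULL, granularity = 0.01) {
  if (!is.numeric(granularity) || granularity <= 0)
    stop("`granularity` must be positive")
  background <- background %||% motif$background
  si <- int_score_matrix(motif, background, granularity)
  w <- nrow(si)
  dist <- 1
  offset <- 0L  # integer score of dist[1]
  for (j in seq_len(w)) {
    row <- si[j, ]
    lo <- min(row); hi <- max(row)
    n_new <- length(dist) + (hi - lo)
    new <- numeric(n_new)
    for (b in 1:4) {
      sh <- row[b] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    offset <- offset + lo
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(tail, 1)
  structure(list(int_scores = si, tail = tail, offset = offset,
                 granularity = granularity, background = background),
            class = "score_pvalue_table")
}

#' Look up exact p-values for integer motif scores
#'
#' @param table A [score_pvalue_table()].
#' @param int_score Integer score(s) on the table's discretized scale.
#' @return Upper-tail p-value(s) in `(0, 1]`; scores below the attainable
#'   minimum give 1, above the maximum give the smallest tail mass.
#' @export
pvalue_from_table <- function(table, int_score) {
  idx <- int_score - table$offset + 1L
  idx[idx < 1L] <- 1L
  n <- length(table$tail)
  out <- numeric(length(idx))
  over <- idx > n
  out[over] <- table$tail[n]
  out[!over] <- table$tail[idx[!over]]
  out
}

# Scores of one integer-score matrix at every offset of an encoded sequence.
# NA bases (non-ACGT) contribute zero, mirroring background substitution.
scan_scores <- function(si, enc) {
  w <- nrow(si)
  L <- length(enc)
  n_off <- L - w + 1L
  if (n_off < 1L) return(integer(0))
  scores <- integer(n_off)
  for (j in seq_len(w)) {
    b <- enc[j:(j + n_off - 1L)]
    contrib <- si[j, ]
    v <- contrib[b]
    v[is.na(b)] <- 0L
    scores <- scores + v
  }
  scores
}

#' Scan sequences with one or more motifs on both strands
#'
#' Every offset of every sequence is scored on both strands against each
#' motif (log-odds in bits against a complement-symmetric background), exact
#' p-values are computed from the discretized score distribution, and hits
#' with `p <= p_threshold` are returned. A minus-strand hit at `offset` means
#' the motif matches the reverse complement of the window starting there; the
#' reported `matched` sequence is read on the hit strand.
#'
#' @param motifs A `pwm`/`composite_motif` or a list of them (e.g. the four
#'   spacer variants of a composite motif).
#' @param seqs Named character vector of sequences.
#' @param p_threshold P-value threshold (default 0.05).
#' @param background Length-4 background; default is estimated from `seqs`
#'   with [estimate_background()].
#' @param granularity Score discretization in bits (default 0.01).
#' @return Data frame of hits: `seq_id`, `offset` (0-based window start on
#'   the forward strand), `strand`, `score` (bits), `p_value`, `spacer`
#'   (`NA` for a plain PWM), `width`, `matched`.
#' @export
scan_sequences <- function(motifs, seqs, p_threshold = 0.05,
                           background = NULL, granularity = 0.01) {
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  background <- background %||% estimate_background(seqs)
  encs <- lapply(seqs, encode_dna)
  if (any(vapply(encs, anyNA, logical(1))))
    warning("non-ACGT bases scored as background (zero log-odds contribution)")
  hits <- list()
  for (k in seq_along(motifs)) {
    motif <- motifs[[k]]
    tab <- score_pvalue_table(motif, background, granularity)
    si_fwd <- tab$int_scores
    w <- nrow(si_fwd)
    # reverse-complement score matrix: same integer entries, so the forward
    # table is exact for both strands under a complement-symmetric background
    si_rev <- si_fwd[rev(seq_len(w)), c(4, 3, 2, 1), drop = FALSE]
    spacer <- if (inherits(motif, "composite_motif")) motif$spacer else NA_integer_
    for (i in seq_along(encs)) {
      enc <- encs[[i]]
      for (strand in c("+", "-")) {
        sc <- scan_scores(if (strand == "+") si_fwd else si_rev, enc)
        if (length(sc) == 0L) next
        pv <- pvalue_from_table(tab, sc)
        keep <- which(pv <= p_threshold)
        if (length(keep) == 0L) next
        matched <- substring(seqs[i], keep, keep + w - 1L)
        if (strand == "-") matched <- vapply(matched, revcomp_string, character(1))
        hits[[length(hits) + 1L]] <- data.frame(
          seq_id = names(seqs)[i], offset = keep - 1L, strand = strand,
          score = sc[keep] * granularity, p_value = pv[keep],
          spacer = spacer, width = w, matched = unname(matched),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), spacer = integer(),
                      width = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Extract fixed-width windows centred on peak summits
#'
#' @param peaks Data frame with columns `contig`, `summit` (0-based absolute
#'   position) and `name` (e.g. from [read_narrowpeak()]).
#' @param genome Named character vector (or `Biostrings::DNAStringSet`) of
#'   contig sequences.
#' @param width Window width in bp (default 100): the window is
#'   `[summit - width/2, summit + width/2)`, 0-based half-open.
#' @param policy What to do when a window overruns its contig: `"skip"` the
#'   peak with a warning (default) or `"clip"` to the contig.
#' @return Named character vector of uppercase windows (names = peak names).
#' @export
extract_peak_windows <- function(peaks, genome, width = 100L,
                                 policy = c("skip", "clip")) {
  policy <- match.arg(policy)
  if (!is.character(genome)) genome <- as.character(genome)
  half <- as.integer(width) %/% 2L
  out <- character(0)
  for (i in seq_len(nrow(peaks))) {
    contig <- peaks$contig[i]
    if (!contig %in% names(genome)) stop(sprintf("contig '%s' not in genome", contig))
    L <- nchar(genome[[contig]])
    s <- peaks$summit[i] - half
    e <- peaks$summit[i] + (width - half)
    if (s < 0L || e > L) {
      if (policy == "skip") {
        warning(sprintf("peak '%s': window overruns contig, skipped", peaks$name[i]))
        next
      }
      s <- max(s, 0L); e <- min(e, L)
    }
    out[[peaks$name[i]]] <- toupper(substring(genome[[contig]], s + 1L, e))
  }
  out
}

#' Extract segments upstream of discovered -10 sites
#'
#' For a plus-strand -10 site starting at `s` (0-based), returns the segment
#' `[s - offset, s - offset + length)` — with the defaults, the 10 bp window
#' starting 23 bp upstream in which the -35 element is sought. Minus-strand
#' sites are mirrored (the segment lies downstream in forward coordinates and
#' is reverse-complemented). Segments that would overrun their sequence are
#' skipped with a warning.
#'
#' @param seqs Named character vector of sequences.
#' @param minus10_sites Data frame with columns `seq_id`, `start` (0-based),
#'   `strand` and optionally `width` (else `site_width` is used).
#' @param offset Distance upstream from the site start (default 23).
#' @param length Segment length (default 10).
#' @param site_width Width of the -10 site, used for minus-strand mirroring.
#' @return Character vector of segments (read on the site strand), named by
#'   `seq_id`.
#' @export
extract_upstream_segments <- function(seqs, minus10_sites, offset = 23L,
                                      length = 10L, site_width = NULL) {
  out <- character(0)
  nm <- character(0)
  for (i in seq_len(nrow(minus10_sites))) {
    sid <- minus10_sites$seq_id[i]
    if (!sid %in% names(seqs)) stop(sprintf("unknown seq_id '%s'", sid))
    L <- nchar(seqs[[sid]])
    s <- minus10_sites$start[i]
    strand <- minus10_sites$strand[i]
    w10 <- if (!is.null(minus10_sites$width)) minus10_sites$width[i] else site_width
    if (strand == "-" && is.null(w10))
      stop("minus-strand mirroring needs the -10 site width")
    if (strand == "+") {
      a <- s - offset
      b <- a + length
    } else {
      b <- s + w10 + offset
      a <- b - length
    }
    if (a < 0L || b > L) {
      warning(sprintf("segment for '%s' overruns the sequence, skipped", sid))
      next
    }
    seg <- substring(seqs[[sid]], a + 1L, b)
    if (strand == "-") seg <- revcomp_string(seg)
    out <- c(out, seg)
    nm <- c(nm, sid)
  }
  names(out) <- nm
  out
}

#' Keep the best hit per sequence plus all pattern matches
#'
#' Two-stage retention rule for scanned motif sites: (1) on each sequence the
#' hit with the lowest p-value is retained (ties broken by leftmost offset,
#' then plus strand); (2) additionally, every hit whose matched sequence
#' equals the given wildcard pattern (`-` matches any base) is retained.
#'
#' @param hits Hit data frame from [scan_sequences()].
#' @param pattern Wildcard pattern, default `"--TA---T--"`; its length must
#'   equal the width of the matched motif core.
#' @return Filtered hit data frame (union of the two rules, duplicates
#'   removed), ordered by `seq_id` then `offset`.
#' @export
filter_best_and_pattern <- function(hits, pattern = "--TA---T--") {
  if (nrow(hits) == 0L) return(hits)
  if (any(nchar(hits$matched) != nchar(pattern)))
    stop("pattern length does not match the motif core width")
  best_idx <- unlist(lapply(split(seq_len(nrow(hits)), hits$seq_id), function(ix) {
    h <- hits[ix, ]
    ord <- order(h$p_value, h$offset, match(h$strand, c("+", "-")))
    ix[ord[1]]
  }))
  pat_idx <- which(vapply(hits$matched, matches_pattern, logical(1),
                          pattern = pattern))
  keep <- sort(unique(c(best_idx, pat_idx)))
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$seq_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a sequence against a wildcard pattern
#'
#' @param x Sequence to test.
#' @param pattern Same-length pattern where `-` matches any base.
#' @return Logical.
#' @export
matches_pattern <- function(x, pattern) {
  if (nchar(x) != nchar(pattern)) return(FALSE)
  px <- strsplit(toupper(x), "")[[1]]
  pp <- strsplit(toupper(pattern), "")[[1]]
  all(pp == "-" | px == pp)
}

#' Collapse overlapping hits to the most significant one
#'
#' Hits on the same sequence whose windows overlap (across strands and
#' spacer variants) are clustered transitively; within each cluster only the
#' lowest-p hit is kept (ties: leftmost offset, then plus strand).
#'
#' @param hits Hit data frame from [scan_sequences()].
#' @return Pruned hit data frame.
#' @export
prune_overlapping_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$seq_id), function(ix) {
    h <- hits[ix, ]
    ord <- order(h$offset)
    h <- h[ord, ]; ix <- ix[ord]
    cluster <- cumsum(c(1L, as.integer(
      h$offset[-1] >= cummax(h$offset + h$width)[-nrow(h)]
    )))
    unlist(lapply(split(seq_len(nrow(h)), cluster), function(cx) {
      hc <- h[cx, ]
      o <- order(hc$p_value, hc$offset, match(hc$strand, c("+", "-")))
      ix[cx[o[1]]]
    }))
  }))
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally retained hits by spacer length
#'
#' @param hits Hit data frame with a `spacer` column (one retained hit per
#'   peak/gene).
#' @param spacer_range Spacer lengths to report (default `16:19`).
#' @return Named integer vector of counts over `spacer_range`, summing to
#'   `nrow(hits)` when all spacers fall in the range.
#' @export
tally_spacers <- function(hits, spacer_range = 16:19) {
  counts <- vapply(spacer_range, function(s) sum(hits$spacer == s, na.rm = TRUE),
                   integer(1))
  names(counts) <- as.character(spacer_range)
  counts
}

#' Discover an ungapped motif with a zero-or-one-per-sequence EM
#'
#' Expectation-maximization over the ZOOPS model: each sequence carries a
#' site with probability `gamma`, at a uniformly distributed position (and
#' strand, when `revcomp`), emitted from the PWM; everything else is
#' background. The best of `n_starts` runs (each seeded from a random data
#' window) by log-likelihood is returned. The EM objective (log-likelihood
#' plus the Dirichlet pseudocount prior) is non-decreasing across iterations.
#'
#' @param seqs Named character vector of sequences.
#' @param width Motif width (`<=` shortest sequence length).
#' @param revcomp Also consider sites on the minus strand (default `TRUE`).
#' @param n_starts Number of EM restarts (default 5).
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations per start (default 100).
#' @param pseudocount Dirichlet pseudocount mass per PWM column (default
#'   0.01).
#' @return List with `pwm`, `sites` (data frame `seq_id`, `start`, `strand`,
#'   `posterior` for sequences whose site posterior exceeds 0.5), `gamma`,
#'   `loglik` and `objective_trace`.
#' @export
discover_motif_zoops <- function(seqs, width, revcomp = TRUE, n_starts = 5L,
                                 seed = 1L, max_iter = 100L,
                                 pseudocount = 0.01) {
  width <- as.integer(width)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  lens <- nchar(seqs)
  if (width < 2L || width > min(lens)) stop("`width` out of range for the sequences")
  bg <- estimate_background(seqs)
  # enumerate all candidate windows once
  win <- list(); meta <- list()
  for (i in seq_along(seqs)) {
    enc <- encode_dna(seqs[[i]])
    if (anyNA(enc)) stop("sequences must contain only A, C, G, T")
    n_off <- lens[i] - width + 1L
    idx <- outer(0:(width - 1L), seq_len(n_off), "+")
    win[[length(win) + 1L]] <- t(matrix(enc[idx], nrow = width))
    meta[[length(meta) + 1L]] <- data.frame(seq = i, start = seq_len(n_off) - 1L,
                                            strand = "+")
    if (revcomp) {
      enc_rc <- rev(5L - enc)
      win[[length(win) + 1L]] <- t(matrix(enc_rc[idx], nrow = width))
      # start of the matched window in forward coordinates
      meta[[length(meta) + 1L]] <- data.frame(seq = i,
                                              start = rev(seq_len(n_off)) - 1L,
                                              strand = "-")
    }
  }
  windows <- do.call(rbind, win)
  meta <- do.call(rbind, meta)
  n_win <- nrow(windows)
  seq_of <- meta$seq
  slots_per_seq <- tabulate(seq_of, length(seqs))

  log_bg_win <- numeric(n_win)
  for (j in seq_len(width)) log_bg_win <- log_bg_win + log(bg[windows[, j]])

  em_run <- function(theta) {
    gamma <- 0.5
    obj_trace <- numeric(0)
    loglik <- -Inf
    for (iter in seq_len(max_iter)) {
      lw <- log(theta) - matrix(log(bg), width, 4, byrow = TRUE)
      llr <- numeric(n_win)
      for (j in seq_len(width)) llr <- llr + lw[j, windows[, j]]
      lr <- exp(llr)
      sum_lr <- vapply(split(lr, seq_of), sum, numeric(1))
      denom <- (1 - gamma) + gamma * sum_lr / slots_per_seq
      z <- gamma / slots_per_seq[seq_of] * lr / denom[seq_of]
      loglik_new <- sum(log(denom))  # background word term is constant
      prior <- sum(pseudocount * matrix(bg, width, 4, byrow = TRUE) * log(theta))
      obj_trace <- c(obj_trace, loglik_new + prior)
      # M-step
      counts <- matrix(pseudocount * bg, width, 4, byrow = TRUE)
      for (j in seq_len(width)) {
        for (b in 1:4) counts[j, b] <- counts[j, b] + sum(z[windows[, j] == b])
      }
      theta <- counts / rowSums(counts)
      gamma <- min(max(mean(vapply(split(z, seq_of), sum, numeric(1))), 1e-4),
                   1 - 1e-4)
      if (iter > 1 && abs(loglik_new - loglik) < 1e-8 * (abs(loglik) + 1)) {
        loglik <- loglik_new
        break
      }
      loglik <- loglik_new
    }
    list(theta = theta, gamma = gamma, loglik = loglik,
         objective_trace = obj_trace, z = z)
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    pick <- sample.int(n_win, 1)
    theta0 <- matrix(0.3 * bg, width, 4, byrow = TRUE)
    for (j in seq_len(width)) {
      theta0[j, windows[pick, j]] <- theta0[j, windows[pick, j]] + 0.7
    }
    theta0 <- theta0 / rowSums(theta0)
    run <- em_run(theta0)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  z_by_seq <- split(best$z, seq_of)
  idx_by_seq <- split(seq_len(n_win), seq_of)
  sites <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    tot <- sum(z_by_seq[[i]])
    if (tot <= 0.5) return(NULL)
    k <- idx_by_seq[[i]][which.max(z_by_seq[[i]])]
    data.frame(seq_id = names(seqs)[i], start = meta$start[k],
               strand = meta$strand[k], posterior = tot,
               width = width, stringsAsFactors = FALSE)
  }))
  if (is.null(sites))
    sites <- data.frame(seq_id = character(), start = integer(),
                        strand = character(), posterior = numeric(),
                        width = integer(), stringsAsFactors = FALSE)
  list(pwm = pwm(best$theta, bg), sites = sites, gamma = best$gamma,
       loglik = best$loglik, objective_trace = best$objective_trace)
}
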