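#' Read a genes x time-points expression table
#'
#' Expects a TSV whose header row gives the time points in hours and whose
#' first column holds gene IDs; values are on the scale stated (log2 for
#' published microarray tables).
#'
#' @param path TSV file path.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Named list of `expression_profile`s.
#' @export
read_expression_tsv <- function(path, scale = "log2") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  times <- as.numeric(colnames(tab)[-1])
  if (anyNA(times)) stop("header row must contain numeric hours")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    expression_profile(as.character(tab[i, 1]), times,
                       as.numeric(tab[i, -1]), scale = scale)
  })
  names(out) <- as.character(tab[[1]])
  out
}

#' Write expression profiles as a genes x time-points TSV
#'
#' @param profiles Named list of `expression_profile`s on a shared grid.
#' @param path Output TSV path.
#' @export
write_expression_tsv <- function(profiles, path) {
  times <- profiles[[1]]$times
  for (p in profiles) stopifnot_shared_grid(profiles[[1]], p)
  mat <- t(vapply(profiles, function(p) p$values, numeric(length(times))))
  df <- data.frame(gene_id = vapply(profiles, function(p) p$gene_id, character(1)),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", as.character(times))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peak regions from a MACS2 narrowPeak file
#'
#' narrowPeak is BED6+4; the 10th column is the summit offset from the peak
#' start. Coordinates are kept 0-based half-open; the returned `summit` is
#' the absolute 0-based summit position (`start + offset`).
#'
#' @param path narrowPeak file path.
#' @return Data frame: `contig`, `start`, `end`, `name`, `summit`.
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  start0 <- GenomicRanges::start(gr) - 1L  # GRanges is 1-based closed
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else sprintf("peak%04d", seq_along(gr)),
    summit = start0 + gr$peak,
    stringsAsFactors = FALSE
  )
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene set from a one-ID-per-line text file
#'
#' @param path File path.
#' @param name Set name (default the file name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  ids <- readLines(path)
  ids <- trimws(ids)
  gene_set(name, ids[nzchar(ids)])
}

#' Read a gene-to-class annotation TSV
#'
#' @param path Two-column TSV (`gene_id`, `class`) with a header row.
#' @return Data frame with unique `gene_id`s.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  colnames(tab)[1:2] <- c("gene_id", "class")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene IDs in annotation table")
  tab[, c("gene_id", "class")]
}

#' Write motifs in minimal MEME text format
#'
#' @param motifs Named list of `pwm`s (composite motifs included).
#' @param path Output path.
#' @param background Length-4 background written to the header (default the
#'   first motif's).
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "pwm")) motifs <- list(motif = motifs)
  bg <- background %||% motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (nm in names(motifs)) {
    m <- motifs[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       pwm_width(m)), con)
    for (i in seq_len(pwm_width(m)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$probs[i, 1], m$probs[i, 2],
                         m$probs[i, 3], m$probs[i, 4]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from minimal MEME text format
#'
#' @param path MEME-format motif file.
#' @return Named list of `pwm`s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx) > 0) {
    toks <- strsplit(trimws(lines[bg_idx[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_idx <- grep("^MOTIF ", lines)
  out <- list()
  for (mi in motif_idx) {
    nm <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- mi + 1
    while (!grepl("^letter-probability matrix", lines[hdr])) hdr <- hdr + 1
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
    rows <- t(vapply(lines[(hdr + 1):(hdr + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }, numeric(4)))
    rows <- rows / rowSums(rows)  # guard against printed rounding
    dimnames(rows) <- NULL
    out[[nm]] <- pwm(rows, bg)
  }
  out
}

#' Write a hit table as TSV
#'
#' @param hits Hit data frame from [scan_sequences()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(seq_id = hits$seq_id, start = hits$offset,
                    end = hits$offset + hits$width, strand = hits$strand,
                    spacer = hits$spacer, score_bits = hits$score,
                    p_value = hits$p_value, matched_sequence = hits$matched,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
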