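#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least `k` class members in a sample of `n`
#' genes from a genome of `N` genes containing `K` class members —
#' the standard overrepresentation test for a functional class within a
#' gene set.
#'
#' @param k Number of class members in the set.
#' @param n Set size.
#' @param K Class size in the genome.
#' @param N Genome size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, in `(0, 1]`.
#' @export
hypergeometric_enrichment <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment over a background incidence
#'
#' @param k Class members in the set.
#' @param n Set size (> 0).
#' @param background_fraction Genome-wide incidence of the class (> 0).
#' @return `(k/n) / background_fraction`.
#' @export
fold_enrichment <- function(k, n, background_fraction) {
  if (n <= 0) stop("`n` must be positive")
  if (background_fraction <= 0) stop("`background_fraction` must be positive")
  (k / n) / background_fraction
}

#' Gene set constructor
#'
#' @param name Set name.
#' @param members Character vector of gene IDs (deduplicated).
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  structure(list(name = name, members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Overlap arithmetic between two regulon gene sets
#'
#' @param a,b `gene_set`s (or plain character vectors).
#' @return List with `n_a`, `n_b`, `n_intersection`, `n_union`
#'   (`n_union = n_a + n_b - n_intersection`).
#' @export
regulon_overlap <- function(a, b) {
  ma <- if (inherits(a, "gene_set")) a$members else unique(as.character(a))
  mb <- if (inherits(b, "gene_set")) b$members else unique(as.character(b))
  ni <- length(intersect(ma, mb))
  list(n_a = length(ma), n_b = length(mb), n_intersection = ni,
       n_union = length(ma) + length(mb) - ni)
}

#' Class membership count and percentage within a gene set
#'
#' @param set A `gene_set` (or character vector of gene IDs).
#' @param annotations Data frame with columns `gene_id`, `class`; set members
#'   absent from it count as `"unclassified"`.
#' @param class Class label to count.
#' @return List with `k` (members in class), `n` (set size) and `percent`
#'   (`100 k/n` rounded to the nearest integer).
#' @export
class_percentages <- function(set, annotations, class) {
  members <- if (inherits(set, "gene_set")) set$members else unique(as.character(set))
  n <- length(members)
  if (n == 0L) stop("empty gene set")
  cls <- annotations$class[match(members, annotations$gene_id)]
  cls[is.na(cls)] <- "unclassified"
  k <- sum(cls == class)
  list(k = k, n = n, percent = round(100 * k / n))
}

#' Functional-class enrichment report for a gene set
#'
#' One hypergeometric upper-tail test per class present in the annotation
#' universe, with fold enrichment against the genome-wide class incidence.
#' No multiple-testing correction is applied by default (set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted p-values in an extra
#' column).
#'
#' @param set A `gene_set` (or character vector).
#' @param annotations Data frame `gene_id`, `class` covering the genome.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `class`, `k`, `n`, `K`, `N`, `fold`, `p_value`
#'   (and `p_adjusted` when requested), sorted by `p_value`.
#' @export
enrichment_report <- function(set, annotations, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  members <- if (inherits(set, "gene_set")) set$members else unique(as.character(set))
  N <- nrow(annotations)
  n <- sum(members %in% annotations$gene_id)
  if (n == 0L) stop("no set member found in the annotation table")
  in_set <- annotations$gene_id %in% members
  classes <- sort(unique(annotations$class))
  rows <- lapply(classes, function(cl) {
    K <- sum(annotations$class == cl)
    k <- sum(in_set & annotations$class == cl)
    data.frame(class = cl, k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K / N),
               p_value = hypergeometric_enrichment(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
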