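# Shared fixture builders for the suite; everything is generated in code.

linear_profile <- function(values, times = seq_along(values), id = "g") {
  expression_profile(id, times, values, scale = "linear")
}

log2_profile <- function(values, times = seq_along(values), id = "g") {
  expression_profile(id, times, values, scale = "log2")
}

# Symmetric GC-rich background matching the default simulation regime.
gc_background <- function(gc = 0.72) {
  c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
}

# Random i.i.d. background sequences under a symmetric background.
random_sequences <- function(n, len, gc = 0.72, seed = 1) {
  set.seed(seed)
  bg <- gc_background(gc)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = bg),
          collapse = "")
  }, character(1))
  names(out) <- sprintf("s%04d", seq_len(n))
  out
}

# Brute-force upper-tail p-values for a small-width PWM: enumerate all 4^w
# words under the background. Used as the oracle for the DP table.
brute_force_pvalues <- function(int_scores, background, scores) {
  w <- nrow(int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  word_scores <- apply(words, 1, function(wd) sum(int_scores[cbind(1:w, wd)]))
  word_probs <- apply(words, 1, function(wd) prod(background[wd]))
  vapply(scores, function(s) sum(word_probs[word_scores >= s]), numeric(1))
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size n
# from a genome of size N (N small).
enumerate_hypergeom_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  in_class <- seq_len(K)  # first K genes form the class
  hits <- apply(draws, 2, function(d) sum(d %in% in_class))
  mean(hits >= k)
}
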