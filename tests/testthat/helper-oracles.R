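# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: k-mer positions come from regex lookahead
# matching, tail probabilities from direct log-space summation, and the
# hypergeometric tail from explicit sums of binomial coefficients.

# Brute-force FT detection: try every |alphabet|^k candidate k-mer by
# overlapping regex search over the whole sequence.
oracle_fts <- function(seq, alphabet, n = 5L, k = 3L) {
  cands <- do.call(paste0, expand.grid(rep(list(alphabet), k),
                                       stringsAsFactors = FALSE))
  hits <- lapply(cands, function(w) {
    m <- gregexpr(paste0("(?=", w, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  })
  names(hits) <- cands
  hits[vapply(hits, length, integer(1)) >= n]
}

# RP numerator by explicit enumeration of consecutive occurrence pairs.
oracle_rp_numerator <- function(ft_positions, mfi) {
  total <- 0L
  for (pos in ft_positions) {
    if (length(pos) < 2L) next
    for (i in seq_len(length(pos) - 1L))
      if (pos[i + 1L] - pos[i] == mfi) total <- total + 1L
  }
  total
}

# Binomial upper tail P(X >= n) by log-space term summation.
oracle_binom_tail <- function(W, p, n) {
  m <- n:W
  sum(exp(lchoose(W, m) + m * log(p) + (W - m) * log1p(-p)))
}

# Hypergeometric upper tail P(X >= q) for q successes in a sample of n from
# a population of N with K successes, by direct enumeration.
oracle_hyper_tail <- function(q, K, N, n) {
  ks <- q:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# A random protein over a reduced alphabet (dense in repeats, so FTs occur).
random_seq <- function(L, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# Repeat units whose k-mers are all distinct within one unit (so a pure
# tandem repeat has every constituent triplet recurring exactly at the unit
# length). Checked at load time.
UNIT3 <- "SGE"
UNIT13 <- "ADEFGHIKLNPQR"
UNIT28 <- "ACDEFGHIKLMNPQRSTVWYAGCEHDKI"
stopifnot(vapply(c(UNIT3, UNIT13, UNIT28), function(u) {
  circ <- paste0(u, substr(u, 1, 2))
  w <- substring(circ, 1:nchar(u), 3:(nchar(u) + 2))
  !anyDuplicated(w)
}, logical(1)))
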