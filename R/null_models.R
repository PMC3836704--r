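## Bernoulli/binomial null model for FT misidentification and random-protein
## generators for its Monte-Carlo validation.

#' Null model specification
#'
#' Parameters of the random-sequence model used for the analytic FT
#' expectation and for simulation. Under the uniform model every letter has
#' probability 1/20 and every triplet probability 1/8000 per window; under
#' the unigram model letters are drawn i.i.d. from supplied first-order
#' (single amino-acid) frequencies, e.g. estimated from a reference proteome.
#'
#' @param model \code{"uniform"} or \code{"unigram"}.
#' @param aa_probs Named numeric vector of length 20 over
#'   \code{\link{CANONICAL_AA}} summing to 1. Required for the unigram model;
#'   ignored (set to 1/20 each) for the uniform model.
#' @return Object of class \code{null_model_spec} with elements \code{model},
#'   \code{aa_probs} and \code{p_triplet} (the 8000-vector of per-window
#'   triplet probabilities; all equal to 1/8000 under the uniform model).
#' @export
null_model_spec <- function(model = c("uniform", "unigram"), aa_probs = NULL) {
  model <- match.arg(model)
  if (model == "uniform") {
    aa_probs <- stats::setNames(rep(1 / 20, 20), CANONICAL_AA)
  } else {
    if (is.null(aa_probs)) stop("the unigram model requires aa_probs")
    if (is.null(names(aa_probs)) || !setequal(names(aa_probs), CANONICAL_AA))
      stop("aa_probs must be named by the 20 canonical amino acids")
    aa_probs <- aa_probs[CANONICAL_AA]
    if (any(aa_probs < 0) || abs(sum(aa_probs) - 1) > 1e-8)
      stop("aa_probs must be nonnegative and sum to 1")
  }
  p_triplet <- as.vector(outer(as.vector(outer(aa_probs, aa_probs)), aa_probs))
  structure(list(model = model, aa_probs = aa_probs, p_triplet = p_triplet),
            class = "null_model_spec")
}

#' Estimate unigram amino-acid frequencies from proteins
#'
#' @param proteins List of \code{protein_record}s.
#' @return Named probability vector over \code{\link{CANONICAL_AA}}, suitable
#'   for \code{\link{null_model_spec}(model = "unigram")}. Non-canonical
#'   letters are ignored.
#' @export
aa_frequencies <- function(proteins) {
  letters <- unlist(strsplit(vapply(proteins, `[[`, character(1), "seq"), ""),
                    use.names = FALSE)
  letters <- letters[letters %in% CANONICAL_AA]
  if (!length(letters)) stop("no canonical residues in the supplied proteins")
  tb <- table(factor(letters, levels = CANONICAL_AA))
  stats::setNames(as.numeric(tb) / sum(tb), CANONICAL_AA)
}

#' Expected number of misidentified FTs in a random protein
#'
#' Analytic expectation of the number of different k-mers (k = 3) appearing
#' at least \code{n} times in an i.i.d. random sequence of length \code{L}:
#' each of the 8000 triplets t recurs as Binomial(W, p_t) over the W = L - 2
#' windows (overlapping windows treated as independent trials, the standard
#' approximation whose error the simulation quantifies), so
#' E = sum_t P(X_t >= n). Under the uniform model this collapses to
#' 8000 P(X >= n) with p = 1/8000. E/8000 is the per-triplet P-value for FT
#' misidentification.
#'
#' @param L Integer vector of sequence lengths.
#' @param n FT occurrence threshold.
#' @param spec A \code{\link{null_model_spec}}.
#' @return Numeric vector of expectations, 0 where \code{L < 3}.
#' @examples
#' expected_ft_count(c(1000, 8000, 20000))
#' @export
expected_ft_count <- function(L, n = 5L, spec = null_model_spec()) {
  stopifnot(inherits(spec, "null_model_spec"), n >= 1L)
  vapply(as.integer(L), function(l) {
    if (l < 3L) return(0)
    W <- l - 2L
    sum(stats::pbinom(n - 1L, W, spec$p_triplet, lower.tail = FALSE))
  }, numeric(1))
}

#' Analytic FT expectation curve
#'
#' @param lengths Grid of sequence lengths.
#' @param n FT occurrence threshold.
#' @param spec A \code{\link{null_model_spec}}.
#' @return Data.frame with columns \code{L}, \code{expected} and
#'   \code{pvalue} (\code{expected/8000}, the FT misidentification P-value).
#' @export
expectation_curve <- function(lengths, n = 5L, spec = null_model_spec()) {
  e <- expected_ft_count(lengths, n, spec)
  data.frame(L = as.integer(lengths), expected = e, pvalue = e / 8000)
}

#' Generate a random protein
#'
#' I.i.d. letters from the null model's amino-acid distribution. Seed the
#' session RNG (\code{set.seed}) for reproducibility.
#'
#' @param L Sequence length.
#' @param spec A \code{\link{null_model_spec}}.
#' @param id Identifier for the generated record.
#' @return A \code{protein_record}.
#' @export
generate_random_protein <- function(L, spec = null_model_spec(),
                                    id = "random") {
  stopifnot(L >= 1L)
  protein_record(id, paste(sample(CANONICAL_AA, L, replace = TRUE,
                                  prob = spec$aa_probs), collapse = ""))
}

#' Monte-Carlo validation of the FT expectation curve
#'
#' Simulates random proteins on a length grid, applies the full FT detection
#' pipeline, and compares the empirical mean FT count per length against the
#' analytic expectation. Supports the restrictive definition via
#' \code{params$M} (the analytic column then still refers to the regular
#' definition, which upper-bounds it).
#'
#' @param lengths Grid of sequence lengths.
#' @param reps Replicates per grid point.
#' @param spec A \code{\link{null_model_spec}}.
#' @param params An \code{\link{ft_params}}; its \code{n} is used for the
#'   analytic curve.
#' @return Data.frame with columns \code{L}, \code{E_analytic},
#'   \code{pvalue}, \code{E_empirical} and \code{SE} (standard error of the
#'   empirical mean).
#' @export
simulate_ft_expectation <- function(lengths, reps = 200L,
                                    spec = null_model_spec(),
                                    params = ft_params()) {
  stopifnot(reps >= 1L)
  out <- lapply(as.integer(lengths), function(L) {
    cnt <- vapply(seq_len(reps), function(i) {
      length(detect_fts(generate_random_protein(L, spec), params)$ft)
    }, numeric(1))
    data.frame(L = L,
               E_analytic = expected_ft_count(L, params$n, spec),
               pvalue = expected_ft_count(L, params$n, spec) / 8000,
               E_empirical = mean(cnt),
               SE = stats::sd(cnt) / sqrt(reps))
  })
  do.call(rbind, out)
}
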