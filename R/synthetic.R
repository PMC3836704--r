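## Synthetic data: bundled worked-example fixtures, planted-motif proteins
## and proteome generators with controllable statistical structure, so that
## every analysis operation is testable without external downloads.

TABLE1_LENGTHS <- c(A4 = 770L, LORI = 312L, CAMKV = 501L, COLQ = 455L,
                    ASPX = 265L, PRDM9 = 894L)
TABLE1_MD5 <- "3b35afdac426485a01415a5aa4683014"

#' Bundled example proteins
#'
#' Six annotated human proteins spanning the spectrum of compositional
#' order: amyloid beta A4 (scattered acidic runs), loricrin/keratin
#' (glycine-serine runs, high coverage), CAMKV (repeated 8-mer motif), COLQ
#' collagen (degraded PGP periodicity), an ASPX developmental protein
#' (repeated SGE-bearing motif) and the zinc-finger PRDM9 (28-residue pure
#' tandem motif). The bundled FASTA is integrity-checked by length and
#' digest on every load.
#'
#' @return Named list of six \code{protein_record}s.
#' @export
table1_fixtures <- function() {
  path <- system.file("extdata", "table1_examples.fasta", package = "coft",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE1_MD5))
    stop("bundled fixture file is corrupted (digest mismatch)")
  recs <- read_fasta(path)
  got <- vapply(recs, `[[`, integer(1), "L")
  if (!identical(got[names(TABLE1_LENGTHS)], TABLE1_LENGTHS))
    stop("bundled fixture lengths do not match their reference values")
  recs[names(TABLE1_LENGTHS)]
}

#' Generate a protein with a planted repeated motif
#'
#' Concatenates \code{repeats} copies of \code{motif}, substituting each
#' repeat position independently with probability \code{impurity_rate}
#' (substitutions drawn uniformly from the other 19 canonical letters), and
#' pads both sides with i.i.d. uniform random residues. The ground truth
#' (motif, unit length, repeat count, 0-based repeat-region coordinates) is
#' returned alongside for recovery tests.
#'
#' @param motif Amino-acid string (canonical letters), the repeat unit.
#' @param repeats Number of copies (>= 1).
#' @param impurity_rate Per-position substitution probability in [0, 1).
#' @param flank_lengths Integer length-2 vector, random padding before and
#'   after the repeat region.
#' @param seed Optional integer seed.
#' @return List with \code{protein} (a \code{protein_record}) and
#'   \code{truth} (list: motif, m, repeats, impurity_rate, start, end).
#' @examples
#' plant_motif("TPATDGSA", repeats = 6, seed = 1)$protein
#' @export
plant_motif <- function(motif, repeats, impurity_rate = 0,
                        flank_lengths = c(0L, 0L), seed = NULL) {
  motif <- toupper(motif)
  stopifnot(nchar(motif) >= 1L, repeats >= 1L,
            impurity_rate >= 0, impurity_rate < 1,
            length(flank_lengths) == 2L, all(flank_lengths >= 0L))
  if (grepl(NON_CANONICAL_RE, motif))
    stop("motif must use canonical amino-acid letters")
  if (!is.null(seed)) set.seed(seed)
  unit <- strsplit(motif, "")[[1]]
  m <- length(unit)
  body <- rep(unit, repeats)
  if (impurity_rate > 0) {
    mut <- which(stats::runif(length(body)) < impurity_rate)
    for (i in mut)
      body[i] <- sample(setdiff(CANONICAL_AA, body[i]), 1L)
  }
  left <- sample(CANONICAL_AA, flank_lengths[1L], replace = TRUE)
  right <- sample(CANONICAL_AA, flank_lengths[2L], replace = TRUE)
  seq <- paste(c(left, body, right), collapse = "")
  id <- sprintf("planted_%s_x%d", motif, repeats)
  list(protein = protein_record(id, seq),
       truth = list(motif = motif, m = m, repeats = repeats,
                    impurity_rate = impurity_rate,
                    start = flank_lengths[1L],
                    end = flank_lengths[1L] + m * repeats - 1L))
}

#' Generate a synthetic proteome with known ground truth
#'
#' Protein lengths are drawn from a log-normal distribution (the
#' characteristic shape of real proteome length distributions; the defaults
#' give a median around 375 residues, truncated to
#' \code{[min_length, max_length]}). A fraction of proteins receives a
#' planted repeated motif drawn from \code{motif_pool}, replacing a central
#' stretch of the random background; the rest are pure i.i.d. background
#' from \code{null_spec}. Optionally, an annotation term is planted with a
#' logistic dependence on the protein's relative coverage, providing ground
#' truth for enrichment-sweep recovery.
#'
#' @param n_proteins Number of proteins.
#' @param length_meanlog,length_sdlog Log-normal length parameters (defaults
#'   \code{log(375)} and 0.9).
#' @param min_length,max_length Truncation bounds for lengths (50 and 2000).
#' @param planted_fraction Fraction of proteins receiving a motif (default 0).
#' @param motif_pool Character vector of repeat units (default a mixture of
#'   run, short-motif and long-motif units).
#' @param repeats Repeat count for planted motifs (default 10).
#' @param impurity_rate Substitution rate inside planted repeats (default 0).
#' @param enrichment Optional list \code{list(term =, log_odds =, base_rate =)}:
#'   each protein is annotated with \code{term} with probability
#'   \code{plogis(qlogis(base_rate) + log_odds * z)} where z is the
#'   standardized relative coverage, yielding a planted RC-dependent
#'   enrichment of known effect size.
#' @param null_spec Background letter distribution
#'   (\code{\link{null_model_spec}}).
#' @param seed Optional integer seed; fixed seed gives a byte-identical
#'   proteome.
#' @return List with \code{proteins} (list of \code{protein_record}),
#'   \code{ledger} (data.frame: id, L, planted, motif, repeats, start plus
#'   annotation columns when enrichment is planted) and \code{annotations}
#'   (named character vector, or NULL).
#' @export
generate_proteome <- function(n_proteins,
                              length_meanlog = log(375), length_sdlog = 0.9,
                              min_length = 50L, max_length = 2000L,
                              planted_fraction = 0,
                              motif_pool = c("A", "Q", "SGE", "PGP",
                                             "TPATDGSA",
                                             "HQRTHTGEKPYVCRECGRGFS"),
                              repeats = 10L, impurity_rate = 0,
                              enrichment = NULL,
                              null_spec = null_model_spec(),
                              seed = NULL) {
  stopifnot(n_proteins >= 1L, planted_fraction >= 0, planted_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- pmin(pmax(round(stats::rlnorm(n_proteins, length_meanlog,
                                     length_sdlog)), min_length), max_length)
  planted <- stats::runif(n_proteins) < planted_fraction
  motifs <- rep(NA_character_, n_proteins)
  starts <- rep(NA_integer_, n_proteins)
  proteins <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    id <- sprintf("syn%04d", i)
    base <- sample(CANONICAL_AA, L[i], replace = TRUE,
                   prob = null_spec$aa_probs)
    if (planted[i]) {
      motif <- sample(motif_pool, 1L)
      unit <- strsplit(motif, "")[[1]]
      body <- rep(unit, repeats)
      if (impurity_rate > 0) {
        mut <- which(stats::runif(length(body)) < impurity_rate)
        for (j in mut)
          body[j] <- sample(setdiff(CANONICAL_AA, body[j]), 1L)
      }
      if (length(body) > L[i]) {  # motif longer than the protein: extend it
        L[i] <- length(body) + 20L
        base <- sample(CANONICAL_AA, L[i], replace = TRUE,
                       prob = null_spec$aa_probs)
      }
      s <- sample.int(L[i] - length(body) + 1L, 1L)
      base[s:(s + length(body) - 1L)] <- body
      motifs[i] <- motif
      starts[i] <- s - 1L
    }
    proteins[[i]] <- protein_record(id, paste(base, collapse = ""))
  }
  ledger <- data.frame(id = vapply(proteins, `[[`, character(1), "id"),
                       L = L, planted = planted, motif = motifs,
                       repeats = ifelse(planted, repeats, NA_integer_),
                       start = starts, stringsAsFactors = FALSE)
  annotations <- NULL
  if (!is.null(enrichment)) {
    stopifnot(all(c("term", "log_odds", "base_rate") %in% names(enrichment)))
    rc <- vapply(proteins, function(p) relative_coverage(detect_fts(p)),
                 numeric(1))
    z <- if (stats::sd(rc) > 0) (rc - mean(rc)) / stats::sd(rc) else rc * 0
    pr <- stats::plogis(stats::qlogis(enrichment$base_rate) +
                          enrichment$log_odds * z)
    has_term <- stats::runif(n_proteins) < pr
    annotations <- stats::setNames(
      ifelse(has_term, paste("synthetic protein;", enrichment$term),
             "synthetic protein"), ledger$id)
    ledger$term_planted <- has_term
    ledger$rc <- rc
  }
  list(proteins = proteins, ledger = ledger, annotations = annotations)
}
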