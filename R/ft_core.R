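## Core frequent-triplet (FT) machinery: overlapping k-mer scanning and FT
## assignment under the regular and the restrictive (windowed) definitions.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes. Windows containing any other
#' letter (X, B, Z, U, O, *, ...) are never eligible as FT occurrences: the
#' Bernoulli null model underlying FT significance assumes a 20-letter
#' alphabet with 8000 possible triplets.
#'
#' @format Character vector of length 20.
#' @export
CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein record
#'
#' A minimal container for one named amino-acid sequence, the unit on which
#' FTs are scanned. Sequences are uppercased on construction. Letters outside
#' the canonical 20-letter alphabet are tolerated (they occur in real
#' databases as X, B, Z, U, O or *) but any k-mer window containing one is
#' ineligible as an FT occurrence.
#'
#' @param id Character scalar, protein identifier.
#' @param seq Character scalar, amino-acid sequence (any case).
#' @return An object of class \code{protein_record}: a list with elements
#'   \code{id}, \code{seq} (uppercase) and \code{L} (sequence length).
#' @examples
#' p <- protein_record("run", "AAAAAAA")
#' p$L
#' @export
protein_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 1L) stop("empty sequence for protein '", id, "'")
  if (grepl("[^A-Z*]", seq))
    stop("protein '", id, "' contains characters that are not letters or '*'")
  structure(list(id = id, seq = seq, L = L), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (L = %d)\n", x$id, x$L))
  invisible(x)
}

## Accept either a protein_record or a bare string (convenience in scripts
## and tests); always returns a protein_record.
as_protein_record <- function(x, id = "protein") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record(id, x))
  stop("expected a protein_record or a single character string")
}

#' FT detection parameters
#'
#' @param n Minimum occurrence count for FT assignment. Default 5, the
#'   threshold at which random triplet recurrence is negligible for proteins
#'   of ordinary length (see \code{\link{expected_ft_count}}).
#' @param M Optional window length for the restrictive definition: an FT must
#'   then have at least \code{n} occurrences falling inside some stretch of
#'   \code{M} consecutive residues. \code{NULL} (default) selects the regular
#'   definition. The conventional restrictive setting is \code{M = 2000}.
#' @param k Word length. Default 3 (amino-acid triplets); configurable for
#'   sensitivity analyses.
#' @return An object of class \code{ft_params}.
#' @export
ft_params <- function(n = 5L, M = NULL, k = 3L) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (!is.null(M)) {
    M <- as.integer(M)
    if (is.na(M) || M < k) stop("M must be an integer >= k")
  }
  structure(list(n = n, M = M, k = k), class = "ft_params")
}

#' @export
print.ft_params <- function(x, ...) {
  cat(sprintf("<ft_params> n = %d, k = %d, %s\n", x$n, x$k,
              if (is.null(x$M)) "regular" else sprintf("restrictive (M = %d)", x$M)))
  invisible(x)
}

#' Scan all overlapping k-mers of a protein
#'
#' Enumerates every k-long window of the sequence and returns, for each
#' distinct k-mer composed solely of canonical amino-acid letters, the ordered
#' list of all its overlapping start positions (0-based). Windows containing a
#' non-canonical letter are skipped.
#'
#' @param protein A \code{protein_record} (or a bare sequence string).
#' @param k Word length; must satisfy \code{k <= L}.
#' @return Named list mapping each observed k-mer to a strictly increasing
#'   integer vector of 0-based start positions. Empty list when \code{k > L}.
#' @examples
#' scan_kmers(protein_record("run", "AAAAAAA"), 3)  # AAA at 0..4
#' @export
scan_kmers <- function(protein, k = 3L) {
  p <- as_protein_record(protein)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > p$L) return(structure(list(), names = character(0)))
  W <- p$L - k + 1L
  wins <- substring(p$seq, 1:W, k:p$L)
  ok <- !grepl(NON_CANONICAL_RE, wins)
  if (!any(ok)) return(structure(list(), names = character(0)))
  pos <- split((0:(W - 1L))[ok], wins[ok])
  lapply(pos, as.integer)
}

NON_CANONICAL_RE <- "[^ACDEFGHIKLMNPQRSTVWY]"

## Sliding-window criterion of the restrictive definition: some n consecutive
## occurrences (sorted start positions) span at most M residues, spans being
## measured from the first covered locus to the last (pos[i+n-1] + k - pos[i]).
restrictive_ok <- function(pos, n, M, k) {
  m <- length(pos)
  if (m < n) return(FALSE)
  any(pos[n:m] - pos[1:(m - n + 1L)] + k <= M)
}

#' Detect frequent triplets (FTs) in a protein
#'
#' An FT is a k-mer occurring at least \code{n} times in the protein, counted
#' at every start position including overlapping ones (so AAAAAAA holds 5
#' occurrences of AAA). Under the restrictive definition (\code{M} set), the
#' \code{n} occurrences must additionally fall within some window of \code{M}
#' consecutive residues. Position lists of a kept k-mer always retain all of
#' its occurrences, not only those inside a qualifying window.
#'
#' @param protein A \code{protein_record} (or a bare sequence string).
#' @param params An \code{\link{ft_params}} object.
#' @return An object of class \code{ft_profile}: list with \code{protein_id},
#'   \code{L}, \code{params} and \code{ft} (named list mapping each FT to its
#'   0-based occurrence positions).
#' @examples
#' detect_fts(protein_record("rpt", "AQAQAQAQAQAQ"))  # AQA and QAQ, 5 each
#' @export
detect_fts <- function(protein, params = ft_params()) {
  p <- as_protein_record(protein)
  stopifnot(inherits(params, "ft_params"))
  km <- scan_kmers(p, params$k)
  keep <- vapply(km, length, integer(1)) >= params$n
  ft <- km[keep]
  if (!is.null(params$M)) {
    ok <- vapply(ft, restrictive_ok, logical(1),
                 n = params$n, M = params$M, k = params$k)
    ft <- ft[ok]
  }
  structure(list(protein_id = p$id, L = p$L, params = params, ft = ft),
            class = "ft_profile")
}

#' @export
print.ft_profile <- function(x, ...) {
  cat(sprintf("<ft_profile> %s (L = %d): %d FT%s\n", x$protein_id, x$L,
              length(x$ft), if (length(x$ft) == 1L) "" else "s"))
  if (length(x$ft)) {
    cnt <- sort(vapply(x$ft, length, integer(1)), decreasing = TRUE)
    show <- utils::head(cnt, 10L)
    cat("  ", paste(sprintf("%s:%d", names(show), show), collapse = " "), "\n")
  }
  invisible(x)
}

#' Is a protein compositionally ordered?
#'
#' A protein is CO iff its FT profile contains at least one FT; otherwise it
#' is NO (non-ordered).
#'
#' @param profile An \code{ft_profile}.
#' @return Logical scalar.
#' @export
is_co <- function(profile) {
  stopifnot(inherits(profile, "ft_profile"))
  length(profile$ft) >= 1L
}

#' Export FT profiles as TSV
#'
#' One row per (protein, FT): protein id, FT, occurrence count and the
#' comma-joined 0-based occurrence positions.
#'
#' @param profiles An \code{ft_profile} or list of them.
#' @param path Output file path.
#' @return Invisibly, the exported data.frame.
#' @export
write_ft_profiles <- function(profiles, path) {
  if (inherits(profiles, "ft_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(pr) {
    if (!length(pr$ft)) return(NULL)
    data.frame(protein_id = pr$protein_id,
               ft = names(pr$ft),
               count = vapply(pr$ft, length, integer(1)),
               positions = vapply(pr$ft, paste, character(1), collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(protein_id = character(0), ft = character(0),
                       count = integer(0), positions = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
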