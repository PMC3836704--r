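## FASTA input/output and the analysis driver behind the command-line
## interface. Parsing of FASTA is delegated to Biostrings; records are
## uppercased and duplicate ids are disambiguated.

#' Read proteins from a FASTA file
#'
#' Multi-record FASTA; the description line up to the first whitespace is the
#' id. Sequences are uppercased. Duplicate ids are disambiguated with a
#' \code{.2}, \code{.3}, ... suffix and a message.
#'
#' @param path File path.
#' @return List of \code{protein_record}s, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (!length(set)) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- duplicated(ids)
  if (any(dup)) {
    message("disambiguating ", sum(dup), " duplicate id(s) in ", path)
    ids <- make.unique(ids, sep = ".")
  }
  mapply(function(id, s) protein_record(id, s),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write proteins to a FASTA file
#'
#' @param proteins List of \code{protein_record}s.
#' @param path Output file path.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, character(1), "seq"))
  names(seqs) <- vapply(proteins, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Analyze a proteome end to end and write text outputs
#'
#' The driver behind the \code{analyze} CLI subcommand: classifies every
#' protein, builds the proteome vocabulary, and writes plain-text outputs to
#' \code{out_dir}: \code{co_profiles.tsv} (one row per protein),
#' \code{vocabulary.tsv} (FT, carrier count, homo-run flag) and
#' \code{config.tsv} (the echoed run configuration, making the run
#' reproducible).
#'
#' @param input Path to a FASTA file, or a list of \code{protein_record}s.
#' @param out_dir Output directory (created if missing).
#' @param params An \code{\link{ft_params}}.
#' @param periodicity_threshold Minimum MFI support for the periodic flag.
#' @param seed Optional integer seed, echoed into the config (the analysis
#'   itself is deterministic).
#' @return Invisibly, a list with \code{co_table} and \code{vocabulary}.
#' @export
run_analysis <- function(input, out_dir, params = ft_params(),
                         periodicity_threshold = 4L, seed = NULL) {
  proteins <- if (is.character(input)) read_fasta(input) else input
  if (!length(proteins)) stop("empty proteome")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  co <- classify_proteome(proteins, params = params,
                          periodicity_threshold = periodicity_threshold)
  profiles <- lapply(attr(co, "profiles"), `[[`, "profile")
  vocab <- build_vocabulary(profiles,
                            source_id = if (is.character(input))
                              basename(input) else "proteome")
  write_co_table(co, file.path(out_dir, "co_profiles.tsv"))
  write_vocabulary(vocab, file.path(out_dir, "vocabulary.tsv"))
  cfg <- data.frame(
    key = c("input", "n", "k", "M", "periodicity_threshold", "seed",
            "n_proteins", "n_co"),
    value = c(if (is.character(input)) input else "<in-memory>",
              params$n, params$k,
              if (is.null(params$M)) "regular" else params$M,
              periodicity_threshold,
              if (is.null(seed)) "none" else seed,
              length(proteins), sum(co$is_co)),
    stringsAsFactors = FALSE)
  utils::write.table(cfg, file.path(out_dir, "config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(co_table = co, vocabulary = vocab))
}
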