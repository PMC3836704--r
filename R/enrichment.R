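## Threshold-sweep functional enrichment over compositional-order measures,
## with hypergeometric significance. Annotation matching is literal
## case-insensitive text search in user-supplied free-text terms, not
## ontology-graph reasoning.

#' Read a protein annotation table
#'
#' Two-column tab-separated file: protein id, free-text annotation. Multiple
#' rows per id are concatenated.
#'
#' @param path File path.
#' @return Named character vector (id -> annotation text).
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                          col.names = c("id", "text"),
                          colClasses = "character")
  if (!nrow(df)) stop("empty annotation file: ", path)
  tapply(df$text, df$id, paste, collapse = " ")
}

#' Run-length measure of an FT profile
#'
#' Total number of FT recurrences at interval 1, i.e. pooled
#' consecutive-occurrence gaps equal to 1. This is the effective coverage of
#' amino-acid runs and the natural sweep variable for run-length enrichment.
#'
#' @param profile An \code{ft_profile}.
#' @return Integer count of unit gaps.
#' @examples
#' run_length_measure(detect_fts("AAAAAAA"))  # 5 occurrences -> 4 unit gaps
#' @export
run_length_measure <- function(profile) {
  stopifnot(inherits(profile, "ft_profile"))
  sum(interval_distribution(profile)$pooled == 1L)
}

#' Threshold-sweep enrichment of an annotation term over an order measure
#'
#' For each threshold t of the sweep, N_tot(t) counts CO proteins whose
#' measure exceeds t (strict \code{>}), and N_fun(t) those whose annotation
#' contains the term (case-insensitive substring). The ratio N_fun/N_tot
#' versus t is the enrichment pattern. Significance is a one-sided upper
#' hypergeometric P-value comparing the counts at the ratio-maximizing
#' admissible threshold against the population at the minimal threshold;
#' admissible thresholds require N_fun(t) > 15 and N_fun(t) at least 10% of
#' N_fun at the minimal threshold, guarding against small-number artifacts.
#'
#' @param co_table Data.frame from \code{\link{classify_proteome}}; only CO
#'   rows enter the sweep.
#' @param annotations Named character vector (id -> annotation text).
#' @param term Search term (non-empty).
#' @param measure Column of \code{co_table} to threshold (\code{"rc"},
#'   \code{"rp"}, \code{"mfi_support"}, \code{"run_length"}, ...). A
#'   \code{"run_length"} column can be added by the caller from
#'   \code{\link{run_length_measure}}.
#' @param thresholds Ascending numeric grid; default the deciles of the
#'   measure's empirical distribution over CO proteins (starting at the
#'   minimum, so the first point covers the whole CO set).
#' @return Object of class \code{enrichment_curve}: list with \code{term},
#'   \code{measure}, \code{curve} (data.frame threshold, n_tot, n_fun,
#'   ratio), \code{best_threshold}, \code{pvalue} and \code{reason}
#'   (\code{NA} when a P-value was computed, otherwise why not).
#' @export
enrichment_sweep <- function(co_table, annotations, term,
                             measure = "rc", thresholds = NULL) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  co <- co_table[co_table$is_co, , drop = FALSE]
  if (!nrow(co)) stop("no CO proteins in the table")
  if (!measure %in% names(co)) stop("unknown measure column: ", measure)
  vals <- co[[measure]]
  unmatched <- setdiff(co$id, names(annotations))
  if (length(unmatched))
    message(length(unmatched), " CO protein id(s) missing from annotations")
  txt <- annotations[co$id]
  txt[is.na(txt)] <- ""
  hit <- grepl(term, txt, ignore.case = TRUE, fixed = FALSE)
  if (is.null(thresholds)) {
    qs <- stats::quantile(vals, probs = seq(0, 0.9, by = 0.1), names = FALSE)
    thresholds <- unique(qs)
    # sweep is strict ">": shift the first point below the minimum so the
    # first row covers the entire CO set
    thresholds[1L] <- min(vals) - 1e-9
  }
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  n_tot <- vapply(thresholds, function(t) sum(vals > t), integer(1))
  n_fun <- vapply(thresholds, function(t) sum(hit & vals > t), integer(1))
  ratio <- ifelse(n_tot > 0L, n_fun / n_tot, NA_real_)
  curve <- data.frame(threshold = thresholds, n_tot = n_tot, n_fun = n_fun,
                      ratio = ratio)
  N <- n_tot[1L]; K <- n_fun[1L]
  admissible <- n_fun > 15L & n_fun >= 0.1 * K & n_tot > 0L
  res <- list(term = term, measure = measure, curve = curve,
              best_threshold = NA_real_, pvalue = NA_real_,
              reason = NA_character_)
  if (!any(admissible)) {
    res$reason <- "no admissible threshold (N_fun constraints unmet)"
  } else {
    best <- which(admissible)[which.max(ratio[admissible])]
    res$best_threshold <- thresholds[best]
    # population: CO set at the minimal threshold; successes: term matches
    # there; sample: proteins above the chosen threshold; upper tail
    res$pvalue <- stats::phyper(n_fun[best] - 1L, K, N - K, n_tot[best],
                                lower.tail = FALSE)
  }
  structure(res, class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("<enrichment_curve> '%s' over %s: ", x$term, x$measure))
  if (is.na(x$pvalue)) cat(x$reason, "\n") else
    cat(sprintf("P = %.3g at threshold %.4g\n", x$pvalue, x$best_threshold))
  invisible(x)
}

#' Export an enrichment curve as TSV
#'
#' The per-threshold curve followed by a commented summary row.
#'
#' @param ec An \code{enrichment_curve}.
#' @param path Output file path.
#' @export
write_enrichment_curve <- function(ec, path) {
  utils::write.table(ec$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary_line <- sprintf("# term=%s measure=%s best_threshold=%s pvalue=%s",
                          ec$term, ec$measure,
                          format(ec$best_threshold), format(ec$pvalue))
  cat(summary_line, "\n", file = path, append = TRUE)
  invisible(ec)
}
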