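## Proteome-level FT-vocabulary analysis: DFT sets and carrier counts,
## Jaccard similarity between vocabularies, predominant-FT ranking,
## abundance distributions and the power-law regressions underlying the
## universal length dependence of the order measures.

#' Build the FT vocabulary of a proteome
#'
#' The proteome DFT set is the union of the per-protein FT sets; the carrier
#' count of an FT is the number of CO proteins containing it. Vocabulary size
#' is insensitive to protein duplication (two identical proteins contribute
#' the same FTs).
#'
#' @param proteins List of \code{protein_record}s, or a list of precomputed
#'   \code{ft_profile}s.
#' @param params An \code{\link{ft_params}} (ignored when profiles are given).
#' @param source_id Label for the proteome.
#' @return Object of class \code{proteome_vocabulary}: list with
#'   \code{source_id}, \code{dft_set} (sorted character vector),
#'   \code{carrier_counts} (named integer vector over \code{dft_set}),
#'   \code{dft_per_protein} (named integer vector of per-protein DFT counts),
#'   \code{n_proteins} and \code{n_co}.
#' @export
build_vocabulary <- function(proteins, params = ft_params(),
                             source_id = "proteome") {
  stopifnot(length(proteins) >= 1L)
  profiles <- lapply(proteins, function(p) {
    if (inherits(p, "ft_profile")) p else detect_fts(p, params)
  })
  sets <- lapply(profiles, function(pr) names(pr$ft))
  carrier <- table(unlist(sets, use.names = FALSE))
  dft_set <- sort(names(carrier))
  carrier <- stats::setNames(as.integer(carrier[dft_set]), dft_set)
  structure(list(
    source_id = source_id,
    dft_set = dft_set,
    carrier_counts = carrier,
    dft_per_protein = stats::setNames(lengths(sets),
                                      vapply(profiles, `[[`, character(1),
                                             "protein_id")),
    n_proteins = length(profiles),
    n_co = sum(lengths(sets) > 0L)),
    class = "proteome_vocabulary")
}

#' @export
print.proteome_vocabulary <- function(x, ...) {
  cat(sprintf("<proteome_vocabulary> %s: %d DFTs over %d/%d CO proteins\n",
              x$source_id, length(x$dft_set), x$n_co, x$n_proteins))
  invisible(x)
}

#' Jaccard similarity of two FT vocabularies
#'
#' C_IJ = |DFT_I intersect DFT_J| / |DFT_I union DFT_J|. Symmetric, equal to
#' 1 for identical non-empty sets; defined as 0 (with a warning) when both
#' vocabularies are empty.
#'
#' @param a,b \code{proteome_vocabulary} objects (or bare character vectors
#'   of FTs).
#' @return Numeric in [0, 1].
#' @export
jaccard <- function(a, b) {
  sa <- if (inherits(a, "proteome_vocabulary")) a$dft_set else as.character(a)
  sb <- if (inherits(b, "proteome_vocabulary")) b$dft_set else as.character(b)
  u <- union(sa, sb)
  if (!length(u)) {
    warning("both vocabularies are empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(sa, sb)) / length(u)
}

#' Pairwise Jaccard correlation matrix of proteome vocabularies
#'
#' @param vocabularies List of at least two \code{proteome_vocabulary}
#'   objects.
#' @param tree If TRUE, attach an average-linkage hierarchical clustering of
#'   the rows (Euclidean distance between rows of the C_IJ matrix) as a
#'   Newick string in attribute \code{"newick"}.
#' @return Symmetric numeric matrix with unit diagonal, dimnames taken from
#'   the vocabulary source ids.
#' @export
correlation_matrix <- function(vocabularies, tree = FALSE) {
  stopifnot(length(vocabularies) >= 2L)
  ids <- vapply(vocabularies, `[[`, character(1), "source_id")
  m <- diag(1, length(vocabularies))
  dimnames(m) <- list(ids, ids)
  for (i in seq_along(vocabularies)[-1L])
    for (j in seq_len(i - 1L))
      m[i, j] <- m[j, i] <- jaccard(vocabularies[[i]], vocabularies[[j]])
  if (tree) {
    hc <- stats::hclust(stats::dist(m), method = "average")
    attr(m, "newick") <- ape::write.tree(ape::as.phylo(hc))
  }
  m
}

#' Rank predominant FTs of a proteome
#'
#' FTs sorted by the number of CO proteins carrying them (descending; ties
#' broken lexicographically). FTs composed of a single amino-acid letter
#' represent runs (homo-peptides) and are flagged.
#'
#' @param vocab A \code{proteome_vocabulary}.
#' @param top_n Number of FTs to return (default 20).
#' @return Data.frame with columns \code{ft}, \code{carrier_count} and
#'   \code{homo_run}.
#' @export
rank_predominant_fts <- function(vocab, top_n = 20L) {
  stopifnot(inherits(vocab, "proteome_vocabulary"))
  cc <- vocab$carrier_counts
  ord <- order(-cc, names(cc))
  sel <- utils::head(ord, top_n)
  ft <- names(cc)[sel]
  data.frame(ft = ft,
             carrier_count = as.integer(cc[sel]),
             homo_run = vapply(strsplit(ft, ""), function(ch)
               length(unique(ch)) == 1L, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Abundance distributions of an FT vocabulary
#'
#' Two normalized empirical distributions: the probability that an FT is
#' carried by a given number of CO proteins (few FTs are common, many are
#' rare), and the probability that a protein carries a given number of DFTs.
#' Both follow approximate power laws in real proteomes.
#'
#' @param vocab A \code{proteome_vocabulary}.
#' @return List with data.frames \code{ft_carriers} (\code{carriers},
#'   \code{p}) and \code{protein_dfts} (\code{dft_count}, \code{p}), each
#'   summing to 1; \code{protein_dfts} is over CO proteins only.
#' @export
dft_abundance_distribution <- function(vocab) {
  stopifnot(inherits(vocab, "proteome_vocabulary"))
  tb1 <- table(vocab$carrier_counts)
  co_counts <- vocab$dft_per_protein[vocab$dft_per_protein > 0L]
  tb2 <- table(co_counts)
  list(
    ft_carriers = data.frame(carriers = as.integer(names(tb1)),
                             p = as.numeric(tb1) / sum(tb1)),
    protein_dfts = data.frame(dft_count = as.integer(names(tb2)),
                              p = as.numeric(tb2) / sum(tb2)))
}

#' Power-law fit on a log-log scale
#'
#' Least-squares line of log10(p) against log10(x), restricted to points
#' whose log10(x) falls inside \code{fit_range}. The slope is the power-law
#' exponent; r is the Pearson correlation of the fitted points. Points with
#' non-positive x or p are excluded (log undefined).
#'
#' @param x Strictly positive abscissae (e.g. carrier counts, ranks).
#' @param p Strictly positive ordinates (e.g. probabilities).
#' @param fit_range Numeric length-2 interval on log10(x); NULL fits all
#'   points.
#' @return Object of class \code{regression_fit}: list with \code{slope},
#'   \code{intercept}, \code{r}, \code{pvalue}, \code{fit_range} and
#'   \code{n_points}.
#' @examples
#' g <- 1:50
#' fit_loglog(g, g^-2)$slope  # exact power law -> -2
#' @export
fit_loglog <- function(x, p, fit_range = NULL) {
  keep <- is.finite(x) & is.finite(p) & x > 0 & p > 0
  x <- x[keep]; p <- p[keep]
  lx <- log10(x); lp <- log10(p)
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2L)
    inr <- lx >= min(fit_range) & lx <= max(fit_range)
    lx <- lx[inr]; lp <- lp[inr]
  } else {
    fit_range <- range(lx)
  }
  if (length(lx) < 3L) stop("fewer than 3 positive points in the fit range")
  fit <- stats::lm(lp ~ lx)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(lx, lp),
                 pvalue = sm$coefficients[2L, 4L],
                 fit_range = sort(fit_range),
                 n_points = length(lx)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> slope = %.4f, r = %.3f, p = %.3g (%d points in [%.2f, %.2f])\n",
    x$slope, x$r, x$pvalue, x$n_points, x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Binned power-law regression of an order measure against protein length
#'
#' Reproduces the universality analysis of the length dependence of RP and
#' DFT: the measure axis is cut into \code{n_bins} equally spaced bins,
#' within each non-empty bin the mean protein length is computed, and a line
#' is fitted to log10(bin center) against log10(mean L). Binning along the
#' measure axis (rather than along L) equalizes the weight of rare
#' high-measure proteins. Empty bins are dropped. The unbinned Pearson
#' correlation between log10(measure) and log10(L) is attached as
#' \code{rho}.
#'
#' @param co_table Data.frame from \code{\link{classify_proteome}} (CO rows
#'   with a defined, strictly positive measure are used).
#' @param measure One of \code{"rp"}, \code{"dft_count"}, \code{"rc"}.
#' @param n_bins Number of equally spaced measure bins (default 50).
#' @param min_bins Minimum number of non-empty bins required (default 3).
#' @return A \code{\link{fit_loglog}}-style \code{regression_fit} with extra
#'   elements \code{rho} (unbinned correlation) and \code{bins} (data.frame
#'   of bin centers and mean lengths).
#' @export
binned_measure_length_regression <- function(co_table,
                                             measure = c("rp", "dft_count", "rc"),
                                             n_bins = 50L, min_bins = 3L) {
  measure <- match.arg(measure)
  keep <- co_table$is_co & is.finite(co_table[[measure]]) &
    co_table[[measure]] > 0
  y <- co_table[[measure]][keep]
  L <- co_table$L[keep]
  if (length(y) < n_bins)
    stop("need at least n_bins CO proteins with a positive measure")
  edges <- seq(min(y), max(y), length.out = n_bins + 1L)
  bin <- findInterval(y, edges, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  meanL <- tapply(L, factor(bin, levels = seq_len(n_bins)), mean)
  keep_bins <- !is.na(meanL) & centers > 0
  if (sum(keep_bins) < min_bins) stop("too few non-empty bins")
  lx <- log10(as.numeric(meanL[keep_bins]))
  ly <- log10(centers[keep_bins])
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = stats::cor(lx, ly),
                 pvalue = sm$coefficients[2L, 4L],
                 fit_range = range(lx),
                 n_points = sum(keep_bins),
                 rho = stats::cor(log10(L), log10(y)),
                 bins = data.frame(center = centers[keep_bins],
                                   mean_L = as.numeric(meanL[keep_bins]))),
            class = "regression_fit")
}

#' Export a vocabulary table as TSV
#'
#' @param vocab A \code{proteome_vocabulary}.
#' @param path Output file path.
#' @return Invisibly, the written data.frame (ft, carrier_count, homo_run).
#' @export
write_vocabulary <- function(vocab, path) {
  df <- rank_predominant_fts(vocab, top_n = length(vocab$dft_set))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a Jaccard correlation matrix as TSV
#'
#' Square matrix with a header row and a leading id column.
#'
#' @param m Matrix from \code{\link{correlation_matrix}}.
#' @param path Output file path.
#' @export
write_correlation_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
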