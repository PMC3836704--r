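# Proteome vocabulary, Jaccard comparison, predominant FTs, abundance
# distributions and power-law regressions.

test_that("vocabulary is a union of per-protein FT sets with carrier counts", {
  run <- protein_record("run", "AAAAAAA")
  rpt <- protein_record("rpt", "AQAQAQAQAQAQ")
  v <- build_vocabulary(list(run, rpt))
  expect_setequal(v$dft_set, c("AAA", "AQA", "QAQ"))
  expect_true(all(v$carrier_counts == 1L))
  expect_equal(v$n_co, 2L); expect_equal(v$n_proteins, 2L)
  # the six bundled examples: vocabulary equals the brute-force set union
  fx <- table1_fixtures()
  v6 <- build_vocabulary(fx)
  want <- sort(unique(unlist(lapply(fx, function(p)
    names(oracle_fts(p$seq, CANONICAL_AA))))))
  expect_equal(v6$dft_set, want)
})

test_that("vocabulary is invariant under duplication and ordering", {
  fx <- table1_fixtures()
  v1 <- build_vocabulary(fx)
  v2 <- build_vocabulary(c(fx, fx))          # every protein duplicated
  v3 <- build_vocabulary(rev(fx))            # permuted
  expect_equal(v2$dft_set, v1$dft_set)
  expect_equal(v3$dft_set, v1$dft_set)
  expect_equal(v2$carrier_counts, 2L * v1$carrier_counts)
})

test_that("Jaccard similarity satisfies its axioms", {
  a <- c("AAA", "GGG", "PPP"); b <- c("GGG", "PPP", "QQQ")
  expect_equal(jaccard(a, b), 0.5)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, c("WWW")), 0)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_warning(z <- jaccard(character(0), character(0)), "empty")
  expect_equal(z, 0)
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  fx <- table1_fixtures()
  vs <- lapply(names(fx), function(nm)
    build_vocabulary(fx[nm], source_id = nm))
  m <- correlation_matrix(vs, tree = TRUE)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 6))
  expect_true(all(m >= 0 & m <= 1))
  # hand-computed entry: LORI vs PRDM9 share no FT
  expect_equal(m["LORI", "PRDM9"], jaccard(vs[[2]], vs[[6]]))
  # the attached Newick tree parses and carries all leaves
  tr <- ape::read.tree(text = attr(m, "newick"))
  expect_setequal(tr$tip.label, names(fx))
})

test_that("predominant-FT ranking counts carriers and flags homo-runs", {
  polyE <- lapply(1:3, function(i)
    protein_record(paste0("e", i), strrep("E", 10 + i)))
  pgp <- lapply(1:2, function(i)
    protein_record(paste0("p", i), strrep("PG", 10)))
  rk <- rank_predominant_fts(build_vocabulary(c(polyE, pgp)))
  expect_equal(rk$ft[1], "EEE")
  expect_true(rk$homo_run[1])
  expect_equal(rk$carrier_count[1], 3L)
  expect_setequal(rk$ft[rk$carrier_count == 2L], c("GPG", "PGP"))
  expect_false(any(rk$homo_run[rk$ft != "EEE"]))
  # deterministic lexicographic tie-break
  expect_equal(rk$ft, rk$ft[order(-rk$carrier_count, rk$ft)])
})

test_that("abundance distributions are normalized probability tables", {
  run <- protein_record("run", "AAAAAAA")
  rpt <- protein_record("rpt", "AQAQAQAQAQAQ")
  ad <- dft_abundance_distribution(build_vocabulary(list(run, rpt)))
  expect_equal(ad$ft_carriers, data.frame(carriers = 1L, p = 1))
  expect_equal(sum(ad$protein_dfts$p), 1)
  fx <- table1_fixtures()
  ad6 <- dft_abundance_distribution(build_vocabulary(fx))
  expect_equal(sum(ad6$ft_carriers$p), 1)
  expect_equal(sum(ad6$protein_dfts$p), 1)
})

test_that("log-log fits recover planted exponents exactly on noiseless grids", {
  g <- 1:100
  expect_equal(suppressWarnings(fit_loglog(g, 0.3 * g^-2))$slope, -2,
               tolerance = 1e-10)
  zipf <- suppressWarnings(fit_loglog(g, g^-1 / sum(g^-1)))
  expect_equal(zipf$slope, -1, tolerance = 1e-10)
  expect_equal(abs(zipf$r), 1, tolerance = 1e-10)
  # range restriction uses only in-range points
  p <- 0.3 * g^-2; p[g > 10] <- p[g > 10] * 100   # corrupt the tail
  fit <- suppressWarnings(fit_loglog(g, p, fit_range = c(0, 1)))
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$n_points, 10L)
  expect_error(fit_loglog(1:2, c(1, 2)), "fewer than 3")
})

test_that("log-log fits recover a planted exponent from sampled data", {
  set.seed(77)
  alpha <- 1.6
  support <- 1:500
  x <- sample(support, 5000, replace = TRUE,
              prob = support^-alpha)
  tb <- table(x)
  fit <- fit_loglog(as.integer(names(tb)), as.numeric(tb) / sum(tb),
                    fit_range = c(0, 2))
  expect_equal(fit$slope, -alpha, tolerance = 0.1)
  expect_lt(fit$pvalue, 1e-6)
})

test_that("binned measure-length regression recovers planted power laws", {
  set.seed(13)
  n <- 400
  L <- round(exp(runif(n, log(100), log(5000))))
  co <- data.frame(id = paste0("p", 1:n), L = L, is_co = TRUE,
                   dft_count = 2 * L^0.5, rp = 5 * L^-0.5,
                   rc = runif(n, 0.05, 0.6))
  frp <- binned_measure_length_regression(co, "rp")
  fdft <- binned_measure_length_regression(co, "dft_count")
  expect_equal(frp$slope, -0.5, tolerance = 0.05)
  expect_equal(fdft$slope, 0.5, tolerance = 0.05)
  expect_equal(frp$slope / fdft$slope, -1, tolerance = 0.05)
  expect_equal(frp$rho, -1, tolerance = 1e-10)  # exact law, unbinned
  # RC planted independent of L: no significant correlation
  frc <- binned_measure_length_regression(co, "rc")
  expect_lt(abs(frc$rho), 0.15)
  expect_error(binned_measure_length_regression(co[1:10, ], "rp"),
               "at least")
})

test_that("vocabulary and matrix TSV surfaces round-trip", {
  fx <- table1_fixtures()
  v <- build_vocabulary(fx)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), length(v$dft_set))
  expect_equal(sum(back$carrier_count), sum(v$carrier_counts))
  vs <- lapply(names(fx)[1:3], function(nm)
    build_vocabulary(fx[nm], source_id = nm))
  m <- correlation_matrix(vs)
  mt <- withr::local_tempfile(fileext = ".tsv")
  write_correlation_matrix(m, mt)
  back2 <- read.delim(mt, check.names = FALSE)
  expect_equal(as.matrix(back2[, -1]), m, ignore_attr = TRUE)
})
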