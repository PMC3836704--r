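# Per-protein order measures: coverage, intervals, MFI, RP, entropy and the
# assembled classification.

test_that("relative coverage matches the worked examples", {
  expect_equal(covered_loci(detect_fts("AAAAAAA")), 7L)
  expect_equal(relative_coverage(detect_fts("AAAAAAA")), 1.0)
  expect_equal(covered_loci(detect_fts("AQAQAQAQAQAQ")), 12L)
  expect_equal(relative_coverage(detect_fts("ACDEFGHIKLMNPQRSTVWY")), 0)
})

test_that("interval distributions pool per-FT consecutive gaps", {
  d1 <- interval_distribution(detect_fts("AAAAAAA"))
  expect_equal(d1$pooled, rep(1L, 4))
  d2 <- interval_distribution(detect_fts("AQAQAQAQAQAQ"))
  expect_equal(d2$pooled, rep(2L, 8))
  expect_equal(lengths(d2$per_ft), c(AQA = 4L, QAQ = 4L))
  # an FT with m occurrences contributes exactly m - 1 gaps
  set.seed(5)
  for (i in 1:10) {
    prof <- detect_fts(random_seq(300), ft_params(n = 3))
    d <- interval_distribution(prof)
    expect_equal(length(d$pooled), sum(pmax(lengths(prof$ft) - 1L, 0L)))
    expect_true(all(d$pooled >= 1L))
  }
})

test_that("MFI is the modal interval with lowest-value tie-breaking", {
  d <- interval_distribution(detect_fts("AAAAAAA"))
  expect_equal(most_frequent_interval(d), 1L)
  tie <- structure(list(per_ft = list(X = c(3L, 3L), Y = c(7L, 7L)),
                        pooled = c(3L, 3L, 7L, 7L)),
                   class = "interval_distribution")
  expect_equal(most_frequent_interval(tie), 3L)
  empty <- structure(list(per_ft = list(), pooled = integer(0)),
                     class = "interval_distribution")
  expect_true(is.na(most_frequent_interval(empty)))
})

test_that("RP equals the brute-force pair-enumeration oracle and is bounded", {
  set.seed(19)
  for (i in 1:30) {
    s <- random_seq(sample(30:100, 1))
    prof <- detect_fts(s, ft_params(n = 2))
    if (!is_co(prof)) next
    d <- interval_distribution(prof)
    mfi <- most_frequent_interval(d)
    rp <- relative_periodicity(prof, d, mfi)
    expect_gte(rp, 0); expect_lte(rp, 1)
    total <- sum(lengths(prof$ft))
    expect_equal(rp, oracle_rp_numerator(prof$ft, mfi) / total)
  }
})

test_that("MFI and RP are invariant under FT iteration order", {
  set.seed(23)
  s <- random_seq(400)
  prof <- detect_fts(s, ft_params(n = 3))
  stopifnot(length(prof$ft) >= 2)
  perm <- prof
  perm$ft <- perm$ft[sample(length(perm$ft))]
  d0 <- interval_distribution(prof); dp <- interval_distribution(perm)
  expect_equal(most_frequent_interval(d0), most_frequent_interval(dp))
  expect_equal(relative_periodicity(prof, d0), relative_periodicity(perm, dp))
})

test_that("entropy follows the generalized Shannon definition", {
  e <- sequence_entropy("AAAAAAA", 1)
  expect_equal(e$s_k, 0); expect_equal(e$ns_k, 0)
  e <- sequence_entropy("ACDEFGHIKLMNPQRSTVWY", 1)
  expect_equal(e$s_k, log2(20))
  expect_equal(e$ns_k, 1)
  # two equiprobable triplets over 10 windows: one bit, normalized by log2(L)
  e <- sequence_entropy("AQAQAQAQAQAQ", 3)
  expect_equal(e$s_k, 1)
  expect_equal(e$ns_k, 1 / log2(12))
  expect_equal(e$normalization_base, log2(12))
  expect_error(sequence_entropy("ACD", 5), "exceeds")
})

test_that("a pure tandem repeat has MFI equal to its unit length", {
  for (unit in c(UNIT13, UNIT28)) {
    p <- plant_motif(unit, repeats = 6, seed = 1)$protein
    cp <- classify_protein(p)
    expect_equal(cp$mfi, nchar(unit))
    expect_equal(cp$purity_class, "pure")
    # every constituent FT recurs at the unit length
    d <- interval_distribution(cp$profile)
    expect_true(all(d$pooled == nchar(unit)))
  }
})

test_that("classification assembles all measures coherently", {
  fx <- table1_fixtures()
  prdm9 <- classify_protein(fx$PRDM9)
  expect_equal(prdm9$dft_count, 28L)
  expect_equal(prdm9$mfi, 28L)
  expect_equal(prdm9$purity_class, "pure")
  expect_true(prdm9$periodic)
  aspx <- classify_protein(fx$ASPX)
  expect_equal(aspx$dft_count, 6L)
  expect_equal(aspx$mfi, 5L)
  expect_equal(aspx$purity_class, "complex")
  no <- classify_protein("AAAAAA")
  expect_false(no$is_co)
  expect_equal(no$dft_count, 0L)
  expect_true(is.na(no$mfi))
  expect_equal(no$rc, 0)
})

test_that("RC bounds hold on fuzz inputs: [0,1] with a floor for CO proteins", {
  set.seed(31)
  for (i in 1:30) {
    s <- random_seq(sample(10:300, 1))
    prof <- detect_fts(s)
    rc <- relative_coverage(prof)
    expect_gte(rc, 0); expect_lte(rc, 1)
    if (is_co(prof)) {
      # 5 overlapping occurrences of one triplet cover at least 7 loci
      expect_gte(covered_loci(prof), 7L)
      expect_gte(rc, 7 / (nchar(s) - 2L))
    }
  }
})

test_that("RC rank-correlates with triplet order (1 - nS3) across a batch", {
  set.seed(47)
  # mixed-order batch: backgrounds plus planted repeats of varying extent
  prots <- c(
    lapply(1:15, function(i) generate_random_protein(300, id = paste0("r", i))),
    lapply(1:15, function(i)
      plant_motif(UNIT13, repeats = sample(5:20, 1),
                  flank_lengths = sample(20:150, 2, TRUE))$protein))
  co <- classify_proteome(prots)
  rho <- suppressWarnings(
    cor(co$rc, 1 - co$ns3, method = "spearman"))
  expect_gt(rho, 0.5)
})

test_that("the proteome table round-trips through its TSV surface", {
  co <- classify_proteome(table1_fixtures())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_co_table(co, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 6L)
  expect_equal(back$dft_count, co$dft_count)
  expect_equal(back$rc, round(co$rc, 4))
  expect_equal(back$rp, round(co$rp, 4))
})
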