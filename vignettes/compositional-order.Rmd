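---
title: "Quantifying compositional order in protein sequences with frequent triplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compositional order in protein sequences with frequent triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coft)
```

## The problem

Many proteins carry ordered stretches of sequence: homo-peptide runs (poly-Q,
poly-A), tandem repeats of short motifs (collagen's PGP period, the 28-residue
zinc-finger unit), and low-complexity regions of biased composition. These
phenomena are usually treated by separate tools (entropy filters for low
complexity, alignment-based tandem-repeat finders for repeats). `coft`
implements a single framework that captures all of them through one primitive:
the **frequent triplet** (FT), an amino-acid 3-mer that occurs at least
`n = 5` times in one protein, counted at every start position *including
overlapping ones*. A protein containing at least one FT is called
**compositionally ordered** (CO); a protein with none is NO.

Overlap counting is essential to the arithmetic: the run `AAAAAAA` (7
residues) contains exactly 5 overlapping occurrences of the single FT `AAA`,
and the tandem repeat `AQAQAQAQAQAQ` contains the two FTs `AQA` and `QAQ`,
5 occurrences each, every consecutive pair separated by 2 residues.

## Why five occurrences of a triplet is a signal

Amino-acid triplets form a set of $20^3 = 8000$ types. In an i.i.d. random
sequence of length $L$ a fixed triplet occurs in each of the $W = L - 2$
windows with probability $p = 1/8000$ (uniform model), so its occurrence
count is approximately $X \sim \mathrm{Binomial}(W, p)$, treating overlapping
windows as independent trials. The expected number of triplet types reaching
the threshold $n$ is

$$E(L, n) \;=\; \sum_{t=1}^{8000} P(X_t \ge n) \;=\; 8000\, P(X \ge n)
\quad\text{(uniform model)},$$

and $E/8000$ is the per-triplet P-value for FT misidentification.
`expected_ft_count()` evaluates this with the numerically stable binomial
survival function (no factorials), which is exact for lengths up to the
longest known proteins (~35,000 residues). `simulate_ft_expectation()`
validates the independence approximation by Monte Carlo: across a grid
$L \in \{2000, 4000, 8000, 12000, 16000, 20000\}$ with 200 replicates per
point — sizes chosen so that each grid point has a meaningful empirical
standard error while the whole validation runs in well under a minute — the
empirical mean FT count agrees with the analytic curve within three standard
errors at every point. The residual dependence between overlapping windows
(self-overlapping words such as `AAA` occur in clumps) is below that
resolution.

Exact evaluation places the crossing of the $10^{-3}$ misidentification
level near $L \approx 6000$ (at $L = 7999$ the P-value is $3.7\times
10^{-3}$); for the vast majority of proteins ($L < 2000$) the P-value is
astronomically small. For very long proteins the package offers the
**restrictive** definition: the $n$ occurrences must fall within some window
of $M$ consecutive residues (conventionally $M = 2000$), implemented as a
sliding criterion over the sorted occurrence positions
($\exists i:\; \mathrm{pos}_{i+n-1} + k - \mathrm{pos}_i \le M$). A kept
FT's reported occurrence list always retains *all* of its occurrences, not
only those inside a qualifying window: the windowed criterion decides
membership, not the occurrence set (the alternative — trimming to the
window — would make downstream interval statistics depend on an arbitrary
choice of qualifying window).

The **unigram** model replaces the uniform letter law with empirical
single amino-acid frequencies (`aa_frequencies()`); the triplet probability
becomes the product of its letter probabilities and $E$ is summed over all
8000 types. The uniform model is its equal-probability special case. No
reference frequency set is bundled; the user supplies one (or uses uniform).

## The order measures

All measures derive from the per-protein FT profile (`detect_fts()`), the
map FT → ordered 0-based occurrence positions.

**Regularity — relative coverage (RC).** The number of distinct residue
loci covered by FT occurrences (each occurrence covers $k = 3$ consecutive
loci), divided by the number of triplet windows $W = L - k + 1$ and clipped
to 1. Normalizing by the window count rather than by $L$ is deliberate: it
is the same $W$ that enters the null model, and it reproduces published
reference values for annotated example proteins (the two normalizations
differ only in the third decimal for ordinary lengths, but the bundled
keratin example discriminates between them at its printed precision). The
clip keeps RC in $[0, 1]$ for degenerate short sequences such as the
7-residue run, whose 7 covered loci exceed its 5 windows. RC is strongly
anti-correlated with the triplet entropy $nS_3$, recapitulating classical
low-complexity detection with a larger dynamic range.

**Periodicity — MFI and RP.** For each FT the gaps between consecutive
occurrences are collected; pooling the gaps of all FTs of a protein gives
the empirical interval distribution. The **most frequent interval** (MFI)
is its mode, with ties resolved to the smallest tied interval (the lower
value is typically the fundamental of the higher harmonic). MFI = 1 marks
runs; a pure tandem repeat of unit length $m > k$ has MFI = $m$, because
every constituent triplet recurs exactly one unit later. **Relative
periodicity** (RP) is the number of pooled gaps equal to the MFI divided by
the total number of FT occurrences. Two readings of "occurrences within the
MFI" are possible — counting MFI-gaps, or counting occurrences that
participate in at least one MFI-gap; evaluated on the six bundled example
proteins only the gap-counting convention reproduces all six published RP
values, so it is frozen here. RP lies in $[0, 1]$ and decays as the MFI
loses support. A CO protein whose MFI is supported by fewer than
`periodicity_threshold = 4` recurrences is flagged non-periodic; at that
default a majority of CO proteins in well-annotated proteomes carry genuine
periodic structure.

**Vocabulary — DFT.** The number of *different* frequent triplets, per
protein or per proteome (the union of per-protein FT sets;
`build_vocabulary()`). Being a set size, it is invariant under protein
duplication, which makes it robust to database redundancy. Comparing the
DFT against the MFI yields a motif **purity class**: DFT = MFI is a pure
repeated motif (the DFTs *are* the motif's triplets), DFT < MFI indicates
mutational degradation, DFT > MFI regularity in excess of periodicity (low
complexity without a dominant period).

**Entropy.** The generalized $k$-mer Shannon entropy
$S_k = -\sum_i (n_i/W)\log_2(n_i/W)$ over the $W = L - k + 1$ overlapping
windows, normalized by $\log_2 20^k$ when $20^k \le L$ and by $\log_2 L$
otherwise. The switch is stated for $k$-mers with $20^k \gg L$; generalizing
it to "whenever $20^k > L$" makes $k = 2$ behave continuously between the
two regimes. Only $nS_1$ and $nS_3$ are used downstream.

## Proteome comparison and universality fits

Vocabularies of different proteomes are compared by the Jaccard index
$C_{IJ} = |DFT_I \cap DFT_J| / |DFT_I \cup DFT_J|$ (`jaccard()`,
`correlation_matrix()`); average-linkage hierarchical clustering of the
Euclidean distances between matrix rows (exported as Newick) groups related
proteomes. Predominant FTs are ranked by the number of CO proteins carrying
them, with homo-run FTs (three identical letters) flagged; ranking ties are
broken lexicographically so that outputs are deterministic.

`fit_loglog()` fits a least-squares line to $\log_{10} p$ versus
$\log_{10} x$ within a caller-specified range of the $\log_{10} x$ axis,
returning the power-law exponent; zero-probability points are excluded
(log undefined) rather than imputed. `binned_measure_length_regression()`
reproduces the length-universality analysis: the measure axis (RP, DFT or
RC) is cut into 50 equally spaced bins, each non-empty bin contributes its
center and the mean protein length of its members, and the regression runs
on the log-log pairs; empty bins are dropped rather than interpolated.
Binning is performed on the raw measure scale before taking logs (binning
on the log scale would be an equally defensible alternative for unbounded
measures like DFT; for measures bounded in $[0,1]$ the raw scale matches
the equal-spacing description). The unbinned Pearson correlation between
log-measure and log-length is reported alongside.

## Functional enrichment

`enrichment_sweep()` quantifies how an annotation term's share of the CO
set changes as an order-measure threshold rises: $N_{tot}(t)$ counts CO
proteins with measure $> t$ (strict inequality, following "value greater
than some threshold"; with decile-based default grids the boundary choice
only relabels grid points), $N_{fun}(t)$ those whose free-text annotation
contains the term (case-insensitive literal search — deliberately not
ontology-graph expansion). Significance is the one-sided upper
hypergeometric tail comparing the counts at the ratio-maximizing threshold
against the full CO set at the minimal threshold; thresholds are admissible
only when $N_{fun} > 15$ and $N_{fun}$ is at least 10% of its value at the
minimal threshold (the published constraint is parenthetical and ambiguous;
it is read here as a floor relative to the baseline count). When no
threshold is admissible the curve is still returned, with the P-value
undefined and a reason code. The companion measure `run_length_measure()`
(total recurrences at interval 1, i.e. the effective coverage of runs)
supports run-length sweeps.

## Synthetic data

The generators exist so that every analysis operation is testable without
downloads, with known ground truth.

* `table1_fixtures()` returns six bundled annotated human proteins spanning
  the order spectrum (scattered runs, glycine-serine keratin, an 8-residue
  repeated motif, degraded collagen periodicity, an SGE-rich developmental
  protein, and a 28-residue pure zinc-finger motif). The FASTA is
  integrity-checked by digest and by length on every load. One residue of
  the A4 record, dropped in transcription, was restored from the canonical
  amyloid-beta A4 sequence so that the record matches its reference length.
* `plant_motif()` concatenates $r$ copies of a motif, applies i.i.d.
  substitutions at a chosen impurity rate, pads with random flanks, and
  returns the ground truth (unit length, repeat count, coordinates).
* `generate_proteome()` draws lengths from a log-normal law (default
  `meanlog = log(375)`, `sdlog = 0.9`, truncated to [50, 2000] — the
  characteristic shape and median of real proteome length distributions),
  plants motifs in a chosen fraction of proteins, and can plant an
  annotation term with a logistic dependence on relative coverage (known
  log-odds), providing ground truth for enrichment recovery.

What the generators do *not* emulate: real mutational processes (slippage,
segmental duplication), compositional autocorrelation beyond first order,
domain architecture, or database annotation noise. Passing recovery tests
therefore demonstrates correctness of the measures and estimators on
sequences with the assumed statistical structure, not performance claims
about any particular organism's proteome.

## Numerical choices and degenerate inputs

* Positions are 0-based internally; all reported measures are
  position-system independent.
* MFI of a profile with an empty pooled interval multiset is undefined
  (`NA`); RP is 0 by convention in that case. Under the default `n = 5`
  every CO protein has at least four gaps, so this arises only for
  user-lowered thresholds.
* Proteins with only short runs (< 7 residues) are NO by construction:
  a 6-run holds only 4 overlapping triplet occurrences.
* Printed-precision comparisons round half-up, matching how the reference
  values are typeset; internal TSV output keeps 4 decimals.
* Vectorized base-R string scanning (`substring` windows + `split`)
  processes a 20,000-residue sequence in ~20 ms; no compiled code is
  needed at the package's design scales.

## Known limitations

* The binomial null treats overlapping windows as independent; the
  Monte-Carlo module quantifies the (small) error rather than correcting it
  with word-autocorrelation combinatorics.
* FT detection is exact string matching: a single substitution inside a
  repeat splits an FT's occurrence list, which is precisely what the purity
  classes exploit, but means measures are not robust to sequencing error.
* Enrichment matching is literal substring search; synonyms and ontology
  ancestors are out of scope.
* Reference values for whole published proteomes (species DFT counts,
  proteome CO fractions, GO enrichment P-values) require the corresponding
  database downloads and are therefore outside the test surface; the
  machinery that would compute them is validated on exact small instances
  and synthetic ground truth instead.
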