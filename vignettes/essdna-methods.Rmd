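---
title: "Mapping endogenous single-stranded DNA from 3'-OH terminus sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endogenous single-stranded DNA from 3'-OH terminus sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssingleP1)
library(GenomicRanges)
```

## The measurement

Endogenous single-stranded DNA (essDNA) arises wherever the double helix is
opened or nicked in vivo: replication origins, R-loops, melted promoters, the
displacement loop of the mitochondrial genome. The SSiNGLe-P1 assay marks
essDNA by limited digestion of crosslinked nuclei with P1 endonuclease, which
strongly prefers single-stranded substrates and leaves 3'-OH termini at its
cut sites. Each 3'-OH terminus is polyA-tailed, linearly amplified with an
oligo(T) primer, polyC-tailed, and sequenced as a read pair in which read 1
begins with a 9–11 G anchor and read 2 begins with an 11–13 T anchor followed
by the reverse complement of the broken strand ending at the terminus.
Untreated samples carry the endogenous single-strand-break (SSB) background
and serve as controls; a titration (0.01, 0.1, 1, 10 U of P1) separates
essDNA-specific cutting from the enzyme's weak double-stranded activity,
which becomes visible only at the top dose.

This package implements the downstream analysis of that design end to end —
read filtering, terminus extraction, mitochondrial strand-displacement
statistics, essDNA region calling, null simulation, and element/promoter
association — together with a synthetic-data generator so that every stage
is testable hermetically.

## From reads to termini

`classify_read_pairs()` applies the structural and quality rules in a fixed
order (adaptor, N fraction > 10%, bases at Q ≤ 5 over 50%, tag structure,
then per-base Q > 20 strictly), so rejection counters are deterministic;
`trim_tag_pairs()` removes the maximal leading G/T runs in lockstep with
their qualities. The per-base quality rule is applied to the untrimmed read;
whether the published pipeline filtered before or after trimming is not
stated, so the choice is isolated in configuration.

The single most consequential convention of the pipeline is how a read-2
alignment maps to a terminus. The tailing chemistry makes sequenced read 2
the reverse complement of the broken-strand segment that *ends* at the
3'-OH. Hence, in `terminus_from_alignments()`:

* a read 2 aligned to `+` with span `[s, e)` yields terminus `(s, "-")`;
* a read 2 aligned to `-` with span `[s, e)` yields terminus `(e - 1, "+")`.

This is isolated in one function and locked by synthetic-alignment tests.
Alignments whose first sequenced base is clipped have ambiguous positions
and are excluded by default; "uniquely mapped" is operationalized as primary,
non-supplementary, MAPQ ≥ 20.

Oligo(T) priming on genomic A-rich tracts mimics a tailed terminus.
`apply_priming_filter()` therefore inspects the 20 reference bases
immediately 5' of the terminus along the read-2 strand and discards sites
whose T fraction is strictly above 40% (9 of 20 is dropped, 8 of 20 kept).
Near a contig edge the available bases are used under the same fraction
rule — a truncated window with half its bases T is still discarded.

All coordinates at the package surface are 0-based half-open (BED
convention); interval containers are `GRanges`.

## Mitochondrial strand-displacement statistics

Under the strand-displacement model of mitochondrial replication, the
parental heavy (H) strand spends part of each cycle single-stranded, and the
duration of exposure varies along the genome: replication initiates in the
non-coding region (NCR) and the light-strand origin (OL) fires only after
roughly two-thirds of the H strand has been displaced. The genome outside
the NCR and OL is partitioned into Q1–Q4 (printed 1-based coordinates
10,593–16,024 / 5160–10,592 / 2869–5158 / 579–2868, converted internally to
0-based half-open). The printed partition leaves a single base between Q3
and Q2, which is treated as the OL placeholder; the NCR is the wrapped
complement, represented as two linear sub-intervals counted as one region.
The model predicts longer single-stranded exposure for Q1 than Q2 and for
Q3 than Q4 on the H strand, and little exposure on the L strand.

The heavy strand is mapped to the reference *minus* strand by default: the
displayed mitochondrial reference strand is the G-poor light strand, so the
G-rich heavy strand is its complement. Annotation sources differ here, so
the mapping is a visible, configurable parameter of `mito_annotation()`.

Counts are summarized in three modes — all termini, unique sites, and depth
(termini per site) — because redundant signal such as the fixed 3' end of
the 7S DNA species in the D-loop inflates termini counts without adding
sites. `hl_ratio()`, `normalized_hl_ratio()` (treated over control) and
`essdna_index()` (region/strand fraction of treated over control, each
normalized by its own mitochondrial total, hence library-size and
scale-invariant) expose the model's predictions; `paired_t_test()` compares
replicate vectors and flags zero-variance differences instead of producing
fake p-values.

## Calling essDNA regions

Nuclear essDNA produces discrete clusters of P1 termini over a diffuse SSB
background. The caller follows the windowed-Poisson island strategy of
broad-domain ChIP-seq callers, with the published parameterization as
default: redundancy threshold 1, window w = 10 bp, fragment size 1 bp,
effective genome fraction (EGF) 0.8, gap g = 30 bp, E-value 0.01.

With N deduplicated termini on a genome of length L, the background mean
per window is λ = N·w / (EGF·L). A window with k termini is *eligible* when
P(X ≥ k) < p₀ under Poisson(λ); p₀ = 0.2 follows the original island
caller's published default, since the analysis parameter list does not name
it. Islands are maximal runs of eligible windows separated by at most g/w
ineligible windows, scored by Σ −ln Poisson pmf(kᵢ; λ) over eligible
windows; the island interval spans the first through last eligible window.

The score threshold realizes the E-value: the expected number of
random-background islands with score at or above the threshold, across the
effective genome, must not exceed E. `island_score_threshold()` computes
this by dynamic programming under a renewal description of the background:
an island starts at an eligible window preceded by more than g/w ineligible
windows (rate q(1−q)^(g/w+1) per window, q the eligibility probability) and
continues past each eligible window with probability 1−(1−q)^(g/w+1); the
island score is then a geometric mixture of m-fold convolutions of the
single-window score distribution, evaluated on a 0.01 discretization grid
with overflow mass retained conservatively in the top bin and the truncated
island-length tail added as an upper bound. A seeded Monte Carlo null
(`simulate_island_null()`) provides an independent cross-check — the two
agree within Monte Carlo error across the tested grid — and serves as a
fallback if the DP cannot converge. Thresholds are memoized per parameter
signature because null-replicate loops repeat identical backgrounds.

The published parameter list names only the E-value although an untreated
control is used, so the control stage is made explicit rather than guessed:
candidate islands are detected on the treated sample by E-value, then each
island's treated count is tested by an upper-tail Poisson test against
`max(scaled control count, λ × island window span)`, with
Benjamini–Hochberg correction across islands and retention at FDR ≤ 0.01.
Control scaling defaults to the ratio of deduplicated totals. Both stages
are configurable, and `use_control = FALSE` reproduces pure
random-background calling. Strands are pooled (nuclear regions are reported
unstranded). Termini inside retained regions are the *clustered P1 cut
sites*; their fraction of all unique sites is the headline stringency
statistic, and `merge_region_sets()` produces the union across doses and
replicates (overlapping and bookended intervals joined).

`run_null_replicates()` rebuilds the background expectation empirically:
the same numbers of termini as in the real samples are placed uniformly
(contigs weighted by length, matching the default behaviour of the standard
interval shufflers — per-chromosome counts are not preserved), the caller is
re-run, and region/clustered-site counts are recorded per seeded replicate;
the published analysis used 100 replicates.

## Element enrichment and promoters

Enrichment of clustered cut sites in an element class is the odds ratio
EP / (TP × (EL/GL)) — the fraction of clustered sites in the class over the
fraction of the genome it covers. Element sets are merged before computing
EL so overlapping annotation records do not double-count bases; GL is the
total (not EGF-scaled) genome length, as the formula is printed. A site in
two classes counts for both — each class is a marginal question — whereas
`hierarchical_assign()` is exclusive: each region goes to the first class
in a stated priority order that it overlaps, and the remainder to
"others". `multiset_membership()` compares 2–4 annotation databases by
interval overlap, reporting unique fractions at the conventional
two-decimal percent precision (round half even).

Promoter analysis classifies promoters as proximal when they overlap the
closed ±1 kb window around any TSS (a midpoint-distance alternative is
available by flag), restricts TSSs to those inside CAGE peaks when
expression support is wanted, and assigns promoters to every gene whose
TSS window they overlap (a promoter between two genes gets both). Group
expression is compared by per-replicate group means under a paired t-test;
the 2×2 proximity contrast uses Pearson's chi-square without continuity
correction (the published test's calculator settings are unknown; the
correction is a flag). Over-representation of a hit list against gene sets
is the upper-tail hypergeometric with BH correction — a database-free
analog of a GO run in which the background is the set of genes with any
promoter in the same window.

One printed-value note: the fraction 28,235/51,899 computes to 54.4% at one
decimal; this package reports the computed value.

## What the generator emulates — and what it does not

`make_toy_genome()`, `plant_regions()`, `simulate_titration_termini()`,
`simulate_mito_termini()` and `emit_reads()` generate every input the
pipeline consumes, with recorded truth.

* **Nuclear titration.** Background SSB termini at 0.5 sites/kb
  (dose-independent), Poisson everywhere; P1-specific cuts inside planted
  regions at a dose-dependent per-bp density; genome-wide nonspecific cuts
  appearing at the top doses. The default 0.1U in-region density is 0.10
  termini/bp (~20 cuts in a 200 bp region). This mirrors the cluster
  density the assay actually produces in called regions — about 5 sites
  per 40–50 bp — and is the regime the windowed caller is designed for: at
  w = 10/g = 30, termini more than ~40 bp apart cannot chain, so a
  diffuse in-region rate of a few multiples of background would be
  invisible *by design*, not by defect. The default dose curve rises to
  0.1–1U and collapses at 10U (degradation of the exposed strand), with
  nonspecific cutting of 8× background appearing at 10U; a two-class
  variant (origin-like regions responding more sharply than other essDNA)
  reproduces the rise-then-fall of the enrichment odds ratio across doses.
* **Mitochondrial strand displacement.** Termini are allocated
  multinomially over (region × strand) cells with weight length ×
  (background + strength × dose × exposure); default H-strand exposures
  encode Q1 > Q2 and Q3 > Q4 with a uniform low L-strand exposure. The
  total P1 signal is deliberately modest (~20% of background at the 0.1U
  multiplier): the essDNA index normalizes by total mitochondrial termini,
  so a dominant treated signal would mechanically depress L-strand indices
  below 1 — the simulation keeps the L strand near 1, as the model
  predicts for unexposed DNA. An optional 7S-like cell places redundant
  termini at one fixed NCR heavy-strand position in every sample including
  the control, reproducing the termini-vs-unique-sites divergence of the
  D-loop.
* **Reads.** Read 2 carries the biology (anchor + reverse complement of
  the broken strand ending at the terminus); read 1 is an anchor plus
  inert filler, since the pipeline consumes only read 2's alignment. SAM
  records are emitted directly so extraction is testable without an
  aligner. Termini whose first sequenced genomic base is a T are
  *tag-ambiguous* — the polyT anchor would absorb adjacent genomic Ts, so
  no pipeline could recover their exact position; the generator flags and
  excludes them, and recovery tests assert exactness on the emitted rest.

The generator does not emulate sequencing errors, quality variation, PCR
duplication, mappability structure, GC bias, or chromatin accessibility;
passing tests therefore demonstrate the correctness of the analytical
chain, not robustness to artefacts of real libraries.

## Numerical choices and degenerate inputs

* Score discretization 0.01 with conservative overflow; island-length
  truncation chosen so the untracked tail is below 10⁻³ of the E-value.
* Depth over zero sites, H/L ratios with empty L-strand denominators, and
  essDNA indices with empty control regions are reported as missing or
  raised as flagged errors — never silently 0.
* Medians of region sizes use lower interpolation; Venn percentages round
  half-even to two decimals, proximity percentages to one.
* Empty BED files load as empty sets; empty treated tables call no
  regions; a sample called against itself yields nothing.

Default problem sizes in the test-suite and reproduction script — a 1 Mb
toy genome with 20 planted 200 bp regions, 100 shuffle replicates, 50,000
mitochondrial termini, 10-seed index replication — were chosen so each
stage exercises its full code path at desk scale while the statistics of
interest (recovery, calibration, orderings) are far from their decision
boundaries.

## A worked example

```{r example, eval = FALSE}
g <- c(chr1 = 1e6)
truth <- plant_regions(g, n = 20, sizes = 200, seed = 1)
sims <- simulate_titration_termini(truth, g, seed = 2)
res <- call_regions(sims[["0.1U"]], sims$control,
                    island_caller_config(), g)
res
mean(countOverlaps(truth, res$regions) > 0)  # sensitivity
```

## Known limitations

* The caller is single-threaded R; genome-scale inputs (10⁹ bp, 10⁶–10⁷
  termini) run, but the per-window histogram is held sparse in memory and
  very deep libraries may warrant chunking by contig.
* The renewal-based threshold ignores contig-edge effects; on contigs
  shorter than a few hundred windows the Monte Carlo route is the more
  faithful null.
* The control comparison assumes the scaled control count is a Poisson
  mean; overdispersed controls (copy-number structure) would need a
  negative-binomial extension.
* The H-strand mapping and the OL placeholder are annotation conventions,
  not measurements; both are configurable and should be checked against
  the reference in use.
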