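---
title: "Screening trans-regulators of recombination hotspots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening trans-regulators of recombination hotspots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hotspotTF)
```

## The screening model

`hotspotTF` screens a panel of DNA-binding proteins for preferential
binding inside meiotic recombination hotspots. The underlying model is
deliberately simple: a protein is a candidate trans-regulator if the
*fraction of hotspots containing at least one of its binding sites*
exceeds the corresponding fraction in matched background regions by more
than sampling noise allows. Everything else in the package — the scanner,
the control sampler, the GO statistic, the coverage graph — exists to make
that comparison well-defined, reproducible and interpretable.

The per-motif summary is a 2x2 table: `HM`/`HN` hotspots with/without a
motif occurrence, `CM`/`CN` the same for coldspots, compared through the
odds ratio `O_hc = (HM/HN)/(CM/CN)` with a Yates-corrected chi-square
p-value. Only the per-region *indicator* enters the statistic; raw hit
counts (reported separately) do not affect it, so the handling of
overlapping hits is irrelevant to the enrichment itself.

Two deliberate deviations from statistical convention are inherited from
the screening design and kept:

* Coldspot cells may be fractional, because they are arithmetic means over
  replicate coldspot draws (default 20). The fractional table is fed to
  the chi-square formula as-is. A per-replicate exact test would be more
  orthodox; the averaged-table convention is what the screening procedure
  defines, and the package follows it.
* No multiple-testing correction is applied *across motifs*. The q-values
  control FDR across scanned positions within one scan, not across the
  panel.

## Coldspot controls

Controls are matched per hotspot: same chromosome, same length (this
preserves both the length distribution and the per-chromosome count
distribution), at least `min_distance` (default 50 kb) from every hotspot,
and pairwise non-overlapping. Distance is measured between closest
interval ends, the conservative reading that guarantees no control base
lies within 50 kb of hotspot sequence. Controls are *not* required to keep
any minimum distance from each other beyond non-overlap — requiring more
would be an assumption the matching rules do not state.

Sampling is uniform rejection sampling per hotspot, processing hotspots in
descending length (long intervals are hardest to place), with a
configurable attempt budget (default 10,000) and a clear failure naming
the chromosome when a genome is too crowded. An optional filter rejects
candidates whose N fraction exceeds `max_n_fraction` (default 0.5):
assembly gaps cannot carry motif hits, so controls buried in N-runs would
bias `CM` downward. The filter is off unless genome sequence is supplied.

## The scanner and its exact p-values

Motifs are position frequency matrices (JASPAR, TRANSFAC and MEME minimal
formats are read; TRANSFAC and JASPAR counts are row-normalised, MEME
probabilities taken as given). Scoring matrices are smoothed log2
likelihood ratios against a 0-order background:

```
llr[i, b] = log2( (n[i,b] + pc * bg[b]) / (N[i] + pc) / bg[b] )
```

* **Background**: uniform (0.25 each) by default — the reproducible
  choice; a 0-order background estimated from the scanned sequences is
  available (`background = "sequence"`).
* **Pseudocount** `pc = 0.1`, a common scanner default; with `pc = 0`,
  zero cells are floored at probability 1e-6 so scores stay finite
  (about -17.9 bits against a uniform background), which keeps the
  discretised score range bounded.

Score p-values are exact under the background model: the distribution of
the score of a random width-`w` word is computed by dynamic programming
over scores discretised to `granularity` bins (default 1000) spanning the
achievable range. Window p-values looked up during scanning use the
integer score grid directly, so identical window scores always receive
identical p-values on either strand. The standalone score-to-p map is
conservative to within the discretisation: its value at `s` is bracketed
by the exact tail probabilities at `s ± w * bin_width`. The test suite
verifies this bracket against exhaustive enumeration of all `4^w` words.

Both strands are scanned (the reverse strand scores the reverse complement
of each window, reported at the forward-strand offset); windows containing
an ambiguous base never match. A degenerate matrix in which every word
scores identically is rejected for scanning as uninformative.

Hit q-values are Benjamini–Hochberg over `n_tests = 2 * sum(L - w + 1)`
scanned positions. Regions are counted as "with hit" on the raw p-value
filter by default; counting on `q <= 0.05` is available
(`count_filter = "q"`), since the two filters coincide at the default
threshold in the regime the pipeline targets.

The default scan threshold 3.73e-6 sits inside the plateau where the odds
ratio is insensitive to the exact threshold; `sweep_thresholds()` recomputes
the enrichment over a threshold grid, reusing one scoring pass per
sequence set, to check that stability on any given dataset. On the
scaled-down synthetic worlds used here the plateau is narrower than on
genome-scale data: at the loose end of the grid (1e-4) chance hits cover a
large fraction of 3.4-kb regions and dilute the odds ratio toward 1, which
is visible in the sweep output rather than hidden.

## GO gap statistic

Term-term similarity is the Wang graph measure: S-values over a term's
ancestor closure (`S_t(t) = 1`, `S_t(a) = max over children c on paths to
t of w_edge * S_t(c)`) with edge weights 0.8 (`is_a`) and 0.6 (`part_of`),
both configurable; similarity is the summed S-values over common ancestors
divided by the two total semantic values. This graph-based measure is the
standard choice for GO term similarity of this kind; no
information-content (Resnik/Lin) variant is provided, and no classical
hypergeometric enrichment — the screening statistic is the *gap*
`(S(t,HG) - S(t,G)) / S(t,G)`.

Conventions where the definitions leave room:

* Cross-namespace similarity is 0; ranking is restricted to one namespace
  (default `biological_process`).
* Genes without annotations are dropped from both HG and G before
  averaging — `S(t, g)` divides by `|T(g)|`, so scoring them 0 would
  conflate "unannotated" with "dissimilar".
* `gap` at `S(t, G) = 0` is defined as 0 with a warning rather than ±Inf.
* The candidate-term universe for ranking is every term annotating at
  least one background gene plus all ancestors, so regulatory parents can
  surface even when only their children are annotated directly.
* Gene-to-reference-term scores (for recombination-related reference terms
  such as GO:0006310, DNA recombination, and GO:0007127, meiosis I — term
  ids taken as authoritative over labels) are the arithmetic mean of
  `S(t, g)` over the reference terms.
* Ranking ties are broken by term id for determinism.

## Coverage graph

`HS(g)` is the set of hotspots covered by at least one hit of gene `g`'s
motif; `|HS(g)|` equals the gene's `HM`. Edges carry the meet/min
coefficient, and two clusterings are offered: components after filtering
edges with `w >= w_t` (the inclusive comparison, default `w_t = 0.16`),
and agglomerative clustering on `1 - w`. Average linkage is the default
(the common choice for similarity-derived distances; single and complete
are available). `stats::hclust` provides the agglomeration; given a fixed
input order its merge order is deterministic, which is the determinism the
pipeline needs. Cluster lists are always reported largest-first with
lexicographic tie-breaks. Coverage summaries emit per-cluster unions, all
pairwise intersections and the full Venn-region decomposition, so any
sharing question can be answered from the output without re-running.

## The synthetic world and what it does (not) show

The generator builds: uniform i.i.d. ACGT chromosomes; hotspots placed one
per equal-width slot with a uniform offset, which guarantees pairwise gaps
of at least `2 * min_distance` so valid coldspots always exist; exact
consensus copies planted per hotspot with probability `p_hot`; background
copies either planted per region sequence with probability `p_cold`
(`plant_in_sequences`, the exact per-window Bernoulli contract, used by
the recovery experiments) or dropped genome-wide as a Poisson process over
the coldspot-eligible zones at per-bp density `-log(1 - p_cold)/(L - w + 1)`
(`plant_motifs`), calibrated so a uniformly placed length-`L` window
contains a full copy with probability exactly `p_cold` — a stationary
process has no tile-boundary bias. Planted copies are exact consensus so
scan sensitivity is decoupled from enrichment recovery; the scanning
motifs carry degeneracy 0.1 to keep the scoring realistic.

The toy GO world is a balanced `is_a` tree under one
`biological_process` root. Enriched genes are annotated round-robin inside
a marked depth-1 subtree; background genes round-robin across all leaves;
in the null mode each "enriched" gene instead receives leaves evenly
strided across the whole tree, so no subtree is over-represented. All
assignments are deterministic, which is what makes the "every marked term
outranks every unmarked term" check exact rather than statistical.

Defaults: hotspot length 3414 bp (the scale of experimentally mapped mouse
hotspots), 50 kb exclusion distance, 20 coldspot replicates, threshold
3.73e-6, candidate filter `O_hc > 1.20` and `p < 0.05`, coverage threshold
0.16. The default *problem sizes* are scaled to a workstation: 4
chromosomes of 6 Mb with 200 hotspots for the end-to-end world, 5000
regions of 500 bp per arm for the odds-ratio recovery experiment, a
10-Mb genome for the coldspot-validity sweep. At a few hundred regions the
planted rate contrasts must be larger (e.g. 0.45 vs 0.18) than the subtle
enrichments detectable on ~10^4 real hotspots, or the chi-square filter
has no power; the recovery experiment instead uses exactly the 0.25 vs
0.20 contrast at 5000 regions, where the analytic odds ratio is 4/3 and a
chance-hit-corrected Monte-Carlo interval provides the acceptance band.

What passing these tests shows: the estimator machinery is correct — the
scanner finds what is planted at the advertised false-positive rate, the
odds ratio recovers planted contrasts, the gap statistic recovers planted
functional structure, the clusterings agree with brute force. What it does
not show: behaviour on real genomes with repeat structure, GC
heterogeneity, soft-masking and correlated hotspot placement, none of
which the generator emulates; nor the biological truth of any specific
candidate. Real scans also depend on the exact smoothing and background of
the scanner used, so third-party hit counts are reproducible only to the
extent those conventions match.

## Numerical and degenerate-input conventions

* Odds ratio flags instead of errors: `HN = 0` or `CM = 0` yields `Inf`
  with flag `infinite_odds`; `HM = 0` yields 0 with `zero_numerator`.
  A fully saturating scan threshold therefore reports the flagged
  degenerate table rather than a conventional value.
* Chi-square: the Yates correction term is floored so the corrected
  difference is never negative; zero marginals return a `degenerate` flag
  with `chi2 = 0`, `p = 1`.
* Odds ratios are kept at full precision and rounded (3 decimals) only in
  printed reports.
* All stochastic stages run under a single configuration seed; repeated
  runs with the same configuration produce byte-identical outputs, and all
  persisted tables carry the hash of the producing configuration.

## Interfaces

The package is library-first: `run_pipeline()` over a `pipeline_config()`
is the main entry point, returning a classed result with print and summary
methods, and each stage is an exported function usable on its own.
`inst/scripts/hotspot-transreg.R` wraps the pipeline for shell use (YAML
config in, TSV reports out); `scripts/acceptance.R` recomputes the
package's headline numbers from scratch.

## Limitations

Motif matching is gapless — no insertions/deletions and no
nucleotide-adjacency dependencies; proteins whose sites contain indels
need a different matcher. Coldspot sampling assumes the genome has room
for length-matched controls outside the exclusion zones and fails loudly
when it does not. The Wang similarity is computed exactly but naively
(per-term S-value closures); it is comfortable at toy-ontology and
GO-slim scale, not tuned for the full GO graph. Hotspot inference itself
(from LD or pedigree data) is out of scope: hotspot intervals are inputs.
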