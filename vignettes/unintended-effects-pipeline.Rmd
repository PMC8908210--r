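---
title: "Assessing unintended effects of RNAi crops: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing unintended effects of RNAi crops: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siromics)
```

## The problem

An RNAi-based insect-resistant crop carries an inverted-repeat transgene
whose transcript folds back on itself into double-stranded RNA (dsRNA).
Dicer-like proteins process this dsRNA into 21–24 nt short interfering RNAs
(siRNAs) that guide sequence-specific silencing of the target pest gene.
Two questions follow for biosafety assessment:

1. **Off-target potential.** Could any of those siRNAs silence a host
   transcript? Silencing tolerates a small number of mismatches, so the
   question becomes: which transcripts carry a site within a small Hamming
   distance of some 21–24-mer of the construct?
2. **Substantial equivalence.** Do the GE lines differ from their parent —
   in gene expression and metabolite accumulation — by more than
   conventional breeding lines differ from each other? This is answered by
   a pairwise comparison design over GE, parent and conventional lines,
   with differential calling, multivariate structure, shared/unique set
   logic and pathway over-representation.

`siromics` implements both, plus a synthetic-data module that generates
every input with known planted truth. All empirical statements below are
properties the test suite or `scripts/acceptance.R` actually computes.

## Mock library and Hamming-bounded scan

`enumerate_kmers()` cuts every k-mer for k = 21..24 from both strands of
the construct (both strands of a dsRNA are diced, so both contribute
candidate guides; a flag restricts to the sense strand). An L-nt construct
yields exactly L − k + 1 k-mers per k and strand; antisense k-mers are
reverse complements indexed on sense coordinates so every candidate maps
back to one construct window.

`hamming_search()` reports every (k-mer, transcript, offset) whose
**ungapped** Hamming distance is at most `max_mm` (default 2, the mismatch
budget conventional for siRNA off-target screens). "Within two bases" is
interpreted as substitutions only — gapped near-matches change the
guide/target register and are not silencing-competent in the same way, and
the companion read-to-construct alignment convention in this workflow is
explicitly gap-free. The implementation is seed-and-extend: by the
pigeonhole principle a match with at most m substitutions of a k-mer
contains an exact seed of length ⌊k/(m+1)⌋ at one of m+1 fixed offsets, so
the scanner indexes all seed-length words of the transcripts (2-bit packed,
in C++), looks up each query chunk and verifies candidates by direct
distance count. Three implementations coexist deliberately: the C++ hot
path, a pure-R reference of the same index algorithm
(`method = "rseed"`), and a brute-force all-offsets oracle in the test
suite; property tests assert their equivalence on random instances, along
with monotonicity in `max_mm`, strand symmetry, and a distance recheck on
every emitted hit.

Conventions worth stating once: coordinates are 0-based half-open
internally and 1-based inclusive in written reports (the report header
records this); duplicate k-mer sequences are matched once and hits
attributed to all source positions; transcripts containing non-DNA
characters are scanned over their valid stretches and fully invalid records
are skipped with a warning.

`combine_offtargets()` aggregates hits per transcript by minimum mismatch
and emits cumulative tier counts (genes at ≤0, ≤1, ≤2 mismatches). Because
it is unstated in the motivating workflow whether candidate genes require
evidence that the matching siRNA was actually sequenced, both evidence
modes are provided — `all_mock` (any library k-mer) and `expressed_only`
(k-mer or its reverse complement observed among expressed reads) — and
neither is asserted to reproduce any published gene count.

## Expressed siRNA profile

Reads are length-filtered to 18–30 nt (inclusive), collapsed to unique
sequences with multiplicities, and mapped to the construct requiring an
**exact** match on either strand (0 gaps and 0 mismatches): the aim is to
profile only reads demonstrably derived from the transgene, so partial
matches are excluded by construction. All occurrences of multi-mapping
reads are reported and flagged; coverage counts (read, occurrence) pairs,
while the size distribution counts each read once.

The base-preference matrix over k-length reads (default k = 21, the Dicer
product that dominates functional populations) is a position frequency
matrix weighted by read counts; each row is a probability vector and the
per-position information content is `2 − H(p)` bits with no small-sample
correction, hence bounded [0, 2]. GC fraction is computed over all bases of
the used reads and the 5′ A/U fraction over positions 1–5 — elevated 5′
A/U is associated with favourable guide-strand loading. A `min_count`
parameter (default 1) controls which reads qualify as "enriched" for this
matrix, since any abundance threshold here is a display choice, not a
statistic. `abundance_ratio()` compares total mapped counts between
libraries (e.g. GE versus non-GE), with an explicit pseudocount convention
`(a + c)/c` when the denominator is zero.

## Differential calling

Both omics stages share one univariate machinery on features × samples
matrices with replicate groups:

* **Expression (DEGs):** fold change is the ratio of group mean
  intensities; the test is a two-sided pooled-variance t on
  `log2(x + 1)`; p-values are BH-adjusted across the comparison's full
  feature set; the call is `padj < 0.05` **and** FC ≥ 2 or ≤ 0.5
  (inclusive bounds).
* **Metabolites (DAMs):** after deleting any feature whose missing
  fraction exceeds 50 % (strict) in *some* replicate group, the call is
  FC > 2 or < 0.5 (strict bounds) **and** raw p < 0.05; the pseudocount for
  the log transform defaults to half the smallest positive intensity.
  OPLS-DA VIP values can be attached for annotation but never enter the
  call. Accurate-mass identification support (`ppm_match()`) is strict at
  the tolerance: 25.0 ppm against a 25 ppm tolerance is not a match, with
  the boundary decided to double precision.

The inclusive-vs-strict asymmetry between the two stages is intentional and
mirrors how the respective screening conventions are usually stated; both
thresholds are parameters.

**Choice of t statistic.** The default is the pooled (Student) t on the
log2 scale rather than Welch's unequal-variance t. With three replicates
per line, Welch's Satterthwaite degrees of freedom fall to ~2–4 and the
screen becomes measurably conservative — in simulation its raw-p
false-positive rate sits near 0.035 at a nominal 0.05, and recovery of
planted 8-fold effects drops to ~80 %. Under the balanced design the pooled
t is exactly calibrated (measured FPR ≈ 0.049, recovery 100 % at
|log2FC| = 3, dispersion 0.25), and the classical small-sample verification
convention in this field is a Student t. `mode = "welch_log2"` remains
available for unbalanced or heteroscedastic data.

`fpkm()` and `ddct_relative_expression()` implement the standard
normalisations (`count·10⁹/(library·length)`; `2^−ΔΔCt`), used when raw
counts or qPCR Ct values are the input.

## Multivariate stages

Pareto scaling divides each centred feature by the square root of its
sample standard deviation — stronger than plain centring, gentler than
unit variance, the usual compromise for mass-spectrometry intensities where
high-abundance ions would otherwise dominate. Zero-variance features scale
to zeros and are flagged rather than erroring, since flat ion traces are
routine. The scaling object retains means and factors; recomposition is
exact (tested to 1e-9).

PCA is the SVD of the column-centred samples × features matrix; loading
signs are fixed (largest-magnitude entry positive) so results are
deterministic. Explained-variance fractions sum to 1 over the full rank.
Hierarchical clustering (`hcluster()`) offers Euclidean or 1 − Pearson
distance with average or complete linkage; columns are sorted by id before
clustering so the tree is invariant to input order. Defaults in the
pipeline: 1 − Pearson for expression (profiles matter more than magnitude),
Euclidean on Pareto-scaled values for metabolites. Dendrograms export to
Newick via `ape`.

OPLS-DA follows the orthogonal-signal-correction scheme: `n_orthogonal`
rounds (default 1) remove class-uncorrelated variation from X, then one
predictive PLS component is fitted against the centred two-class vector.
With a single predictive component the VIP reduces to
`VIP_j = √p · |w_j| / ‖w‖`, which pins mean(VIP²) = 1 — a normalisation the
tests assert on every fit. The number of orthogonal components and any
cross-validation are exposed as parameters, never asserted: the reference
implementations in commercial software are not reproducible from their
descriptions. With `n_orthogonal = 0` the model is a one-component PLS-DA,
which is the configuration cross-checked against an independent
implementation (mixOmics) in the test suite.

## Comparison design, set logic and enrichment

`build_design()` enumerates all unordered line pairs and labels each by
role pair: GE/parent (group 1), conventional/parent and
conventional/conventional (group 2 — together they measure the span of
conventional variation), GE/GE (group 3), GE/conventional (group 4). The
default six-line design yields 15 comparisons split 3/3/3/6. Labels are
written derived-line-first (`DTS_108/TJ806`, `AR02/TJ806`), matching the
field convention that fold changes read test-over-reference.

`shared_unique()` produces the full disjoint Venn decomposition for 2–4
named sets (the arity of the usual figures); regions partition the union,
which the tests assert by cardinality conservation.

`hypergeom_ora()` tests each annotation term by the upper-tail
hypergeometric `P(X ≥ ListHits)` — ≥, not > — with BH adjustment across
terms within one list (not across comparisons, which would mix designs).
The universe defaults to the annotated features and should generally be the
intersection of the annotation with the assayed features: published
`PopTotal` values far below the full gene count imply exactly such an
annotated-subset universe, and the choice is configurable and recorded.
The fold-enrichment score `(ListHits/ListTotal)/(PopHits/PopTotal)` is
reported to 4 decimals alongside full precision; `expected_hits()` gives
the hypergeometric mean `ListTotal·PopHits/PopTotal`. The score column of a
published pathway table is reproducible exactly from its printed margins
(asserted row by row in the tests); its printed p-values are not consistent
with any hypergeometric tail on those margins, so only the score is
asserted.

## The synthetic study: what it emulates, and what it cannot show

`default_config()` parameterises a study shaped like the motivating maize
assessment: an 876-nt construct at GC 0.5; six lines (three GE, one parent,
two conventional) × three replicates; transcript sets with off-target sites
planted at exact Hamming distances 0–3; read sets with 70 % of mass at
21 nt and 5 % random background; 400 expression and 300 metabolite features
with planted 8-fold effects and 10 % MCAR missingness; 20 annotation terms
with one over-drawn term.

Choices the source material does not determine, fixed once:

* **Replicate noise** — log-normal with sd 0.25 on the log2 scale
  (≈ 19 % CV), a typical biological coefficient of variation for leaf
  tissue pools; exposed as `rep_sd` because no published dispersion exists
  to copy. The negative-binomial count path is out of scope here: all
  downstream statistics operate on FPKM-like intensities.
* **Missingness** — missing completely at random; real LC-MS missingness
  is partly intensity-dependent, so the missing-value filter is exercised,
  but imputation strategies are not stressed.
* **Hotspots** — read 5′ start positions are drawn on the sampled strand's
  own coordinates, strands 50/50; real Dicer processing has sequence
  preferences the generator does not model.
* **Seeds** — one integer seed per generator call; derived stage seeds are
  small offsets of the master seed; every generator restores the caller's
  RNG state.

Passing tests on this synthetic study demonstrate *algorithmic
correctness*: the scanner finds exactly the planted near-matches, the
callers are calibrated and powered under the stated noise model, the
planted term ranks first. They do not demonstrate anything about the
deposited study data — the published off-target gene count, metabolite
total, DEG/DAM ranges, PCA variance fractions, GC bias or siRNA abundance
ratio all depend on the proprietary construct sequence and deposited reads,
and are deliberately never asserted.

## Numerical choices and degenerate inputs

* Empty transcript sets, empty read sets and no-k-length-read profiles
  return empty results or flagged empty profiles, not errors; scans of
  invalid records warn and skip.
* Degenerate group tests (one finite value, or zero variance in both
  groups) yield p = 1 with a flag.
* Fold changes with an all-missing group are NA and never called.
* Problem sizes in the tests and acceptance script (1,000-feature
  calibration runs, ~100-instance oracle sweeps, 4,000–6,000-read
  profiles) were chosen so the whole suite completes in about a minute
  while keeping binomial error bands on the calibrated rates tight enough
  to be meaningful (3 SDs on 1,000 nulls is ±0.021 around 0.05).

## Known limitations

* No thermodynamic or seed-region siRNA efficacy scoring: a Hamming match
  flags a candidate, it does not predict silencing; candidates require
  experimental verification.
* Terms are flat sets — no GO graph propagation.
* OPLS-DA is two-class only, matching its use here.
* The scanner is designed for construct-scale query sets against
  transcript sets, not genome-scale alignment.
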