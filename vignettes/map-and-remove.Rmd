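---
title: "Classifying exogenous RNA in plasma small-RNA sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying exogenous RNA in plasma small-RNA sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exosieve)
library(tibble)
```

## The model

Plasma small-RNA libraries contain short reads (16–35 nt post-trim,
typically ~23 nt) from many genomes at once. `exosieve` assigns each read
to exactly one source category by a **map-and-remove cascade**: an ordered
list of reference tiers is searched one at a time, and a read with at
least one valid placement in the current tier receives that tier's
category and leaves the stream; it is never tested against later tiers.
Survivors of the last tier are `unmapped`. The canonical order
(`default_tier_spec()`) is host miRNA, host transcripts, host genome,
microbiome, exogenous miRNA, broad nucleotide collection.

Mismatch tolerance is asymmetric by design. The host tiers for transcripts
and genome accept 0, 1 or 2 mismatches — the run-level **strategy** —
because host origin is the null hypothesis and sequencing errors should
not inflate the exogenous pool. The miRNA tiers are always exact (mature
miRNAs within a family differ by single bases, so any tolerance would
collapse families), and all exogenous tiers are always exact, keeping
foreign assignment maximally conservative. Two consequences are built into
the tests: the endogenous fraction is non-decreasing and every exogenous
fraction non-increasing in the strategy value, and category counts are
conserved at every stage.

Because assignment is "first tier with any hit", a read present verbatim
in both a host and a bacterial reference is counted as host. This is
deliberate: the pipeline measures the read mass *not explainable by the
host*, not microbial abundance.

## Exact k-mismatch matching

The matcher is exhaustive rather than heuristic, so a negative is a
guarantee, not a best effort. For reads of length $L$ and a budget
$m \in \{0,1,2\}$ the read is partitioned into $m+1$ contiguous segments
with lengths differing by at most one (e.g. $23 = 8 + 8 + 7$). A placement
with $\le m$ mismatches must leave at least one segment exact
(pigeonhole), so the candidate set produced by exact lookup of every
segment in sorted k-mer tables of the reference is complete; candidates
are then verified by full Hamming comparison and deduplicated. One table
is built per distinct segment length; lookups use 2-bit encoded keys
capped at 31 nt (relevant only for exact matching of reads longer than
31 nt, where the 31-mer prefix seeds the lookup and verification restores
exactness).

Strandedness follows the database kind: `genome`, `microbiome` and `nt`
are indexed on both strands (a minus-strand hit reports forward-strand
coordinates of the window whose reverse complement matches the read);
`miRNA`, `transcripts` and `exo_miRNA` are sense-only, matching how
stranded small-RNA libraries read out transcript pools. `N` never matches
anything, on either side — an `N` inside a read consumes one unit of the
mismatch budget at every placement.

Reads of different lengths are dispatched to per-length indexes by the
cascade, since the segmentation is length-specific. There are no gaps, no
soft clipping and no quality-aware scoring: the strategies are defined
purely by Hamming distance, and an indel-bearing read is simply expected
to fail all tiers and be counted `unmapped`.

The test suite holds the matcher to *set equality* with a naive
all-positions Hamming scan implemented independently (vectorized over
window starts), across database kinds, budgets and planted-error designs.

## Taxonomic resolution and structural-RNA masking

Within the winning tier, a read's hits are filtered to the minimal
mismatch count; if the survivors name one taxon the read is assigned to it
at that taxon's rank, otherwise to the lowest common ancestor of the
surviving taxa (best-hit-then-LCA). All-hit LCA was the alternative; the
best-hit rule was chosen because exogenous tiers are exact-match anyway
and species-level reporting is the point of the per-species tables. Reads
are flagged `structural_rna` when **any** surviving hit overlaps an
annotated rRNA/tRNA interval by at least one base — deliberately
conservative, since conserved structural RNAs are the dominant source of
cross-species misassignment. `mask_structural_rna()` removes flagged
assignments; re-rolling up reproduces the masked ("open bar") analysis,
and taxa observed only through conserved genes disappear from it, which
the tests construct explicitly.

Rollups count each assignment once at its ancestor of the requested rank;
assignments whose lineage lacks the rank (e.g. an LCA at kingdom level
rolled up to phylum) are reported as `unranked`, so totals are always
conserved. Across samples, mean counts are unweighted arithmetic means
with absent taxa counted as zero.

## The coincidence model

The negative-control argument — "foreign" assignments from a sterile
single-organism culture are attributable to sequencing error plus chance —
is formalized as an occupancy model. Under a background base composition
$(p_A,p_C,p_G,p_T)$ the per-base mismatch probability between two random
bases is $q = 1 - \sum_i p_i^2$ (uniform: $3/4$), a single position
accepts the read with probability
$p = \sum_{i \le m} \binom{L}{i} q^i (1-q)^{L-i}$, and a database offering
$N$ positions (strands × windows, summed over sequences) captures the read
with probability $1-(1-p)^N$, or $1-e^{-Np}$ in Poisson form. Positions
overlap and are therefore weakly dependent; the approximation error is
bounded in the tests by requiring exact and Poisson forms to agree within
1% whenever $Np < 0.01$ and by checking the closed form against
matcher-based Monte Carlo within three binomial standard errors. The
default background composition is the reference's empirical base
frequencies, which keeps the analytic and simulated models comparable on
non-uniform references.

At the study's scales the model predicts essential impossibility of false
exact exogenous matches: for $L = 23$, $m = 0$ and $N = 10^8$,
$Np \approx 1.4\times10^{-6}$.

## The synthetic-data generator

The generator stands in for raw sequencing data and defines the study
conditions; its defaults are fixed, not tuned:

* **Communities.** Tiered reference databases with per-species sequence
  counts, length ranges and GC content; a taxonomy table
  (taxid, parent, rank, name) in which every sequence's label resolves;
  and optional **conserved genes** — one master sequence copied into
  several species with independent per-base divergence (default designs
  use 2%, leaving copies ≥95% identical) and annotated as rRNA/tRNA
  features. This reproduces the cross-species rRNA/tRNA mapping that
  motivates masking.
* **Reads.** Component read counts are multinomial over normalized
  mixture weights; within a component, source sequences are drawn
  proportionally to their number of eligible start positions and starts
  are uniform (no positional bias is modeled). Transcript-kind sources
  are read sense-strand; genomic kinds from either strand with
  probability 1/2.
* **Errors.** Each cycle substitutes independently at the profile's
  per-cycle rate, replacements uniform over the three alternatives. The
  default `illumina_profile()` ramps linearly from 0.2% at cycle 1 to
  0.9% at the last cycle (mean ≈ 0.55%), a generic Illumina-like
  shape with error growing along the read and mean per-base error below
  1%. There is no indel, chimera or amplification-bias model: the
  cascade is defined purely by mismatch counts, so substitutions are the
  only error channel that matters to it. Quality strings are synthesized
  from the profile's per-cycle mean Phred scores but are cosmetic —
  substitution is governed solely by the rate vector.
* **Truth.** Every read carries its source sequence, interval, strand and
  substituted cycles, enabling exact accuracy scoring downstream.

What passing tests on this generator do **not** show about real data:
real libraries have non-uniform coverage, composition bias, indels,
adapters read-through into low-complexity tails, and references that are
incomplete or wrong. The generator's role is to verify the *pipeline's
logic* (completeness, conservation, monotonicity, masking) under known
truth, not to emulate platform physics.

## Preprocessing

Reads pass, in order: 3' adapter trimming (leftmost alignment of the
adapter prefix with overlap ≥ 5 nt and mismatch fraction ≤ 0.1), then
rejection with first-match-wins precedence — `adapter_only` (trimmed
empty), `too_short` (< 16 nt), `too_long` (> 35 nt), `polyA_only`
(A fraction ≥ 0.9), `low_quality` (mean Phred < 20). The length window,
quality and polyA thresholds are declared package defaults typical for
small-RNA work; the fixed precedence makes rejection summaries
deterministic, and summaries always satisfy kept + rejected = input.
Non-ACGTN characters are a data error naming the read, rather than a
silent drop.

## Numerical and degenerate-input choices

* Fixed seeds drive every random step; identical seed + configuration
  gives byte-identical FASTQ output.
* Zero processed reads make category fractions an error (undefined), not
  a table of `NaN`.
* A fold ratio with a zero denominator mean is an error; no pseudocount
  fallback is applied.
* Reads longer than every reference sequence simply produce no hits.
* Ties in adapter trimming resolve to the leftmost acceptable position.
* Exogenous miRNA tables collapse database entries with identical mature
  sequences into one row (names joined); a read contributes once per
  identity group it hits. Exact-sequence equality is the declared
  collapse rule.

## Validation experiments and problem sizes

Two built-in experiments (`simulated_mapping_rate()`,
`simulated_false_exogenous_rate()`) are the package's own calibration of
the cascade, used by the test suite and by `scripts/acceptance.R`:

1. **Mapping completeness** — 2,000 random transcripts of 0.5–2 kb,
   100,000 reads of 23 nt under the default error profile, classified
   against the source transcriptome at strategy 2. Because the matcher is
   exhaustive, every read with ≤ 2 substitutions is guaranteed to map;
   the shortfall from 100% is essentially the binomial tail
   $P(\text{errors} \ge 3) \approx 3\times10^{-4}$, so the mapped
   fraction sits comfortably above 98%.
2. **False exogenous rate** — a 12 Mb synthetic host genome, 200,000
   reads at a flat 0.5% per-cycle substitution rate, cascaded against
   ~50 Mb of independently generated exogenous genomes (a microbiome
   tier and an nt tier, both exact-match) after host subtraction at
   strategy 2. The coincidence model predicts a false-exogenous
   probability of order $10^{-6}$ per read; the observed percentage is
   far below the 0.15% benchmark, with the ~0.02% unmapped residue again
   matching the ≥3-error binomial tail.

These sizes keep each experiment within a few minutes on one CPU while
leaving the statistical conclusions unchanged from larger designs (both
quantities are governed by per-read probabilities, not corpus size).

## Known limitations

* No gapped alignment: an indel-bearing read cannot rescue into its true
  source and will be counted `unmapped` (or, with vanishing probability,
  elsewhere).
* Multi-mapping within a tier is resolved by LCA, not by abundance
  weighting; no genome-size correction is applied to rollups.
* The coincidence model assumes independent positions and a homogeneous
  background composition along sequences.
* The taxonomy reader expects the simplified 4-column table; full NCBI
  dump parsing is out of scope.
* The cascade holds all tier indexes for one read length in memory one at
  a time; at multi-gigabase reference scale a disk-backed index would be
  needed.
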