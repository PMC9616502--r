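---
title: "Methods: satellite-array binding, divergence and enrichment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite-array binding, divergence and enrichment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`satrep` analyses the regulatory state of a satellite DNA family from
interval and coverage data: which copies a chromatin factor binds, how
bound and unbound copies differ, whether peak–feature overlap exceeds a
randomization null, and how coverage signal distributes over the repeats.
This vignette is the package's own account of the underlying models, the
defaults, the numerical choices, and what the accompanying tests do and do
not demonstrate.

## Coordinate model

All file I/O uses BED/bedGraph conventions (0-based, half-open); in
memory, intervals live in `GRanges` (1-based, closed) validated against a
`Seqinfo` genome layout. Two conventions are fixed package-wide and worth
stating once:

* *Overlap* requires at least one shared base. Abutting intervals
  `[a,b)`, `[b,c)` therefore do **not** overlap, but `merge_intervals()`
  does merge them — the standard interval-set semantics that make binding
  classification unambiguous at copy boundaries.
* Strand never affects overlap computations; it only orients sequence
  extraction and signal-matrix rows.
* Chromosomes absent from the layout are a hard error in every reader.
  Silently dropping them would shrink the genome term of the enrichment
  expectation and quietly bias every O/E ratio.

## Binding classification

A repeat copy is *bound* when it shares ≥ `min_overlap` bases with the
merged peak set. The default `min_overlap = 1` bp is the loosest criterion
that is still reproducible; it is a flag, not a constant, because
peak-caller boundary noise may warrant a stricter threshold on real data.
The partition `n_bound + n_unbound = n_copies` holds on every input and is
property-tested.

## Consensus and percent divergence

The family consensus is rebuilt by an **iterative star alignment**:

1. Seed with the sequence whose length is closest to the group median
   (deterministic; robust against truncated copies dominating the seed).
2. Align every copy to the current consensus with Needleman–Wunsch
   (match +1, mismatch −1, gap −2, linear gaps). Insertions relative to
   the consensus are ignored; each consensus column collects one
   base-or-gap per copy.
3. Emit the per-column majority base; drop columns where ≥ 50% of copies
   carry a gap. Repeat until the consensus is unchanged (`max_rounds`
   default 5).

This is deliberately simpler than a profile-HMM: it is deterministic,
dependency-free, and accurate enough that on 50 copies mutated at 5%
substitutions + 0.2% indels from a 200-bp truth, the rebuilt consensus
lands within Hamming distance 2 of the truth (tested). Its known failure
mode: a deletion present in the seed cannot be regained in later rounds,
since insertions relative to the consensus are never promoted to new
columns. With per-copy deletion rates ≤ 0.1% per base this costs at most
a column or two.

**Percent divergence** is `100 · mismatches / (matches + mismatches)` over
non-gap columns — a plain substitution proportion, with no Kimura or CpG
correction, which is what repeat-annotation "% divergence" columns
approximate and exactly what the generator's truth records.

One subtlety matters for satellites: copies usually span *several tandem
units* of the consensus. Globally aligning a multi-unit copy against the
bare unit leaves hundreds of gap columns whose placement is free, and the
optimal path uses that freedom to route around substituted bases — in
testing, 5% true divergence measured as ~0.7%. `copy_divergence()`
therefore tiles the consensus tandemly to the copy's length before
aligning (flag `tandem`), which removes the bias (recovery within
Monte-Carlo error is property-tested). The phase is taken from the
annotation start; partially phased copies are absorbed by the alignment's
gap handling.

Alignment tie-breaking is fixed (diagonal, then gap-in-second-sequence,
then gap-in-first), so alignments — not just scores — are reproducible
across platforms. Scores are verified against exhaustive enumeration for
short pairs and against an independent aligner (`Biostrings`) for long
ones.

## Group comparison

`group_summary()` reports per-group n/mean/SD and histogram counts for
copy length and divergence, and a **two-sided pooled-variance Student
t-test** per metric (`df = n₁ + n₂ − 2`). Pooled is the classical
"unpaired Student" form; the Welch variant is available via
`var_equal = FALSE` for unequal-variance data. Degenerate inputs follow
explicit conventions: both groups constant and equal gives t = 0, p = 1;
constant but different gives an infinite t. The implementation is the
textbook formula, cross-checked in tests against `stats::t.test` and
verified to produce uniform p-values under the null.

## Randomization overlap enrichment

Given query and reference interval sets on a layout:

* **Observed** O = number of query intervals with ≥ `min_overlap` shared
  bases against the merged reference (a total-shared-bases statistic is
  available behind the `statistic` flag).
* **Null**: each query interval is re-placed uniformly with its length
  preserved, N times (default 1000). `same_chromosome` mode (default)
  keeps every interval on its own chromosome — conservative for clustered
  satellites, since it preserves chromosome-level composition —
  `genome_wide` draws the chromosome with probability proportional to its
  number of valid start positions. The randomization unit is the
  interval, not the whole set; both modes are logged in the result.
* **p-value**: with b = #{i : Oᵢ > O} (strictly greater — ties never count
  against the query),

  p = (1 + b) / (1 + N).

  The add-one appears in numerator *and* denominator, so p ∈ [1/(N+1), 1]
  and can never be zero; at N = 1000 the floor is 1/1001 ≈ 0.000999. This
  denominator choice is deliberate and prominently documented: it is the
  standard bias-corrected empirical p-value, it is super-uniform under
  the null (simulation-tested), and it is what the reported minimum
  attainable value implies.
* **Expectation**: E = |query| · coverage_fraction(reference). This
  covered-proportion definition ignores the finite width of query
  intervals; for wide queries the true null hit probability is slightly
  larger, so O/E is mildly anti-conservative there. The bias is
  documented rather than corrected because E is defined on the
  covered-proportion basis; for 1-bp queries the Monte-Carlo agreement is
  within 2% (tested).

Reproducibility: one seed per test; randomization *i* consumes its own
pre-derived substream seed, so results are independent of execution order
and a result object can be regenerated exactly from its echoed seed.

## Coverage aggregation

Tracks are per-chromosome step functions (`RleList`); bedGraph is the
canonical on-disk format and positions without a run read as zero.

* **Fold enrichment**: per-base `(signal + ε)/(control + ε)` on the union
  of breakpoints. The default pseudocount ε is 1% of the control track's
  mean non-zero value — scale-aware, so empty-control regions do not
  explode — and is a flag, since no universally right constant exists.
* **Signal matrices**: flanks are fixed `bin_size` windows (default
  100 bp); the feature body is scaled to `body_bins` equal-width segments
  with fractional-bp boundaries handled by linear weighting of the
  per-base integral, so features of any length share one column space.
  Out-of-chromosome flank positions read 0. Minus-strand rows are
  reversed when `strand_oriented` (default), putting 5' at column 1.
* **Trimmed-mean profiles**: per column, the lowest and highest
  `ceiling(n · q)` ranks (q = trim/100, default 0.5%) define nearest-rank
  cutoff values and rows strictly outside the closed cutoff band are
  dropped. This convention trims symmetric counts from a symmetric set
  (so the mean of 1…1000 under a 0.5% trim stays 500.5), reduces to the
  plain column mean at trim 0, and is deterministic across platforms. All
  aggregation paths are tested for exact (1e-9) agreement with naive
  per-base oracles.
* **Per-feature means** cover **body bins only** — flanks are display
  context, not part of the feature. Whether real-data summaries include
  flanks is genuinely ambiguous, so this is a documented default rather
  than a hidden choice. Heatmap ordering (descending row mean) is emitted
  as metadata via `signal_row_order()`; rendering itself is a minimal
  convenience (`plot()` on a profile).
* **Occupancy subsets**: a base is *present* in a condition when covered
  by ≥ `min_replicate_support` (default 2) of its individually merged
  replicate sets. The universe partitioned into a-only / b-only / shared
  is the union of the two condition presence sets: with support > 1, bases
  supported in neither condition exist and belong to no subset, so the
  partition is defined over supported space — this keeps
  disjointness-plus-exhaustiveness an invariant instead of an
  approximation.
* **Repeat-class fractions**: overlapping or nested annotation classes are
  resolved per base by widest-interval precedence (ties by class name,
  then input order), making the classes a partition so that per-subset
  fractions plus an `unannotated` remainder sum to exactly 1.
* **Expression utilities**: TPM (`1e6 · rate/Σrate`, conserving one
  million) and −ΔΔCt fold changes (`2^(−ΔΔCt)`) for count tables and qPCR
  cycle values.

## The synthetic data generator

`generate_dataset()` emulates the joint structure the analysis assumes:

* a satellite family whose **bound copies are longer (mean 2500 bp,
  SD 200) and less diverged (5% substitutions)** than unbound copies
  (800 bp, SD 200, 15%), with 0.2% single-base indels;
* bound copies clustered into arrays (inter-copy gaps 200–2000 bp) on 2
  of 5 chromosomes, unbound copies scattered genome-wide, all copies
  disjoint (rejection sampling with a retry cap and an informative
  does-not-fit error);
* peaks covering bound copies with configurable recall/false-positive
  rates (defaults 1.0 / 0.0);
* Poisson coverage tracks with per-base mean `background · enrichment`
  inside features: a high-enrichment "control" (8×), a lower "depleted"
  condition (3×), a flat IgG-like control (1×), and RNA-like tracks over
  all loci; condition peak sets for the occupancy analysis model the
  depleted condition retaining 40% of bound-copy peaks.

Default problem sizes (5 × 300 kb chromosomes, 100 + 200 copies) are desk
scale: large enough for the group tests to be decisive and the arrays to
be array-like, small enough that the full suite runs in minutes. One
master seed fans out to per-component substreams, so adding a track never
perturbs copy placement and a fixed seed yields byte-identical files
(tested).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mappability and alignment artifacts, copy
number at genome scale, CpG-biased or transition-biased substitution,
long indels and internal rearrangements of arrays, overdispersed
(non-Poisson) coverage, correlated replicate noise, and peak-caller
boundary behaviour. Tests on this generator demonstrate *recovery of
designed effects and internal consistency*, not genome-scale counts or
p-values, which depend on external data and tools outside this package's
scope.

## Pipeline and reproducibility

`run_pipeline()` executes generation → classification → consensus and
divergence → group summary → enrichment → signal aggregation → occupancy
from a single validated config (YAML or list; unknown keys rejected, all
range violations reported at once) and one seed. Every number in
`report.json` is also present in a written output file, and re-running
with the echoed config and seed reproduces the report exactly. A stage
failure aborts with the stage name and leaves a `FAILED_<stage>` marker
beside the partial outputs. The analysis stages never see the generator's
truth labels; classification is recomputed from the peak files.

## Known limitations

* The star consensus is a majority heuristic, not an optimal multiple
  alignment; highly indel-rich families would need a profile method.
* E ignores query width (documented above); gap/exclusion masks and
  GC-matched nulls are out of scope.
* Pairwise alignment is O(len₁·len₂) memory; copies beyond ~50 kb would
  need a banded variant.
* bigWig I/O is not provided; bedGraph is the canonical track format
  here.
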