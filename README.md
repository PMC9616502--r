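# satrep

Satellite DNA arrays — tandemly repeated sequences that can coat megabase
stretches of a chromosome — are silenced by sequence-specific KRAB-zinc
finger proteins (KZFPs) that recruit TRIM28/SETDB1 heterochromatin
machinery. Analysing such an array from ChIP-seq or CUT&RUN data raises a
recurring set of questions: which repeat copies does the factor actually
bind, how do bound and unbound copies differ in length and in divergence
from the family consensus, is the overlap between two peak sets larger than
chance, and how does coverage signal behave over the repeats under
different conditions?

`satrep` is an R package (GenomicRanges/Bioconductor idiom) that answers
those questions with a tested, reusable pipeline, for genomicists working
on repeat regulation. It ships a deterministic synthetic genome generator
so every stage can be exercised — and its statistical guarantees verified —
without downloading any external data.

## What it computes

* **Binding classification** — a repeat copy is *bound* iff it shares at
  least `min_overlap` bases (default 1) with the merged peak set;
  `n_bound + n_unbound` always equals the copy total.
* **Consensus and percent divergence** — an iterative star-alignment
  majority consensus (Needleman–Wunsch global alignment, linear gaps,
  deterministic tie-breaks), and per-copy divergence
  `d = 100 · mismatches / (matches + mismatches)` over non-gap columns,
  with the consensus tiled tandemly across multi-unit copies. Group
  differences are tested with the classical pooled-variance Student
  *t*-test (Welch behind a flag).
* **Randomization overlap enrichment** — observed count *O* of query
  intervals overlapping a reference set, *N* length-preserving uniform
  re-placements, exceedance count *b* = #{*Oᵢ* > *O*}, and the one-sided
  **add-one empirical p-value**

  p = (1 + b) / (1 + N),

  whose minimum at N = 1000 is 1/1001 ≈ 0.000999. The expected count is
  E = |query| · (fraction of the genome covered by the reference), and the
  enrichment is reported as the ratio O/E.
* **Signal aggregation** — features × bins matrices from bedGraph coverage
  (fixed flank bins, bodies scaled to a common bin count), per-bin
  **trimmed means** (default: top and bottom 0.5th percentiles excluded),
  per-feature means over body bins, IgG-normalized fold-enrichment tracks,
  top-k peak selection, occupancy subsets across replicated conditions
  with repeat-class length fractions, plus TPM and −ΔΔCt utilities.

## Worked example

```r
library(satrep)

cfg <- synthetic_config(seed = 1)       # the documented study conditions
ds  <- generate_dataset(cfg)
ds
#> <synthetic_dataset> seed 1: 5 chromosomes (1,500,000 bp),
#>   100 bound + 200 unbound copies, 5 tracks

peaks  <- merge_intervals(do.call(c, ds$peaks$binding))
copies <- classify_copies(ds$repeats, peaks, min_overlap = 1)
seqs   <- extract_repeat_sequences(ds$genome, copies)

consensus <- build_consensus(seqs[seq(1, 300, by = 5)], max_rounds = 5)
consensus
#> <consensus_model> 887 bp consensus after 5 round(s)

mcols(copies)$divergence <- copy_divergence(seqs, consensus$consensus)
group_summary(copies)
#>    group   n mean_length sd_length mean_divergence sd_divergence
#>    bound 100     2490.44   195.284        9.390363     0.5332065
#>  unbound 200      809.81   195.145       17.642509     1.6935876
#> length:     t = 70.3, p = 1.42e-187
#> divergence: t = -47.53, p = 4e-141

run_enrichment_test(peaks, ds$repeats, ds$layout, N = 1000, seed = 1)
#> <enrichment_result> O = 100, E = 27.4, O/E = 3.65
#>   b = 0 of N = 1000 randomizations exceed O; p = 0.000999 (one-sided, add-one)
#>   mode = same_chromosome, min_overlap = 1, statistic = count, seed = 1
```

Reading the output: all 100 truly bound copies received peaks, the bound
group is ~3× longer and visibly less diverged from the rebuilt family
consensus than the unbound group (both *t*-tests overwhelmingly reject
equality, in the expected directions), and the peak set overlaps the
repeat annotation 3.65× more often than the covered-proportion expectation,
at the smallest p-value the 1000-randomization test can produce. The
divergence values sit above the generator's substitution rates because
they are measured against the *rebuilt* consensus, which carries its own
reconstruction error — the bound < unbound ordering is the meaningful
readout.

Signal aggregation over the same dataset:

```r
fe <- fold_enrichment_track(ds$tracks$H3K9me3_control, ds$tracks$IgG)
m  <- extract_signal_matrix(fe, ds$repeats[mcols(copies)$bound],
                            flank = 1000, bin_size = 100, body_bins = 10)
trimmed_mean_profile(m, trim_fraction = 0.5)
#> <profile_curve> 30 bins, trim 0.5% each side; peak 105.6
```

The whole pipeline (generation → classification → consensus → enrichment →
signal → occupancy) runs from one call and one seed:

```r
run_pipeline(list(), out_dir = "run1", seed = 1)   # writes run1/report.json
```

A thin command-line front end with `simulate`, `enrich` and `run`
subcommands is installed at `system.file("cli/satrep.R", package = "satrep")`.

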