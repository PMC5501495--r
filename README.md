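# trindex

Design, simulation and benchmarking toolkit for **triple-indexed 16S
rRNA V4 amplicon sequencing libraries**, aimed at microbiome labs
multiplexing hundreds to thousands of samples on Illumina platforms and
at anyone who wants to stress-test such a pipeline against a mock
community with known ground truth.

## The method in brief

Sample identity is encoded by three indices: a 12-nt internal barcode on
the PCR1 forward primer, a 12-nt internal barcode on the PCR1 reverse
primer, and a 6-nt conventional index added by the PCR2 reverse primer.
Each PCR1 primer is built 5'→3' as

    partial adapter + barcode (12 nt) + heterogeneity spacer (0–7 nt) + priming sequence

with V4 515f/806r priming (IUPAC-degenerate). One fixed set of 12
forward × 8 reverse PCR1 primers covers a 96-well plate; plates are
distinguished by the PCR2 index alone, so the oligo count for *n*
samples is

    N(n) = 12 + 8 + 1 + ⌈n / 96⌉

— one extra oligo per additional plate, versus the two-step
dual-indexing alternative whose cost is 2 + min{i + j : i·j ≥ n}. The
0–7 nt spacers stagger the shared priming bases across sequencing
cycles, restoring the per-cycle base diversity Illumina cluster calling
needs.

The package provides:

* **oligo design** — primer assembly and validation, plate layouts with
  an identical-index (hairpin) exclusion rule, multiplexing cost
  arithmetic, per-position base-composition diagnostics;
* **demultiplexing** — paired-read assignment on the (pool index,
  forward barcode, reverse barcode) triple, spacer/primer stripping,
  quality-aware read-pair merging, reverse-primer trimming, with a
  conservation-checked statistics object;
* **PCR simulation** — a branching-process generative model with
  GC-dependent amplification efficiency e(gc) = clamp(e₀ − γ·max(0, gc −
  gc_ref)/boost, 0, 1) and per-duplication template-switching chimera
  formation, emitting paired FASTQ in the full read layout with a
  ground-truth table;
* **benchmarking** — exact-identity read assignment, OTU tables, common
  scaling, rare-OTU filtering, deviation-from-expectation and GC-bias
  statistics, chimera rate statistics, Bray-Curtis dissimilarities and
  PERMANOVA/ANOSIM variance partitioning.

## Worked example

```r
library(trindex)

count_oligos_triple(1152)        # 12 plates of 96
count_oligos_dual_alternative(1152)

cfg <- run_config(n_samples = 4, n_reads = 2000, seed = 42)
rep <- run_end_to_end(cfg)       # simulate -> demux -> merge -> assign -> stats
rep
```

prints

```
<scheme_cost> triple indexing, 1152 samples: 33 oligos
  pcr1_fwd=12, pcr1_rev=8, pcr2_fwd=1, pcr2_rev=12
<scheme_cost> dual indexing, 1152 samples: 70 oligos
  pcr1_fwd=1, pcr1_rev=1, pcr2_fwd=32, pcr2_rev=36
<trindex_report>
<demux_stats> 8000 pairs: 8000 assigned (4 samples), 0 unassigned
  unassigned by reason:  bad_fwd_barcode=0, bad_rev_barcode=0, bad_primer=0, no_samplesheet_entry=0
  merged 8000, merge_failed 0
  mean |dev| from expected: 1.382 pct points
  GC-bias slope: -0.1167 pct per GC%
  mean pairwise Bray-Curtis: 0.0737
  mean ground-truth chimera fraction: 0.1560
```

Reading the report: 1152 samples need 33 oligos under triple indexing
against 70 for dual indexing. The demo run simulates four samples of
2000 read pairs from a 33-species mock community (equal blending, so
each species is expected at ~3%); every pair demultiplexes and merges.
With the default GC penalty the mean per-species deviation from the 3%
expectation is 1.38 percentage points and abundance falls by ~0.12
percentage points per 1% GC; with the default chimera probability
(0.01 per duplication) about 15.6% of molecules after 35 + 10 cycles
are chimeric — chimeras match no reference exactly and surface as
unassigned reads in the OTU step.

A shell interface wrapping the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "trindex", package = "trindex"))')
Rscript $CLI cost --samples 1152
Rscript $CLI run --out demo_run/ --seed 7
```

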