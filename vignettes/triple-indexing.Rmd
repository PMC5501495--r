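---
title: "Triple-indexed amplicon libraries: design arithmetic, simulation model and benchmark statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-indexed amplicon libraries: design arithmetic, simulation model and benchmark statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trindex)
```

## The design problem

Highly multiplexed 16S rRNA V4 amplicon sequencing on Illumina platforms
faces two coupled problems. First, encoding thousands of sample
identities with indexed primers is expensive if every sample needs its
own long custom oligo: with conventional two-step dual indexing, i
forward and j reverse indexed PCR2 primers cover i × j samples, so index
sets grow with the square root of the sample count per direction and the
oligo bill grows steeply. Second, amplicon libraries are
low-complexity: every read starts with the same priming sequence, so
per-cycle base composition is badly skewed exactly where Illumina
cluster calling needs balanced A/C/G/T fractions (the first ~11
cycles), traditionally forcing large PhiX spike-ins.

The triple-indexing design addresed here solves both at once. Sample
identity is encoded in three indices: a 12-nt internal barcode on the
PCR1 forward primer, a 12-nt internal barcode on the PCR1 reverse
primer, and a 6-nt conventional (TruSeq-style) index on the PCR2
reverse primer. One fixed plate's worth of PCR1 primers (12 forward × 8
reverse = 96 combinations) is reused for every plate; plates are then
distinguished by the PCR2 index alone. A heterogeneity spacer of 0-7 nt
sits between each internal barcode and the priming sequence, staggering
the shared priming bases across read positions and restoring per-cycle
base diversity.

### Multiplexing arithmetic

`count_oligos_triple(n)` counts distinct oligos as 12 + 8 PCR1 primers,
one universal PCR2 forward primer, and ceiling(n / 96) indexed PCR2
reverse primers — so 96 samples need 22 oligos, and each further plate
of 96 adds exactly one. Twelve plates (1152 samples) need 33.
`count_oligos_dual_alternative(n)` is the comparison point: 2 universal
PCR1 oligos plus the minimum of i + j over positive integers with
i × j ≥ n (found by scanning i up to √n + 1, which always contains the
optimum). For 1152 samples that is 70 oligos; the gap widens linearly.

`positional_base_composition()` quantifies the spacer mechanism: for a
plate layout it tabulates, position by position, the base fractions over
all wells' read-start constructs (barcode + spacer + priming), counting
degenerate IUPAC priming positions fractionally. On the shipped default
layout no position in the first 31 is monomorphic.

### The shipped primer table

`inst/extdata/primers_default.tsv` is a structurally faithful but
synthetic oligo set (the sequences were generated for this package, not
taken from any published design): 12 forward and 8 reverse 12-nt
barcodes with minimum pairwise Hamming distance 6 within each direction,
spacers of length 0-7 mapped one-to-one onto the 8 reverse barcodes and
cyclically (0-7, 0-3) onto the 12 forward ones, V4 515f/806r priming
sequences, and partial/remaining Illumina adapters. The table's
`full_oligo` column is validated against the concatenation of its parts
on every load, and barcode sets are rejected at load time if the
requested mismatch tolerance exceeds half their minimum pairwise
Hamming distance (unique decodability).

## Demultiplexing model

Reads begin at the internal barcode. `parse_read_start()` matches the
first 12 nt against the direction's barcode set (exact match by
default; optionally within a Hamming tolerance when the set supports
it), obtains the spacer length from the barcode's table entry (`lookup`
mode) or scans lengths 0-7 until the priming sequence matches (`scan`
mode), and verifies the priming sequence by IUPAC-aware comparison.
A read pair is assigned when the triple (pool index, forward barcode,
reverse barcode) resolves in the sample sheet; otherwise it is counted
under exactly one failure reason (`bad_fwd_barcode`, `bad_rev_barcode`,
`bad_primer`, `no_samplesheet_entry`), so assigned + unassigned always
equals the input count — this conservation identity is asserted inside
the statistics constructor on every run.

Default tolerances, chosen as common conventions where the protocol
itself is silent: 0 barcode mismatches, priming mismatch fraction 0.1,
minimum merge overlap 10 nt, merge mismatch fraction 0.25. The element
order barcode → spacer → priming is the default; a configuration switch
(`spacer_before_barcode`) supports the converse layout, since published
schematics of such constructs are ambiguous about the rendering
direction.

Merging reverse-complements mate 2 and selects the overlap with the
lowest mismatch fraction (ties to the longest) among overlaps of at
least `min_overlap` bases; within the overlap, disagreements resolve
toward the higher-quality base and agreements keep the maximum quality.
The implementation anchors the search on mate 2's leading 16-mer
(exact, found by fixed-string search) and falls back to an exhaustive
overlap scan when the anchor fails, so error-free pairs merge in linear
time. `trim_trailing_primer()` removes a read-through reverse-priming
site from merged fragments; it is idempotent and flags absence rather
than failing.

## PCR simulation model

`simulate_pcr()` runs a per-molecule Bernoulli branching process over
`cycles1 + cycles2` cycles. The model's two bias mechanisms are the
ones repeatedly observed in amplicon benchmarking: GC-dependent
amplification efficiency and per-duplication chimera formation.

**Efficiency law.** Each molecule duplicates in a cycle with probability

e(gc) = clamp(e0 − γ · max(0, gc − gc_ref) / boost, 0, 1)

with defaults e0 = 0.9, γ = 0.5, gc_ref = 0.5, boost = 1. The law is
piecewise-linear in GC above a reference point: high-GC templates melt
incompletely during short denaturation steps and are progressively
outcompeted, while the `denaturation_boost` divisor models longer
melting times that rescue them. Published observations report an
abundance-versus-GC *slope*, not an efficiency law, so this law is the
package's own construction and the mapping from γ to any observed slope
is emergent, not calibrated.

**Chimeras.** Each duplication is, with probability q (default 0.01 in
stage 1, 0 in stage 2 — chimera formation is empirically dominated by
the degenerate-primer first-stage reaction), a template-switching
event: the new molecule takes the duplicating molecule's prefix up to a
uniform interior breakpoint and the suffix of another pool molecule
(drawn proportionally to copy number) at the homologous coordinate.
Templates share one length, so fragment length is conserved. Provenance
(two parent species ids, breakpoint, cycle of origin) is recorded per
distinct chimeric product. Under this mechanism the chimeric fraction
of the pool grows by roughly q · e/(1+e) per cycle — a few tenths of a
percent per cycle at the defaults, accumulating to the mid-teens over a
35 + 10 cycle protocol — and is close to linear in the first-stage
cycle number, which is exactly the property the test suite asserts
(strict increase over 25/30/35 cycles and a linear fit with R² > 0.8);
no particular slope value is asserted.

**Bookkeeping.** Molecules are tracked as counts per distinct sequence
(one count per template plus one row per distinct chimeric product), so
pools of millions of molecules cost only as much as the number of
distinct sequences. When the pool exceeds `capacity` (default 2 × 10⁶)
it is thinned by per-category binomial sampling with keep probability
capacity/total and the cumulative dilution recorded. Binomial thinning
approximates exact without-replacement down-sampling to
O(1/√capacity), which is far below every tolerance used in the tests.

**Read emission.** `sample_reads()` draws molecules with replacement
proportionally to copy number and emits each as a pair in the full
read layout: barcode + spacer + realized priming sequence + fragment
(mate 2 reverse-complemented), truncated to the read length (default
250 nt, the HiSeq rapid-mode length; with ~39-nt constructs and 253-nt
fragments this leaves a ~169-nt overlap for merging). Degenerate
priming positions are realized uniformly per read. Sequencing error is
i.i.d. substitution at `err_rate` (default 0); indels and
position-dependent error are deliberately out of model since the V4
Illumina error mode is substitution-dominated. Identical seeds produce
byte-identical FASTQ.

`simulate_experiment()` maps a design table (sample, well, pool,
cycles, template amount) over the simulator, pools reads per PCR2
index, concatenates truth tables, and can optionally emulate the
same-index yield collapse: wells whose forward and reverse barcode
sequences are identical form stable hairpins and return roughly
tenfold fewer reads, modeled as a fixed 10× down-weighting of the read
budget for flagged wells (the mechanism is modeled only as this yield
effect; no thermodynamic folding is attempted, and the plate builder's
`exclude_identical` switch removes such wells from designs altogether).

**What the generator does and does not emulate.** It reproduces the
study conditions that matter for the pipeline's correctness and for
the bias phenomenology: equal-proportion blending of 33 templates on a
30-69% GC gradient, factorial cycle/template designs, triple-index
read layout with spacers, GC-dependent depletion, cycle-dependent
chimera load, and same-index yield collapse. It does not emulate
polymerase error spectra, quality-score dynamics, primer-site
mismatch bias between species, PhiX contamination, or real taxonomic
sequence structure (templates are random DNA at controlled GC), so
passing tests demonstrate the pipeline's arithmetic and the model's
internal consistency — not performance on real MiSeq/HiSeq data.

## Benchmark statistics

Reads are assigned to species by exact full-length identity against
the reference fragments, in either orientation (`assign_reads()`); a
hash lookup is the exact-arithmetic equivalent of a full-length 100%
identity alignment criterion, under which any substitution or chimera
(except a join that happens to reconstruct a parent) is unassigned.
Library sizes are equalized by common scaling (multiply each library by
smallest size / own size) rather than rarefying; rare OTUs are dropped
when their average relative abundance falls below 0.01%, with no
renormalization by default (a flag enables it).

Accuracy statistics: `mean_abs_deviation_from_expected()` reports, per
species, |mean observed − expected| in percentage points and averages
over species (deviations are in percentage points; with 33 equally
blended species the expectation is ~3% per species).
`gc_bias_slope()` and `chimera_cycle_regression()` are ordinary least
squares of mean abundance on GC% and of chimera fraction on cycle
count. `chimera_stats()` reports the chimeric read fraction and the
singleton fraction among distinct chimeric sequences (undefined, and
reported as NA, when a sample has no chimeras).

Community structure: Bray-Curtis dissimilarities, PERMANOVA with
sequential (order-dependent) sums of squares in the user's column
order, and ANOSIM, all computed through vegan with explicit permutation
counts (default 10000) and seeds. The test suite checks these against
implementation-independent oracles: a brute-force pairwise-SS partition
for single-factor PERMANOVA R² (equal to 1e-9), a hand-ranked ANOSIM
statistic, and closed-form OLS fits. Bray-Curtis is a semimetric, so
only symmetry, range and zero diagonal are asserted — no triangle
inequality.

## Numerical and design choices

* Well order is row-major A1..H12; the fwd × rev product is
  forward-major, so 12 forward × 8 reverse fills one plate with the
  reverse index cycling fastest.
* The hairpin-risk predicate is simply `fwd.sequence == rev.sequence`;
  no folding thermodynamics.
* Degenerate priming positions count fractionally in composition
  tables and are realized uniformly at read emission.
* Chimera breakpoints are uniform over interior positions with
  homologous-coordinate joining, which keeps fragment length constant;
  the real template-switching position distribution is unknown.
* Sequential sums of squares for multi-factor PERMANOVA (the order is
  the user's column order and appears in the output); for balanced
  orthogonal factors the order does not change R² beyond numerical
  noise, which the suite asserts at 1e-9.
* `merge_pair` resolves overlap conflicts by maximum quality; at
  agreements it keeps the maximum of the two qualities.
* Reads shorter than the minimal construct are counted
  `bad_fwd_barcode`/`bad_rev_barcode` rather than crashing the parser.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at sizes a laptop handles in
minutes, chosen as this package's definition of its desk-scale study
conditions: the end-to-end exact-recovery oracle runs 8 samples × 20000
error-free read pairs; the chimera-linearity property uses 12 samples
(4 replicates × cycles 25/30/35, second stage fixed at 5) at 20000
reads per sample with pool capacity 2 × 10⁵; the GC-ordering property
uses 20 independent simulations at the default capacity; binomial-band
checks use 50000 reads. Read depth matters for the linearity property:
at a few thousand reads per sample, multinomial sampling noise on a
~12% chimera fraction is comparable to the between-cycle signal, while
at 20000 reads (still an order of magnitude below real per-sample
depths) the linear fit is stable.

## Known limitations

* Exact-identity assignment is only appropriate for mock communities
  whose reference is complete; it is not a general-purpose classifier.
* The branching-process model treats molecules independently;
  late-cycle reagent saturation and primer exhaustion are represented
  only crudely by the capacity cap.
* The chimera probability q and GC penalty γ are free parameters; the
  package makes no claim that its defaults reproduce any particular
  instrument's measured slopes, only the qualitative phenomena.
* `sample_reads` emits constant quality scores; quality-aware merge
  logic is exercised through explicit quality strings in tests.
* Pool-index (PCR2) demultiplexing is taken as given (one file pair
  per pool), as vendor software performs that level in practice.
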