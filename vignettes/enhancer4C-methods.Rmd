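---
title: "Methods: 4C-seq enhancer identification and CNV screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C-seq enhancer identification and CNV screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures each stage implements, the assumptions they rest on, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the workflow left
genuine choices open.

## The measurement model

4C-seq measures, for one chosen restriction fragment (the viewpoint),
the relative frequency with which every other fragment in the genome was
cross-linked to it. Reads have a rigid structure: a viewpoint-specific
reading primer that terminates in the primary restriction motif, then
the *captured* sequence of the ligated partner fragment, which shares
that motif across the ligation junction. The analysis unit is the
*fragment end*: the first `L` bases inward from a primary cut site.

Two properties of real 4C data drive the whole design:

* **Contact frequency decays monotonically with genomic distance** in
  cis. Everything reproducibly above that decay is signal.
* **Only some fragment ends are informative.** An end is usable when its
  `L`-bp sequence is unique in the genome (otherwise reads cannot be
  attributed) and when its fragment carries a secondary-enzyme site
  (otherwise the fragment cannot circularise in the second
  digestion–ligation round; such fragments are "blind").

## Stage by stage

### Fragment map (`digest_genome()`, `build_fragment_end_map()`)

The genome is cut at every occurrence of the primary motif; the cut
convention places the boundary at the motif start, so fragments begin
with the motif. Both ends of a fragment carry an `L`-bp sequence
starting with the motif: the left end reads the fragment's first `L`
bases; the right end reads the reverse complement of the window spanning
the *adjacent* cut site — exactly what a read sequenced from the other
strand sees across the ligation junction. This works because the common
4C enzymes (NlaIII `CATG`, DpnII `GATC`, Csp6I `GTAC`) have palindromic
motifs. Ends exist only at genuine cut sites: chromosome termini carry
no ligatable end and are excluded.

Uniqueness is exact `L`-bp sequence collision over the whole map — a
desk-scale surrogate for alignment-based mappability that is exact on
synthetic genomes. Sequences containing `N` are never unique. `L`
defaults to 36 bp; below ~16 bp uniqueness becomes meaningless and the
constructor refuses.

### Quantification (`demultiplex_and_trim()`, `quantify_fragment_ends()`, `normalize_and_smooth()`)

Reads are assigned to the unique viewpoint whose reading primer is an
exact prefix (primers are validated to be mutually non-prefix), then
trimmed to the captured sequence *retaining* the motif. Mapping is exact
matching of the captured sequence's first `L` bases against unique,
informative fragment ends — deterministic and faithful on error-free
synthetic reads. Support for real, error-containing FASTQ via a
mismatch-tolerant aligner is deliberately out of scope.

Counts at the viewpoint fragment and its two immediate neighbours are
dominated by self-ligation and undigested template; they are recorded
but flagged `masked` and excluded from normalization and peak calling.

Normalization is reads-per-million over unmasked cis fragment ends —
the common 4C convention that makes replicates comparable; blind and
non-unique ends are excluded from the denominator (they can receive no
reads). Smoothing is a running mean over `k = 21` consecutive fragment
ends per side (shrinking symmetric-index windows at the boundaries).
`k` trades spatial resolution against replicate noise; 21 ends is a few
kilobases at typical NlaIII fragment density and is recorded in the
profile's metadata. `k = 1` disables smoothing.

### Contact-peak calling (`fit_background()`, `call_peaks()`)

On each side of the viewpoint independently, the background is the
least-squares monotone non-increasing fit (pool-adjacent-violators) to
the replicate-mean smoothed profile as a function of distance, floored
at 0.5 normalized units so enrichment ratios are always defined. PAVA is
exact (verified against an exhaustive oracle in the test suite),
deterministic, and assumption-light: it encodes only "contacts decay
with distance".

A fragment end is significant when

1. in **every** replicate the profile is at least `qWd` times the
   background (reproducibility gate; `qWd = 1.5` by default), and
2. the windowed sign statistic — the number of positive residuals over
   all replicates within a window of `qWr · k` ends centred on the end —
   has a one-sided binomial(`n`, ½) p-value that survives
   Benjamini–Hochberg adjustment across all tested ends at `alphaFDR`.

Runs of at least `min_run = 3` significant ends, bridging at most
`merge_gap = 1` non-significant end, become peaks; a peak spans the
fragment boundaries of its outermost significant ends. Analysis is
restricted to ±1 Mb of the viewpoint (`max_span`), the range over which
4C signal is informative. Promoter viewpoints use three replicates and
`alphaFDR = 0.05`; reciprocal (PutE) viewpoints use two replicates and
`alphaFDR = 0.2`.

This caller keeps the parameter surface of the field's viewpoint
peak-calling convention (`alphaFDR`, `qWr`, `qWd`) but its statistic is
its own, transparent construction; its acceptance standard is
planted-truth recovery on synthetic data, not bitwise agreement with any
external implementation. `qWr` is interpreted as a multiplier on the
smoothing window giving the sign test's locality — this keeps the
parameter meaningful and the caller monotone in it. Whether smoothed or
raw profiles feed the caller is switchable (`use_raw`); smoothed is the
default.

Two numerical notes: the sign test treats window counts as binomial
although smoothing correlates neighbouring ends, which makes the
p-values optimistic — this is why the per-replicate ratio gate, not the
test, is the primary false-positive control (the null-scenario property
test shows essentially zero false peaks over 50 seeds); and the caller
cannot resolve peak edges below the sign-test window, so called
intervals may miss the outermost planted end (about one fragment end of
edge slack).

### Annotation (`delineate_putes()`, `assign_tads()`, `confirm_reciprocal()`, `mutual_interactions()`)

A PutE is `peak ∩ open-chromatin ∩ H3K27ac`. "Open" is the **union** of
ATAC and DNase by default — the two assays corroborate one another, and
either suffices to call chromatin open; an `open_mode = "intersection"`
switch implements the stricter reading. Resulting intervals merge when
closer than 500 bp and drop when shorter than 200 bp (both configurable;
the defaults suppress fragmented slivers at typical track resolution).
PutEs are numbered by genomic order.

TAD membership is by interval midpoint with the half-open rule (a
midpoint exactly on a TAD start belongs to that TAD) — a deterministic
convention for boundary-straddling elements. Promoter–element pairs are
intra- or inter-TAD by shared TAD id.

Reciprocal confirmation re-runs the caller from the PutE viewpoint with
the relaxed parameter set and asks whether any peak overlaps the
promoter region (half-open, ≥ 1 bp). Mutual interactions require both
directions; the reported pair list covers only viewpoints that were
actually measured. Elements cloned as several reporter fragments are
active if **any** fragment is active — the natural reading when a large
element must be split for cloning.

### Reporter scoring (`luciferase_fold_change()`)

Per well, activity is firefly/renilla; per construct and experiment,
activities average over wells and are divided by the *same experiment's*
negative control, so transfection-efficiency differences between
experiments cancel (the simulation plants such per-experiment factors
precisely to exercise this). The fold change is the mean of the
per-experiment ratios with its sample standard deviation; the activity
threshold (two-fold) is inclusive. Results from fewer than three
experiments warn rather than error.

### CNV screen (`call_cnvs()`, `filter_controls()`, `overlap_report()`)

Segmentation is a deterministic run-length rule: maximal runs of
consecutive probes with logR below −0.3 (deletion) or above +0.25
(duplication), kept only when supported by at least 10 probes — a
transparent reproduction of threshold-plus-filter CNV screening;
an HMM or CBS would add nothing testable here. Each call carries its
minimal interval (first to last supporting probe), maximal interval
(nearest unaffected flanking probes), per-side breakpoint delimitation,
and flanking probe ids. BAF is carried through but unused — deletion
calling is logR-only, a recorded limitation. Control filtering removes
calls matched by a same-type control CNV at ≥ 50% reciprocal overlap
with carrier frequency above `control_max_freq` (default 0).

Probe positions are kept as printed on arrays (1-based), and
`interval_size()` is plain `end − start` — the arithmetic used when
reporting CNV sizes from printed coordinates, so published sizes verify
directly.

### Expression (`relative_expression()`)

The normalizer is the arithmetic mean of the housekeeping Cts, which is
exactly the geometric mean of their linear abundances (Ct is log2) and
numerically stabler. The reported fold change is `2^(−mean ΔΔCt)` — the
geometric mean of per-replicate fold changes — so the reference sample
is exactly 1 by construction; the arithmetic mean of `2^(−ΔΔCt)` would
exceed 1 under any noise. The sd is that of the per-replicate fold
changes.

## The synthetic-data generator

`simulate_locus()` emulates the statistical structure the analysis
assumes: a uniform-random ACGT chromosome with primary/secondary motifs
additionally seeded at ~300/120 bp mean spacing (guaranteeing fragment
density independent of the random background); captured ends drawn with
probability ∝ `distance^(−decay_exponent)` × planted enrichment;
negative-binomial replicate counts (`variance = μ + dispersion·μ²`,
dispersion 0.05 by default — the standard count-overdispersion model;
the workflow itself does not dictate one); reads assembled as reading
primer + captured end at 75 bp, single-end. Default depth is 5×10⁵
reads per replicate — a realistic per-viewpoint depth recorded in the
truth record; the workflow does not dictate one. The generator samples
only unique, informative ends outside the masked self-ligation
territory: at distance ≈ 0 the power-law weight diverges and would
absorb nearly all reads while contributing nothing measurable
downstream.

The four fixtures plant the per-gene architectures — peak counts 6, 8,
3, 11; track-covered subsets of 2, 5, 2, 7; which PutE viewpoints see
the promoter and each other in the reciprocal experiments; and the
construct-level reporter fold changes — on a 2 Mb toy chromosome with
the viewpoint at its centre, peaks 8 kb wide at 5× enrichment, 120–880
kb from the viewpoint and well separated. Reciprocal scenarios share
the promoter scenario's genome through a common `genome_seed`, so all
viewpoints of a gene quantify against one fragment map.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: sequencing errors and quality
variation (mapping here is exact), PCR duplicates, trans-chromosomal
contacts, chromatin-state-dependent digestion efficiency, partial
digestion, mappability structure of real genomes, BAF patterns of real
CNVs, and primer-efficiency differences in qPCR. The pipeline's
statistical behaviour on real libraries additionally depends on an
upstream aligner, which is out of scope.

## Problem sizes and determinism

Every stochastic test fixes its seed; all generator outputs are
byte-identical under a fixed seed, and truth records depend only on the
scenario, not the noise stream. The test suite runs the four fixtures
through the full read path (three replicates of 5×10⁵ reads each), the
end-to-end cascade on `atxn1` including two reciprocal viewpoints at two
replicates, a 50-seed null-scenario false-positive study on an 8×10⁵ bp
chromosome at 2×10⁵ reads per replicate, exhaustive PAVA verification on
all binary vectors up to length 8 and ternary up to length 5, and
100-run recovery studies for the reporter stage — sizes chosen so the
whole suite completes in a few minutes while keeping every statistical
check at meaningful power.

## Known limitations

* The peak caller is a surrogate with the conventional parameter names;
  its numbers are not interchangeable with any specific external
  implementation's output on real data.
* Exact-match quantification requires error-free reads; real FASTQ needs
  an external aligner upstream.
* Deletion calling ignores BAF and cannot distinguish homozygous from
  heterozygous events or detect copy-neutral LOH.
* TAD assignment consumes TAD intervals; it does not call them from
  Hi-C matrices.
* The mutual-interaction matrix is boolean; it records whether peaks
  overlap elements, not interaction strength.
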