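# enhancer4C

Identification of gene enhancers from 4C-seq viewpoint data, with
copy-number-variant screening of the resulting elements.

## The problem

Enhancers act at distance and in a tissue-specific way, so finding the
enhancers of a disease gene — for example the spinocerebellar-ataxia genes
*ATXN1*, *ATXN3*, *TBP* and *ITPR1* in the cerebellum — requires measuring
which genomic regions physically contact the gene's promoter. Circularized
chromosome conformation capture sequencing (4C-seq) does exactly that: one
restriction fragment (the *viewpoint*, here a promoter) is used to pull
down and sequence everything it was cross-linked to.

`enhancer4C` implements the full analysis cascade downstream of
sequencing, for people who want a tested, scriptable version of this
workflow:

1. **Fragment map** — in-silico digestion of the genome with the primary
   enzyme (e.g. NlaIII, motif `CATG`) and construction of the unique
   fragment-end index: the `L`-bp sequence at each cut site, flagged for
   uniqueness and for presence of the secondary-enzyme site (fragments
   without one are "blind" and uninformative).
2. **Quantification** — demultiplexing by reading primer, trimming to the
   captured sequence (retaining the restriction motif), exact
   fragment-end matching, cis reads-per-million normalization, and
   running-mean smoothing over `k` fragment ends.
3. **Contact-peak calling** — contact frequency decays monotonically with
   genomic distance; on each side of the viewpoint the background
   *b(d)* is the least-squares non-increasing fit (pool-adjacent-violators)
   to the replicate-mean smoothed profile. A fragment end is significant
   when every replicate exceeds `qWd · b(d)` and a windowed binomial sign
   test on positive residuals (window `qWr · k` ends,
   Benjamini–Hochberg-adjusted) passes `alphaFDR`. Runs of at least
   `min_run` significant ends become **4C-contact peaks**.
4. **Enhancer annotation** — a putative enhancer (**PutE**) is the section
   of a contact peak where chromatin is open (ATAC and/or DNase) *and*
   carries H3K27ac; elements are assigned to TADs by midpoint; a PutE is a
   confirmed **R-PutE** when its own reciprocal viewpoint (two replicates,
   `alphaFDR = 0.2`) shows a peak over the original promoter; mutual
   interactions require both directions.
5. **Reporter scoring** — dual-luciferase fold change
   `FC = (firefly/renilla)_candidate / (firefly/renilla)_negative-control`,
   paired within experiment and averaged over three independent
   experiments; an R-PutE with `FC ≥ 2` is an **active enhancer**.
6. **CNV screen** — run-length segmentation of SNP-array logR with the
   ≥ 10-consecutive-probes rule, minimal/maximal breakpoint intervals from
   the nearest unaffected flanking probes, control-cohort filtering by
   50% reciprocal overlap, and overlap reports against enhancers, peaks
   and TAD boundaries.
7. **Expression** — relative qPCR expression by the 2^−ΔΔCt method with
   housekeeping-geomean normalization.

A first-class synthetic-data generator (`simulate_locus()`,
`simulate_tracks()`, `simulate_assays()`) emulates every input — reads
structured as reading-primer + captured fragment end, power-law distance
decay with planted elevated-contact regions and negative-binomial
replicate noise, epigenomic tracks, reporter wells, probe arrays and Ct
tables — so the entire pipeline is testable without external data. Four
bundled fixtures (`atxn1`, `atxn3`, `tbp`, `itpr1`) plant the per-gene
architectures: 6, 8, 3 and 11 promoter contact peaks, of which 2, 5, 2
and 7 are covered by epigenomic tracks.

## Worked example

```r
library(enhancer4C)

scn    <- fixture_scenario("atxn1", seed = 1)
screen <- run_locus_pipeline(scn)   # simulate -> quantify -> call -> annotate
glance(screen)
#> # A tibble: 1 × 6
#>   gene  n_contact_peaks n_putes n_rputes n_active_enhancers n_mutual_pairs
#> 1 atxn1               6       2        2                  2              0

tidy(screen$peaks)[, c("start", "end", "side", "n_ends", "mean_enrichment")]
#> # A tibble: 6 × 5
#>     start     end side       n_ends mean_enrichment
#> 1  519641  528485 upstream       99            3.15
#> 2  599622  608251 upstream      106            3.18
#> 3  779766  788402 upstream      102            2.88
#> 4  879913  888132 upstream       97            2.54
#> 5 1199649 1208261 downstream     91            2.88
#> 6 1429655 1438535 downstream     93            3.20

tidy(screen)[, c("rpute_name", "reciprocal_confirmed", "fold_change", "category")]
#> # A tibble: 2 × 4
#>   rpute_name reciprocal_confirmed fold_change category
#> 1 R-PutE1    TRUE                        2.32 active enhancer
#> 2 R-PutE2    TRUE                        7.11 active enhancer
```

The six called peaks recover the six planted contact regions; the two
track-covered peaks become PutE1/PutE2, both confirm reciprocally and
both drive ≥ 2-fold reporter activity, so the screen reports two active
enhancers. `autoplot(screen$profile, peaks = screen$peaks)` draws the
smoothed profile with its monotone background and peak intervals.

The CNV arm on a simulated patient array with a planted 20-probe
deletion:

```r
assays <- simulate_assays(fixture_assay_scenario("itpr1", seed = 1))
tidy(call_cnvs(assays$probes, cnv_params(min_probes = 10)))
#> # A tibble: 1 × 13
#>   chrom type     n_probes min_start min_end  size delim_centromeric ...
#> 1 chr3  deletion       20   3800881 3838881 38000              2000
```

Interval arithmetic on printed CNV coordinates follows plain
end − start: `interval_size(3797792, 3838896)` is `41104`.

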