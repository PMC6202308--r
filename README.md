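# chortools

Quantitative downstream analysis of **ChOR-seq** (chromatin occupancy
after replication) and its spike-in variant **qChOR-seq** — sequencing
assays that measure histone post-translational-modification (PTM)
occupancy specifically on newly replicated DNA — together with a forward
simulator of chromatin replication that provides ground truth for every
analysis stage.

## Who this is for

Chromatin biologists and computational epigeneticists asking two
questions about replication:

1. **Position** — are modified parental histones re-deposited at their
   pre-replication positions? Measured by pairing parental and nascent
   peaks that overlap reciprocally once and summarizing the absolute
   start/end distances of each pair.
2. **Level and kinetics** — nascent chromatin carries roughly half the
   parental mark level (old and new histones mix ~1:1; new histones lack
   tri-methylation). How fast is the full level restored, and where?

The second question requires spike-in normalization. With constant
exogenous spike-in chromatin in every sample, per-bin counts divided by
total spike-in reads give **reference-adjusted reads per million
(RRPM)**:

    RPM_i  = c_i * 1e6 / N_target        (shape only; erases level changes)
    RRPM_i = c_i * 1e6 / N_spikein       (levels comparable across samples)

Per-window RRPM time courses are classified into restoration categories:
a window belongs to the earliest timepoint `t` at which

    final_level / level(t) <= 1.5

(e.g. R0/R1/R6/R12 for a 0/1/6/12-hour course), keeping only windows
with identical categories in both replicates. Under writer inhibition,
T0/T-late fold changes are binned into low (< 1.5), moderate (1.5–3) and
high (> 3) loss.

## What is in the package

* `genomic I/O` — strict BED3-6, ENCODE narrowPeak/broadPeak and
  bedGraph readers/writers over a dual target + spike-in genome layout.
* `coverage` — read extension, binned occupancy counting, RPM / RRPM /
  RPKM / percent-of-maximum / z-score normalization.
* `regions` — peak tiling into windows, replicated-region filtering,
  oriented domain borders (≥ 5 kb from replicated-region edges),
  parental↔nascent peak pairing and displacement summaries.
* `restoration` — window-level time courses, restoration and loss
  classification, replicate concordance, category proportions.
* `profiles` — anchor-centred matrices and average profiles,
  length-normalized metagene profiles, heatmap percent-max scaling,
  Hilbert-curve genome images.
* `simulation` — parental landscape, replication of a genome subset,
  histone recycling with a positional displacement kernel, two-fold
  dilution, per-locus restoration plateaus, constant spike-in, Poisson +
  lognormal noise, replicates — emitting reads (BED), peaks, replicated
  regions and a truth table.
* `run_pipeline()` / `stage_*()` — a file-based pipeline over a run
  directory with a JSON manifest; `inst/scripts/chor-pipeline.R` exposes
  the stages as shell subcommands.

See the vignette (`vignettes/chor-seq-analysis.Rmd`) for the model,
conventions and limitations.

## Worked example

Simulate a small qChOR-seq time course (100 peaks on a 1 Mb genome, two
replicates, T0/T1/T6/T12) and run the full pipeline:

```r
library(chortools)
cfg <- sim_config(seed = 11, n_peaks = 100, n_domains = 4,
                  depth = 150000, spikein_reads = 30000)
res <- run_pipeline(cfg, "chor-demo")

res$classification$proportions
#>        R0        R1        R6       R12
#> 0.2681159 0.2246377 0.2608696 0.2463768

attr(res$classification$concordant, "retained_fraction")
#> [1] 0.92

res$displacement$mean          # mean parental->nascent displacement (bp)
#> [1] 77.92

res$classification$ratios
#>      replicate rrpm_final_over_t0 rpm_final_over_t0
#> rep1      rep1           1.607064          1.058254
#> rep2      rep2           1.593442          1.056779
```

Reading the output: the simulator assigned the four plateau categories
with equal probability, and the recovered proportions sit near 0.25
each; 92% of windows were classified identically in both replicates.
The mean peak displacement matches the analytic expectation of the
100 bp recycling kernel (σ√(2/π) ≈ 79.8 bp). The RRPM final/T0 ratio of
~1.6 is the programmed aggregate gain — a quarter of the windows are
already restored at T0, so the aggregate is 4/(1 + 3×0.5) = 1.6 — while
RPM, which normalizes the gain away, stays near 1. The run directory
contains every intermediate as plain text (bedGraph tracks with metadata
sidecars, windows, calls, proportions, displacement tables, Hilbert
grid) plus `manifest.json`.

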