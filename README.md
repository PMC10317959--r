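# crisprTiling

Design and analysis of pooled CRISPR-interference (CRISPRi) screens tiled
across transcription-factor-bound regulatory elements.

Regulatory elements bound by a co-activator number in the tens of
thousands per cell line, but only a minority are required for
proliferation, and which ones differ between cancer lineages. A CRISPRi
tiling screen silences each candidate element with several sgRNAs and
reads out guide dropout over time. This package implements the
computational pipeline for such screens, exercised entirely on synthetic
data with planted ground truth:

* **Peak selection** — per cell line, the significance cutoff is the knee
  of the ECDF of peak −log10(FDR), located as the second-derivative sign
  change of a cubic smoothing spline (`selectPeakCutoff`), followed by
  consensus peak union across cell lines (`unionPeaks`).
* **Library design** — NGG PAM scanning within ±300 bp of each consensus
  summit, BbsI restriction-site and >20 bp spacing filters, two
  significance pools plus non-targeting / pan-lethal / pathway /
  target-gene control pools, and 60-nt cloning oligo emission
  (`enumerateCandidates`, `filterCandidates`, `assembleLibrary`,
  `emitOligos`); validation-library design from primary-screen statistics
  (`designValidationLibrary`).
* **Screen analysis** — control-median and TMM normalization, per-guide
  log2 fold changes and depletion tests, and the exponential fitness
  model: normalized counts follow x_t = x_0 · e^(αt) at t = 8, 15, 22
  days, fit as ln(x_t) = b_g + α·t by OLS with guide-level intercepts and
  a shared per-day fitness score α per region (`fitFitness`). Region-level
  rank aggregation uses a modified robust-rank-aggregation statistic with
  permutation p-values (`aggregateRegionRRA`). Hits are called common
  (scoring in ≥3 of 4 cell models) or lineage-specific (both models of one
  lineage, neither of the other) (`callHitsSecondary`), with differential
  guide comparison between lineages (`differentialLineage`).
* **Region signal** — binned occupancy matrices in a 4-kb window around
  summits with percentile clipping and 0–1 scaling, k-means partitioning,
  ±250 bp coverage and log-scale Spearman correlation (`binSignal`,
  `clipScale`, `clusterRegions`, `coverageAt`, `logRankCorrelation`).
* **Synthetic data** — peak sets with a planted ECDF knee, genome-like
  sequences with guaranteed PAM density, and negative-binomial guide count
  matrices around the exponential dropout model with planted common /
  lineage-specific effects across four simulated cell models
  (`simulatePeaks`, `simulateSequences`, `simulateScreen`, `assignTruth`).

## Worked example

```r
library(crisprTiling)
cfg <- pipelineConfig(n_regions = 200, seed = 7, out_dir = "demo_out")
res <- runPipeline(cfg)
#> [pipeline] simulate: 200 regions, seed 7
#> [pipeline] design: per-cell-line cutoffs meso1=46.9, meso2=48.9, uveal1=50.7, uveal2=51.7
#> [pipeline] design: 36 consensus regions after union
#> [pipeline] design: library of 3196 guides
#> [pipeline] analyze: 3196 guides x 32 samples
#> [pipeline] signal: binned occupancy over 36 regions
#> [pipeline] done: 17 output files

table(res$hits$category)
#>        common  lineage-meso lineage-uveal          none
#>             8             4             5            19
```

The pipeline simulates four cell models (two mesothelioma-like, two uveal
melanoma-like), selects each model's peak-significance cutoff from its
ECDF knee (the planted knee is at −log10 FDR = 50), designs a tiling
library over the consensus peaks, simulates the dropout screen, fits the
fitness model per region and model, and calls hits. The hit table above is
read against the generator's truth table (`res$truth`): at these settings
every planted common hit and nearly every lineage-specific hit is
recovered in its correct category.

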