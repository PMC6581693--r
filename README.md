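# cadence

**C**hromatin **a**ccessibility **d**ynamics and **e**xpression
co**nc**ordanc**e**: an R package for the integrative statistics of a
differentiation time course profiled by ATAC-seq, transcription-factor
ChIP, knockdown RNA-seq and single-cell RNA-seq. It is written for
computational biologists who have already aligned reads and called peaks
and now need the downstream analysis: which regions open or close, which
motifs gain footprints, which genes a factor directly controls, and how
chromatin and expression dynamics agree.

## What it computes

* **Peak atlas** — replicate concordance by reciprocal overlap
  (overlap ≥ *f* of both lengths, default *f* = 0.5), union merging of
  condition peak sets by summit distance (single linkage, strict
  < 100 bp), partitioning into promoter (−2 kb/+0.5 kb of a TSS,
  oriented), intragenic and intergenic, and nearest-TSS gene assignment
  with signed distances.
* **Dynamics** — CPM normalization; differential accessibility by a
  conditional negative-binomial exact test (common moment-estimated
  dispersion) with the CPM ≥ 4, fold ≥ 2 (promoter) / ≥ 2.5 (distal),
  q < 0.05 filter; z-scored temporal profiles; fuzzy c-means
  (fuzzifier *m* = 2, restarts, c = 12 over-clustering) with automated
  or explicit merging to broad patterns; per-cluster motif enrichment
  (binomial tail, z-normalized −log10 p).
* **Footprinting** — aggregated cut profiles around motif occurrences;
  flanking accessibility FA and footprint depth
  FPD = log2((flank + ε)/(interior + ε)); per-motif contrasts
  (ΔFA, ΔFPD) classified by a Tukey-depth bagplot (bag = hull of the
  ⌈n/2⌉ deepest points, fence = 3× bag; points beyond the fence are
  significant outliers).
* **Single cells** — 3×MAD QC on library size and detected genes (high
  doublet fence on library size), gene filtering, size-factor CPM, HVG
  selection by mean-variance decomposition, binary co-expression scores,
  JSI = 1 − JD² and MCC co-expression matrices with reference-condition
  ordering, regulon recovery-curve AUC with Otsu activity thresholding,
  a rank-based (PC1) pseudotime stub, and pseudo-bulk aggregation.
* **Integration** — distance-binned hypergeometric concordance between
  accessibility clusters and expression clusters (±10–250 kb bins), and
  direct-target calling (bound ∩ knockdown-responsive, activated =
  down-in-knockdown) with percent-activated summaries.
* **Synthetic data** — seeded generators planting temporal archetypes,
  motif footprints, QC outlier cells, co-expression regulons, a 1-D
  trajectory and knockdown effects, with truth tables for every planted
  structure.

## Worked example

Recover the four planted temporal archetypes from simulated
accessibility counts:

```r
library(cadence)
cfg <- simulation_config(seed = 17)
acc <- simulate_accessibility(cfg)
z   <- zscore_profiles(cpm_normalize(acc$counts))
fit <- fuzzy_cmeans(z, c = 12, seed = 17)
mg  <- merge_clusters(fit, target_K = 4)
table(mg$merged_label, acc$truth$archetype)
#>     down_down transient_down transient_up up_up
#>   1         6            474            1     1
#>   2       452             18            5     0
#>   3         3              0          513     0
#>   4         0              1            1   525
```

Each merged cluster maps to one archetype; the off-diagonal entries are
the handful of low-coverage peaks whose shapes are ambiguous at the
simulated depth (adjusted Rand index ≈ 0.95).

Call direct targets from a simulated knockdown with planted binding:

```r
kd <- simulate_knockdown(cfg, regulon_truth = simulate_single_cells(cfg))
de <- differential_expression(kd$counts, kd$pairs)
bound <- unique(assign_nearest_gene(kd$tf_peaks, kd$genes)$gene_id)
tg <- call_direct_targets(bound, de)
tg$summary
#> $n_total           45
#> $n_activated       30
#> $n_repressed       15
#> $percent_activated 67
```

All 45 planted targets are recovered (30 activated, 15 repressed) with
no false calls among the 25 bound-but-unregulated genes.

The whole pipeline — atlas, dynamics, footprinting, single-cell stage
and integration — runs from one configuration and writes TSV/BED/JSON
outputs plus a hashed manifest:

```r
run_pipeline(pipeline_config(seed = 17, out_dir = "results"))
```

A thin command-line wrapper ships in `inst/scripts/cadence`
(`cadence simulate --seed 17 --out demo/`,
`cadence run --config config.yaml`).

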