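---
title: "Models and methods: chromatin accessibility dynamics and expression concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadence)
```

# Scope

`cadence` implements the statistical core of an integrative analysis of a
differentiation time course profiled by ATAC-seq, TF ChIP, bulk RNA-seq
after factor knockdown, and scRNA-seq: peak-atlas construction, fuzzy
temporal clustering, bivariate motif footprinting with bagplot outlier
calling, single-cell co-expression and regulon statistics, distance-binned
accessibility-expression concordance, and direct-target calling. Read
alignment, peak calling, motif discovery and graph-based trajectory
inference are upstream tools and are out of scope; their outputs (peak
BED files, per-base cut tables, motif occurrence lists, count matrices)
are this package's inputs. A seeded synthetic-data generator supplies
inputs with the statistical structure each stage assumes, so the whole
pipeline is testable without sequencing data.

# Peak atlas

Replicate concordance keeps peaks with a reciprocal overlap of at least
`min_frac` (default 0.5) of *both* peak lengths — the semantics of
`intersectBed -f 0.50 -r`. The union atlas merges peaks across conditions
by single-linkage on summit distance, merging strictly below `max_gap`
(default 100 bp); on sorted 1-D summits single linkage reduces to runs of
adjacent gaps, which is what the transitive-closure oracle in the test
suite checks. Dense chains of peaks each slightly under the gap therefore
merge transitively; tools that re-anchor on a merged summit can differ on
such chains, a documented approximation.

Peaks are partitioned by their center with precedence promoter >
intragenic > intergenic. The promoter window is `(upstream, downstream)`
in TSS-oriented coordinates and is configurable because two conventions
coexist in practice: −2 kb/+0.5 kb for accessibility partitioning and
−2.5 kb/+0.5 kb for annotating TF-binding peaks. Nearest-gene assignment
measures center-to-TSS distance (not edge distance) so that it composes
consistently with the distance-binned concordance, which also measures
from peak centers; ties break to the lexicographically smaller gene id to
keep runs reproducible.

# Differential accessibility and expression

Counts are normalized to CPM; fold changes use a pseudocount of 1 to
avoid division by zero. Differential accessibility across conditions uses
a conditional negative-binomial exact test on library-size-adjusted
counts: given the total of two equal-mean NB variables, outcomes no more
likely than the observed split are summed. The common dispersion is
moment-estimated across features and floored at 1e-4. This is a
deliberate, documented approximation to the empirical-Bayes machinery of
dedicated count-model packages: recovery is validated on synthetic truth,
not by reproducing any particular dataset's peak counts. Two caveats
follow. First, the moment estimator is honest only when most features are
null; in an all-differential matrix (such as the archetype generator's
output) condition effects inflate it, so the pipeline passes an assumed
dispersion of 0.01 (BCV 0.1, the conventional value for well-controlled
unreplicated designs) instead. Second, the exact test is discrete and
therefore conservative; on null simulations the fraction of features at
q < 0.05 sits well below 0.05.

A feature is differentially accessible when its CPM reaches `min_cpm = 4`
in some condition and some pairwise comparison reaches fold
`>= 2` (promoter peaks) or `>= 2.5` (intra/intergenic peaks) at BH
q < 0.05.

Knockdown expression uses the paired design directly: per-gene paired
t-test on log2 CPM differences, significance at fold > 1.2 and p < 0.05,
plus a rescue clause for genes whose replicate pairs all move in the same
direction with mean fold > 1.2 — capturing consistent effects that small
replicate numbers leave underpowered.

# Fuzzy temporal clustering

Condition profiles are z-scored per feature (population SD; constant
profiles map to the zero vector), so clustering operates on shapes, not
amplitudes. Fuzzy c-means uses the standard alternating updates with
fuzzifier `m = 2` (configurable; the value is a convention, not derived
from data), 5 random restarts keeping the best objective, and convergence
on the maximum membership change. Memberships are computed with
row-minimum normalization so fuzzifiers near 1 cannot overflow; in the
`m -> 1` limit the hard labels coincide with Lloyd's k-means, which the
test suite checks against `stats::kmeans`. Profiles are first
over-clustered (c = 12) and then merged to 4 broad patterns — the
over-cluster-then-merge style usual for temporal profiles; because such
merges are often done by manual inspection, the default here is automated
average-linkage agglomeration on 1 − Pearson correlation of centroids,
and an explicit mapping argument reproduces any manual choice.

Per-cluster motif enrichment is a binomial survival test of the
occurrence rate in cluster peaks against a user-supplied background peak
set (GC-matched background construction is out of scope), with
−log10 p capped at 320 and z-normalized per motif across clusters.

# Bivariate footprinting

For each motif the per-base cut profile is averaged over occurrences
(minus-strand occurrences reversed) and scaled to cuts per 10 million
library cuts. With flanks defined beyond `motif_width/2 + flank_margin`
from the window center, flanking accessibility FA is the mean flank
density and footprint depth is `FPD = log2((FA + eps)/(interior + eps))`
with `eps = 0.1`; footprint-depth definitions vary between tools, so
this log-ratio is stated as this package's explicit convention. The condition
contrast is the point `(delta FA, delta FPD) = (log2 FA_b/FA_a,
FPD_b − FPD_a)` per motif.

Classification follows the bagplot: Tukey halfspace depths (exact
rotational sweep for n ≤ 2000, seeded random directions beyond), depth
median = deepest point (centroid of the deepest set on ties), bag =
convex hull of the ⌈n/2⌉ deepest points with ties at the cut resolved
toward the depth median, fence = bag inflated 3× about the depth median;
points outside the fence are outliers. The construction is invariant to
affine maps of the plane. Collinear panels fall back to per-axis quartile
fences and are flagged. Because the bag is estimated from a finite
sample, an isolated borderline null can occasionally exceed the fence —
exactly as isolated motifs do in real bagplot panels; the synthetic panel
keeps this rare by giving motifs bounded systematic profile variation
(see below). Tn5 insertion-bias correction is out of scope: cut tables
are taken as given.

# Single-cell statistics

QC removes cells below median − 3·MAD in library size or detected genes,
or above median + 3·MAD in library size (doublet proxy; high detected
genes alone is not filtered). "Below 3× MAD" is read as an absolute
deviation from the median — a deviation threshold needs a center — and
the MAD is scaled by 1.4826 by default, matching common single-cell QC
implementations. Genes are kept at mean raw count ≥ 0.05 over passing
cells; size factors are library sizes centered to unit mean.

HVGs come from a mean-variance decomposition of log2(CPM+1): a running
median followed by loess gives the technical trend, the excess is the
biological component, and `var·(n−1)/trend ~ chi-square(n−1)` gives
p-values, BH-corrected. Binary co-expression scores sum detection
indicators over a gene set and z-transform with the population SD
(chosen so small worked examples are exact; configurable conventions are
deliberately avoided to keep outputs comparable). Because a per-condition
cell-number correction can be defined in several ways, both pooled
z-scores and per-condition equal-weight summaries are reported and
labelled.

JSI is `1 − JD²` on detection vectors; MCC is the phi coefficient, equal
to the Pearson correlation of the binary vectors (tested numerically).
Heatmap orderings are computed once on a reference condition (hierarchical
clustering for JSI, first principal component for MCC) and reused as pure
permutations for the other conditions.

Regulon activity is the normalized area under the recovery curve over the
top 5% of each cell's expression ranking (the customary default for
recovery-curve scoring;
ties broken by a seeded shuffle), and the active/inactive threshold is
chosen by Otsu's method on the AUC distribution, replacing an interactive
choice; a manual threshold is supported. Pseudotime is deliberately a
stub: the first principal component of z-scored log-CPM over HVGs,
min-max rescaled and oriented along the condition order (pass a factor
whose level order is the temporal order; orientation is then invariant to
cell permutations). Graph-based trajectory methods are out of scope.
When examining a regulon along the trajectory, order cells on HVGs
*excluding* the regulon and its driver — otherwise the ordering leaks
regulon detection noise into both strata.

# Concordance and direct targets

For accessibility cluster Ai, expression cluster Rj and distance
half-width b (defaults 10, 25, 50, 75, 100, 150, 200, 250 kb, an
8-bin grid spanning ±10–250 kb; fully configurable), K is the set of genes with TSS within ±b of any peak
center in Ai, and the overlap with Rj is tested with the exact
hypergeometric upper tail over the annotated-gene universe. The exact
tail is what a random-expected-set resampling procedure estimates; the
randomized version remains available behind a flag and agrees within
Monte-Carlo error. Each bin is its own K-set (half-widths are cumulative
by construction); this is recorded in the output metadata. Direct targets
are bound genes (nearest-gene assignment of TF peaks) intersected with
knockdown-responsive genes; genes down in the knockdown are classified
activated, up repressed, and the summary reports percent activated
rounded to the nearest integer.

# The synthetic study

The generators are pure functions of `(config, seed)` and default to a
toy genome of 2 × 10 Mb chromosomes, 400 genes, 2,000 peaks, 3
conditions and 300 cells per condition, chosen so every stage runs in
seconds while each planted structure is identifiable:

* **Accessibility**: four temporal archetypes (up-up, down-down,
  transient-up, transient-down) at equal proportions, per-step fold 2,
  lognormal baselines (meanlog log 100, sdlog 1), NB dispersion 0.01.
  The dispersion encodes the replicate concordance a merged-replicate
  ATAC design implies (BCV ≈ 0.1); at several-fold higher dispersion the
  archetypes are no longer cleanly recoverable and the benchmark would
  measure noise, not the method. With `effect_fold = 1` the generator is
  a null for FDR calibration.
* **Cut profiles**: 60 motifs × 150 occurrences, 100-bp window around a
  12-bp motif, multinomial cuts at 1 cut/bp; 10 motifs gain a footprint
  in the later conditions (interior × 0.4, flanks × 1.5). All motifs
  carry bounded log2-uniform systematic variation (±0.15 whole-window,
  ±0.2 interior) between conditions, modelling sequence-composition and
  insertion-bias differences; without it, nulls differ only by counting
  noise, whose scale-free Gaussian shape makes rare fence exceedances
  unavoidable at any depth.
* **Single cells**: per-cell depth is bounded uniform (±20%) and planted
  outliers sit at 0.12× (low quality) and 2.5× (doublet-like) depth, so
  they are separated from the normal population by more than 4 scaled
  MADs while normal cells stay safely inside 3 — the QC benchmark is
  then exact rather than probabilistic. A bounded per-cell complexity
  factor (log2-uniform, ±1.4 in natural log) scales low-abundance
  background genes, dominating the detected-genes spread for the same
  reason. Libraries are rescaled per cell so sequencing depth sets the
  total and biology the composition. Trajectory positions are uniform
  within each condition's third of [0, 1]; 80 trajectory genes move
  4-fold log-linearly. Regulon genes are on/off at a detection rate of
  0.08 + 0.62·t in driver-positive cells (65% of cells) and 0.08
  elsewhere, expressed at marker level (mean 30) when on.
* **Knockdown**: 3 control/knockdown pairs, NB dispersion 0.003
  (BCV ≈ 5%, isogenic-culture replicate variability), lognormal baselines
  (meanlog log 2000), planted 2-fold effects on 30 activated and 15
  repressed targets, binding planted on all targets plus 25 unregulated
  genes. At these settings an a-priori power calculation puts the
  expected number of false direct-target calls well below one, so exact
  recovery is the designed behavior, not luck.

What passing these benchmarks does *not* show: real data have GC and
insertion bias, doublets that are not simple depth multiples, ambient
RNA, unbounded technical tails, and batch structure — none of which the
generators emulate. The synthetic study validates the statistical
machinery, not robustness to those artifacts.

# Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 17)
acc <- simulate_accessibility(cfg)
z <- zscore_profiles(cpm_normalize(acc$counts))
fit <- fuzzy_cmeans(z, c = 12, seed = 17)
mg <- merge_clusters(fit, target_K = 4)
table(mg$merged_label, acc$truth$archetype)
```

The full pipeline, including the concordance grid and direct-target
calling, runs from one configuration:

```{r pipeline, eval = FALSE}
run_pipeline(pipeline_config(seed = 17, out_dir = "results"))
```

# Numerical choices and degenerate inputs

Tolerances: fuzzy c-means converges at membership change < 1e-6;
membership rows sum to 1 within 1e-9. Degenerate rules: constant
z-profiles are zero vectors; a profile coinciding with a centroid takes
membership 1 there; empty clusters keep their previous centroid; JD of an
empty union is defined as 1 (JSI 0) and flagged; MCC with a zero margin
is 0 and flagged; a constant co-expression score yields z = 0 with a
warning; −log10 p is capped at 320 where tails underflow; identical
bagplot points are all "bag". Chromosome names are compared exactly — no
silent "chr" aliasing; `normalize_chrom()` exists for deliberate
conversion. All interval coordinates are 0-based half-open internally;
GTF input is converted at the boundary.

# Problem sizes

The test suite and the acceptance script run the generators at their
defaults (2,000 peaks, 60 motifs, 900 cells, 400 genes) — sizes at which
every property check completes in seconds on one core while remaining
large enough for the calibration checks (binomial error bounds at 1,000+
features) to be meaningful.
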