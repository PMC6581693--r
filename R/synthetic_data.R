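#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. All generators are
#' pure functions of `(config, config$seed)`: the same config yields the same
#' data. Defaults describe a toy genome (2 chromosomes x 10 Mb, 400 genes,
#' 2,000 peaks, 3 conditions) on which every pipeline stage runs in seconds;
#' the methods vignette motivates each value.
#'
#' @param seed integer seed driving all randomness.
#' @param n_chrom,chrom_length toy genome shape.
#' @param n_genes,n_peaks,n_conditions dataset sizes (3 conditions model an
#'   ESC / day-1 / day-2 time course).
#' @param archetype_fractions proportions of the four temporal archetypes
#'   (up-up, down-down, transient-up, transient-down); must sum to 1.
#' @param nb_dispersion NB dispersion phi for accessibility counts
#'   (variance `mu + phi * mu^2`).
#' @param effect_fold per-step accessibility fold change of the archetypes.
#' @param peak_baseline_meanlog,peak_baseline_sdlog lognormal baseline of
#'   per-peak mean counts.
#' @param n_motifs,n_footprint_motifs,motif_width,occurrences_per_motif,
#'   cut_halfwidth,cut_rate,footprint_depletion,footprint_fa_fold cut-profile
#'   generator: number of motifs, how many carry a planted footprint gain,
#'   motif width and window half-width (bp), expected cuts per bp per
#'   occurrence, interior depletion factor and flanking-accessibility fold
#'   applied in the gaining conditions (2 and 3).
#' @param motif_window_jitter,motif_interior_jitter half-widths (log2) of
#'   the bounded uniform per-motif per-condition systematic variation in
#'   whole-window depth and interior shape (sequence-composition and
#'   insertion-bias differences between motifs and libraries).
#' @param condition_cut_depth per-condition global cut-depth factors
#'   (library-size differences the normalization must undo).
#' @param n_cells_per_condition,sc_dispersion,sc_gene_meanlog,sc_gene_sdlog,
#'   cell_depth_range,cell_complexity_range single-cell generator: cells per
#'   condition, NB dispersion, lognormal gene-mean law, bounded uniform
#'   per-cell depth factor range and bounded log-uniform complexity factor
#'   range (scales low-abundance gene capture; models per-cell library
#'   diversity without moving total depth).
#' @param outlier_cell_fraction fraction of cells planted as QC outliers
#'   (half low-depth at `low_depth_factor`, half doublet-like at
#'   `doublet_depth_factor`).
#' @param low_depth_factor,doublet_depth_factor depth multipliers of planted
#'   outlier cells.
#' @param n_regulon_activated,n_regulon_repressed,regulon_base_rate,
#'   regulon_max_gain regulon structure: activated/repressed member counts,
#'   background detection rate, and the trajectory-linked detection gain in
#'   driver-positive cells (`rate = base + gain * t`).
#' @param regulon_on_mean expression mean of a regulon gene in cells where
#'   it is on (marker-level expression).
#' @param driver_positive_fraction fraction of cells expressing the driver
#'   transcription factor.
#' @param n_trajectory_genes genes whose expression moves log-linearly
#'   (amplitude `trajectory_fold`) along the trajectory, half up, half down.
#' @param trajectory_fold total fold change of trajectory genes over t in
#'   `[0, 1]`.
#' @param n_replicate_pairs,rna_dispersion,rna_baseline_meanlog,
#'   rna_baseline_sdlog,knockdown_fold,n_bound_null knockdown generator:
#'   paired control/knockdown replicates, NB dispersion (isogenic-culture
#'   replicate variability), baseline law, planted fold, and number of
#'   bound-but-unregulated genes.
#' @return a classed list of settings.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 2L, chrom_length = 1e7,
                              n_genes = 400L, n_peaks = 2000L,
                              n_conditions = 3L,
                              archetype_fractions = c(0.25, 0.25, 0.25, 0.25),
                              nb_dispersion = 0.01,
                              effect_fold = 2,
                              peak_baseline_meanlog = log(100),
                              peak_baseline_sdlog = 1,
                              n_motifs = 60L, n_footprint_motifs = 10L,
                              motif_width = 12L, occurrences_per_motif = 150L,
                              cut_halfwidth = 50L, cut_rate = 1,
                              footprint_depletion = 0.4,
                              footprint_fa_fold = 1.5,
                              motif_window_jitter = 0.15,
                              motif_interior_jitter = 0.2,
                              condition_cut_depth = c(1, 1.2, 0.9),
                              n_cells_per_condition = 300L,
                              sc_dispersion = 0.2,
                              sc_gene_meanlog = log(3), sc_gene_sdlog = 1,
                              cell_depth_range = c(0.8, 1.2),
                              cell_complexity_range = c(-1.4, 1.4),
                              outlier_cell_fraction = 0.04,
                              low_depth_factor = 0.12,
                              doublet_depth_factor = 2.5,
                              n_regulon_activated = 30L,
                              n_regulon_repressed = 15L,
                              regulon_base_rate = 0.08,
                              regulon_max_gain = 0.62,
                              regulon_on_mean = 30,
                              driver_positive_fraction = 0.65,
                              n_trajectory_genes = 80L,
                              trajectory_fold = 4,
                              n_replicate_pairs = 3L,
                              rna_dispersion = 0.003,
                              rna_baseline_meanlog = log(2000),
                              rna_baseline_sdlog = 0.8,
                              knockdown_fold = 2,
                              n_bound_null = 25L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$archetype_fractions) - 1) > 1e-8)
    stop("archetype_fractions must sum to 1")
  if (length(cfg$archetype_fractions) != 4)
    stop("exactly four archetype fractions are required")
  if (cfg$nb_dispersion < 0 || cfg$rna_dispersion < 0 || cfg$sc_dispersion < 0)
    stop("dispersions must be positive")
  if (cfg$n_conditions < 2) stop("need >= 2 conditions")
  if (length(cfg$condition_cut_depth) != cfg$n_conditions)
    cfg$condition_cut_depth <- rep_len(cfg$condition_cut_depth,
                                       cfg$n_conditions)
  structure(cfg, class = "simulation_config")
}

# NB draws parameterized by mean/dispersion; Poisson limit at phi ~ 0
nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

condition_names <- function(config) {
  base <- c("esc", "d1", "d2")
  if (config$n_conditions <= 3) base[seq_len(config$n_conditions)]
  else c(base, paste0("d", 3:(config$n_conditions - 1)))
}

archetype_names <- c("up_up", "down_down", "transient_up", "transient_down")

# per-condition mean multipliers for each archetype, f = effect_fold
archetype_multipliers <- function(f, n_conditions) {
  tt <- seq_len(n_conditions) - 1
  mid <- pmin(tt, rev(tt))          # 0,1,...,1,0 tent profile
  rbind(
    up_up = f^tt,
    down_down = f^(-tt),
    transient_up = f^mid,
    transient_down = f^(-mid)
  )
}

#' Simulate a toy gene annotation
#'
#' Genes are laid on a regular grid across the toy chromosomes with jittered
#' positions, random strand and 10-kb bodies, so nearest-gene assignment is
#' unambiguous at the default density.
#'
#' @param config a [simulation_config()].
#' @return gene models as from [gene_models()].
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  g_per_chrom <- ceiling(config$n_genes / config$n_chrom)
  out <- list()
  gid <- 0
  for (ch in seq_len(config$n_chrom)) {
    n <- min(g_per_chrom, config$n_genes - gid)
    if (n <= 0) break
    spacing <- floor(config$chrom_length / (n + 1))
    tss <- seq_len(n) * spacing +
      as.integer(runif(n, -0.2, 0.2) * spacing)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    body <- 10000L
    start <- ifelse(strand == "+", tss, tss - body + 1L)
    out[[ch]] <- data.frame(
      gene_id = sprintf("gene_%04d", gid + seq_len(n)),
      chrom = paste0("chr", ch), start = start, end = start + body,
      strand = strand, stringsAsFactors = FALSE
    )
    gid <- gid + n
  }
  g <- do.call(rbind, out)
  gene_models(g$gene_id, g$chrom, g$start, g$end, g$strand)
}

#' Simulate temporal accessibility counts with planted archetypes
#'
#' Each peak is assigned one of four temporal archetypes (up-up, down-down,
#' transient-up, transient-down); its per-condition NB mean is a lognormal
#' baseline scaled by the archetype's fold profile. With
#' `config$effect_fold = 1` all archetypes are flat and the dataset is a
#' null for differential-accessibility calibration.
#'
#' @param config a [simulation_config()].
#' @param genes optional gene models used to place peaks; defaults to
#'   [simulate_genome()] of the same config.
#' @return list with `peaks` (intervals), `counts` (a [count_table()],
#'   peaks x conditions), `truth` (`peak_id`, `archetype`), and `genes`.
#' @export
simulate_accessibility <- function(config, genes = NULL) {
  if (is.null(genes)) genes <- simulate_genome(config)
  set.seed(config$seed + 1L)
  n <- config$n_peaks
  chrom <- sample(paste0("chr", seq_len(config$n_chrom)), n, replace = TRUE)
  width <- sample(300:700, n, replace = TRUE)
  start <- floor(runif(n, 0, config$chrom_length - max(width)))
  peaks <- genomic_intervals(chrom, start, start + width,
                             name = sprintf("peak_%05d", seq_len(n)),
                             summit_offset = width %/% 2L)
  arche <- sample(archetype_names, n, replace = TRUE,
                  prob = config$archetype_fractions)
  baseline <- rlnorm(n, config$peak_baseline_meanlog,
                     config$peak_baseline_sdlog)
  mult <- archetype_multipliers(config$effect_fold, config$n_conditions)
  mu <- baseline * mult[arche, , drop = FALSE]
  counts <- matrix(nb_draw(length(mu), as.vector(mu), config$nb_dispersion),
                   nrow = n, dimnames = list(peaks$name,
                                             condition_names(config)))
  list(peaks = peaks,
       counts = count_table(counts),
       truth = data.frame(peak_id = peaks$name, archetype = arche,
                          baseline = baseline, stringsAsFactors = FALSE),
       genes = genes)
}

#' Simulate per-base cut-site counts around motif occurrences
#'
#' Null motifs have flat expected cut rates across the window in every
#' condition (up to global per-condition depth factors); planted motifs gain
#' a footprint in conditions 2..n: interior rate multiplied by
#' `footprint_depletion`, flanking rate by `footprint_fa_fold`. Counts are
#' Poisson per occurrence per base, i.e. multinomial given totals.
#'
#' @param config a [simulation_config()].
#' @return list with `occurrences` (intervals + `motif_id`), `cuts` (one
#'   occurrence x position count matrix per condition), `libsizes`, `truth`
#'   (`motif_id`, `planted`), `motif_width`, `halfwidth`.
#' @export
simulate_cut_profiles <- function(config) {
  set.seed(config$seed + 2L)
  L <- 2L * config$cut_halfwidth + config$motif_width
  if (2L * config$cut_halfwidth < 20L)
    stop("window must extend >= 20 bp beyond the motif")
  n_m <- config$n_motifs
  n_occ <- config$occurrences_per_motif
  motif_ids <- sprintf("motif_%03d", seq_len(n_m))
  planted <- seq_len(n_m) <= config$n_footprint_motifs
  pos <- seq_len(L) - (L + 1) / 2          # distance from window center
  interior <- abs(pos) <= config$motif_width / 2
  occ_chrom <- sample(paste0("chr", seq_len(config$n_chrom)),
                      n_m * n_occ, replace = TRUE)
  occ_start <- floor(runif(n_m * n_occ, 0,
                           config$chrom_length - config$motif_width))
  occurrences <- genomic_intervals(
    occ_chrom, occ_start, occ_start + config$motif_width,
    name = sprintf("occ_%05d", seq_len(n_m * n_occ)),
    strand = sample(c("+", "-"), n_m * n_occ, replace = TRUE)
  )
  occurrences$motif_id <- rep(motif_ids, each = n_occ)
  cond <- condition_names(config)
  # bounded per-motif per-condition systematic variation: motif-specific
  # window depth (sequence composition) and interior shape (insertion
  # bias) differences between libraries, on top of which the planted
  # footprint effects act
  win_fac <- matrix(2^runif(n_m * length(cond),
                            -config$motif_window_jitter,
                            config$motif_window_jitter), n_m)
  int_fac <- matrix(2^runif(n_m * length(cond),
                            -config$motif_interior_jitter,
                            config$motif_interior_jitter), n_m)
  cuts <- list()
  for (j in seq_along(cond)) {
    shape <- matrix(config$cut_rate, nrow = n_m, ncol = L)
    if (j >= 2) {
      shape[planted, interior] <- config$cut_rate * config$footprint_depletion
      shape[planted, !interior] <- config$cut_rate * config$footprint_fa_fold
    }
    shape <- shape * win_fac[, j]
    shape[, interior] <- shape[, interior] * int_fac[, j]
    lambda <- shape[rep(seq_len(n_m), each = n_occ), , drop = FALSE] *
      config$condition_cut_depth[j]
    # multinomial cuts per occurrence: fixed total spread over the window
    # proportionally to the expected per-base rates
    tot <- round(rowSums(lambda))
    m <- t(vapply(seq_len(nrow(lambda)), function(i)
      as.integer(rmultinom(1, tot[i], lambda[i, ])), integer(L)))
    rownames(m) <- occurrences$name
    cuts[[cond[j]]] <- m
  }
  list(occurrences = occurrences, cuts = cuts,
       libsizes = vapply(cuts, sum, 0),
       truth = data.frame(motif_id = motif_ids, planted = planted,
                          stringsAsFactors = FALSE),
       motif_width = config$motif_width, halfwidth = config$cut_halfwidth)
}

# NB detection probability 1 - (1 + phi mu)^(-1/phi); inverse gives the mean
# that yields a target detection rate
nb_mean_for_detection <- function(p, dispersion) {
  if (dispersion <= 1e-12) return(-log(1 - p))
  ((1 - p)^(-dispersion) - 1) / dispersion
}

#' Simulate single-cell counts with planted QC outliers, regulons and a
#' trajectory
#'
#' Cells carry a differentiation position `t` in `[0, 1]` monotone in the
#' condition index. Trajectory genes move log-linearly in `t`; regulon genes
#' are detection-calibrated: activated members are detected at
#' `base + gain * t` in driver-positive cells and at the background rate
#' elsewhere. Per-cell depth is a bounded uniform factor and a bounded
#' complexity factor scales low-abundance background genes, so that planted
#' outlier cells (depth `low_depth_factor` / `doublet_depth_factor`) are
#' separated from the normal population by more than 4 scaled MADs in
#' library size and detected genes.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (cells x genes), `cell_truth` (`cell_id`,
#'   `condition`, `t`, `outlier` in none/low_depth/doublet,
#'   `driver_positive`), `gene_truth` (`gene_id`, `class`), `regulon`
#'   (activated member ids), `regulon_repressed`, `driver_gene`.
#' @export
simulate_single_cells <- function(config) {
  genes <- simulate_genome(config)
  set.seed(config$seed + 3L)
  gid <- genes$gene_id
  G <- length(gid)
  need <- config$n_trajectory_genes + config$n_regulon_activated +
    config$n_regulon_repressed + 1L
  if (need > G) stop("too few genes for the configured structure")
  cls <- rep("background", G)
  idx <- sample.int(G, need)
  n_tr <- config$n_trajectory_genes
  cls[idx[seq_len(n_tr %/% 2)]] <- "trajectory_up"
  cls[idx[(n_tr %/% 2 + 1):n_tr]] <- "trajectory_down"
  a0 <- n_tr
  cls[idx[a0 + seq_len(config$n_regulon_activated)]] <- "regulon_activated"
  a0 <- a0 + config$n_regulon_activated
  cls[idx[a0 + seq_len(config$n_regulon_repressed)]] <- "regulon_repressed"
  cls[idx[need]] <- "driver"

  ncond <- config$n_conditions
  npc <- config$n_cells_per_condition
  ncell <- ncond * npc
  condition <- rep(condition_names(config), each = npc)
  t_pos <- (rep(seq_len(ncond), each = npc) - 1 + runif(ncell)) / ncond

  depth <- runif(ncell, config$cell_depth_range[1], config$cell_depth_range[2])
  outlier <- rep("none", ncell)
  n_out <- round(config$outlier_cell_fraction * ncell)
  if (n_out > 0) {
    oi <- sample.int(ncell, n_out)
    low <- oi[seq_len(ceiling(n_out / 2))]
    high <- setdiff(oi, low)
    outlier[low] <- "low_depth"
    outlier[high] <- "doublet"
    depth[low] <- config$low_depth_factor
    depth[high] <- config$doublet_depth_factor
  }
  driver_positive <- runif(ncell) < config$driver_positive_fraction
  complexity <- exp(runif(ncell, config$cell_complexity_range[1],
                          config$cell_complexity_range[2]))

  base_mu <- rlnorm(G, config$sc_gene_meanlog, config$sc_gene_sdlog)
  phi <- config$sc_dispersion

  # cells x genes expected counts
  mu <- outer(depth, base_mu)
  tr_up <- which(cls == "trajectory_up")
  tr_dn <- which(cls == "trajectory_down")
  amp <- config$trajectory_fold
  mu[, tr_up] <- mu[, tr_up] * amp^(t_pos - 0.5)
  mu[, tr_dn] <- mu[, tr_dn] * amp^(0.5 - t_pos)
  # complexity factor scales low-abundance background genes only
  lowbg <- which(cls == "background" & base_mu < 2)
  mu[, lowbg] <- mu[, lowbg] * complexity

  # detection-calibrated regulon genes: on/off at the target detection
  # rate; expressed at marker level when on
  act <- which(cls == "regulon_activated")
  rep_ <- which(cls == "regulon_repressed")
  p_act <- matrix(config$regulon_base_rate, ncell, length(act))
  p_act[driver_positive, ] <- config$regulon_base_rate +
    config$regulon_max_gain * t_pos[driver_positive]
  p_rep <- matrix(pmax(0.02, 0.6 - 0.4 * t_pos), ncell, length(rep_))
  on_mu <- config$regulon_on_mean * depth
  mu[, act] <- (matrix(runif(length(p_act)), ncell) < pmin(p_act, 0.98)) *
    on_mu
  mu[, rep_] <- (matrix(runif(length(p_rep)), ncell) < p_rep) * on_mu
  drv <- which(cls == "driver")
  mu[, drv] <- ifelse(driver_positive, 5 * depth, 0)

  # library size reflects sequencing depth, composition reflects biology:
  # rescale each cell's expected counts to depth x a fixed target total
  target <- depth * sum(base_mu)
  mu <- mu * (target / rowSums(mu))

  counts <- matrix(nb_draw(length(mu), as.vector(mu), phi),
                   nrow = ncell,
                   dimnames = list(sprintf("cell_%04d", seq_len(ncell)), gid))
  list(counts = counts,
       cell_truth = data.frame(cell_id = rownames(counts),
                               condition = condition, t = t_pos,
                               outlier = outlier,
                               driver_positive = driver_positive,
                               stringsAsFactors = FALSE),
       gene_truth = data.frame(gene_id = gid, class = cls,
                               stringsAsFactors = FALSE),
       regulon = gid[act], regulon_repressed = gid[rep_],
       driver_gene = gid[drv], genes = genes)
}

#' Simulate a paired control/knockdown expression experiment
#'
#' Planted activated targets drop by `knockdown_fold` in the knockdown
#' samples, repressed targets rise by the same fold, all other genes are
#' unchanged. Binding (a TF peak assigned to the gene) is planted on all
#' regulated targets plus `n_bound_null` unregulated genes, and TF peak
#' intervals are emitted 500 bp upstream of each bound gene's TSS so the
#' nearest-gene route can be exercised end to end.
#'
#' @param config a [simulation_config()].
#' @param regulon_truth optional list with `regulon` and `regulon_repressed`
#'   gene-id vectors (as returned by [simulate_single_cells()]); when absent
#'   targets are drawn fresh from the toy genome.
#' @return list with `counts` (a [count_table()] with paired columns),
#'   `pairs` (control/knockdown column pairing), `truth` (`gene_id`,
#'   `planted_class`, `bound`, `direction`), `tf_peaks`, `genes`.
#' @export
simulate_knockdown <- function(config, regulon_truth = NULL) {
  genes <- simulate_genome(config)
  set.seed(config$seed + 4L)
  gid <- genes$gene_id
  G <- length(gid)
  if (is.null(regulon_truth)) {
    pick <- sample(gid, config$n_regulon_activated +
                     config$n_regulon_repressed)
    activated <- pick[seq_len(config$n_regulon_activated)]
    repressed <- setdiff(pick, activated)
  } else {
    activated <- regulon_truth$regulon
    repressed <- regulon_truth$regulon_repressed
  }
  others <- setdiff(gid, c(activated, repressed))
  bound_null <- sample(others, config$n_bound_null)
  bound <- c(activated, repressed, bound_null)

  np <- config$n_replicate_pairs
  if (np < 2) stop("need >= 2 replicate pairs")
  baseline <- rlnorm(G, config$rna_baseline_meanlog, config$rna_baseline_sdlog)
  fold <- rep(1, G)
  names(fold) <- gid
  fold[activated] <- 1 / config$knockdown_fold
  fold[repressed] <- config$knockdown_fold
  pair_depth <- rlnorm(np, 0, 0.05)
  cols <- as.vector(rbind(paste0("ctrl_", seq_len(np)),
                          paste0("kd_", seq_len(np))))
  mu <- matrix(0, G, 2 * np)
  for (p in seq_len(np)) {
    mu[, 2 * p - 1] <- baseline * pair_depth[p]
    mu[, 2 * p] <- baseline * pair_depth[p] * fold
  }
  counts <- matrix(nb_draw(length(mu), as.vector(mu), config$rna_dispersion),
                   nrow = G, dimnames = list(gid, cols))
  direction <- rep(NA_character_, G)
  if (config$knockdown_fold != 1) {       # fold 1 plants no effect
    direction[gid %in% activated] <- "down_in_kd"
    direction[gid %in% repressed] <- "up_in_kd"
  } else {
    activated <- repressed <- character(0)
  }
  tss <- genes$tss[match(bound, genes$gene_id)]
  sgn <- ifelse(genes$strand[match(bound, genes$gene_id)] == "+", 1L, -1L)
  pk_start <- pmax(0L, tss - sgn * 500L - 100L)
  tf_peaks <- genomic_intervals(genes$chrom[match(bound, genes$gene_id)],
                                pk_start, pk_start + 200L,
                                name = paste0("tf_", bound),
                                summit_offset = 100L)
  list(counts = count_table(counts),
       pairs = data.frame(control = paste0("ctrl_", seq_len(np)),
                          knockdown = paste0("kd_", seq_len(np)),
                          stringsAsFactors = FALSE),
       truth = data.frame(
         gene_id = gid,
         planted_class = ifelse(gid %in% activated, "activated",
                         ifelse(gid %in% repressed, "repressed", "null")),
         bound = gid %in% bound, direction = direction,
         stringsAsFactors = FALSE),
       tf_peaks = tf_peaks, genes = genes)
}
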