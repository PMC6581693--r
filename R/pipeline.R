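#' Pipeline configuration
#'
#' A declarative description of a full synthetic-data pipeline run: the
#' seed, which stages to execute, the output directory, and every
#' threshold of the downstream stages (surfaced with the defaults used
#' throughout the package).
#'
#' @param seed integer seed; recorded in the manifest and forwarded to
#'   every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("atlas", "dynamics", "footprint", "single_cell", "integration")`.
#' @param sim a [simulation_config()]; defaults to
#'   `simulation_config(seed)`.
#' @param merge_gap,min_frac,promoter_window atlas thresholds.
#' @param min_cpm,fold_promoter,fold_distal,alpha,n_clusters,target_K
#'   differential-accessibility and clustering thresholds.
#' @param fence_factor bagplot fence inflation.
#' @param qc_mads,gene_min_mean,hvg_fdr,auc_top_fraction single-cell
#'   thresholds.
#' @param bins_kb concordance distance bins.
#' @return classed list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cadence_"),
                            stages = c("atlas", "dynamics", "footprint",
                                       "single_cell", "integration"),
                            sim = NULL,
                            merge_gap = 100, min_frac = 0.5,
                            promoter_window = c(2000, 500),
                            min_cpm = 4, fold_promoter = 2,
                            fold_distal = 2.5, alpha = 0.05,
                            n_clusters = 12, target_K = 4,
                            fence_factor = 3,
                            qc_mads = 3, gene_min_mean = 0.05,
                            hvg_fdr = 0.05, auc_top_fraction = 0.05,
                            bins_kb = c(10, 25, 50, 75, 100, 150, 200,
                                        250)) {
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  cfg <- as.list(environment())
  known <- c("atlas", "dynamics", "footprint", "single_cell", "integration")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys mirror the [pipeline_config()] arguments; keys under `sim:`
#' are passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed) && !is.null(y$seed))
      sim_args$seed <- y$seed
    y$sim <- do.call(simulation_config, sim_args)
  }
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Stages run in dependency order (atlas -> dynamics -> footprint ->
#' single_cell -> integration); a stage whose upstream dependency is
#' toggled off fails with an error naming it. Every output file is listed
#' in a JSON manifest with its MD5 hash; reruns with the same
#' configuration reproduce the hashes.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return manifest list (invisibly also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(stage, dep) {
    if (!dep %in% config$stages)
      stop("stage '", stage, "' requires upstream stage '", dep,
           "' which is not enabled")
  }
  files <- character(0)
  emit <- function(path) files <<- c(files, path)
  log_stage <- function(...) message("[cadence] ", ...)

  sim <- config$sim
  atlas <- NULL
  dyn <- NULL
  acc <- NULL

  if ("atlas" %in% config$stages) {
    log_stage("atlas: building union atlas")
    acc <- simulate_accessibility(sim)
    cond_sets <- setNames(rep(list(acc$peaks), sim$n_conditions),
                          condition_names(sim))
    atlas <- build_atlas(cond_sets, acc$genes, min_frac = config$min_frac,
                         merge_gap = config$merge_gap,
                         promoter_window = config$promoter_window,
                         counts = acc$counts)
    atlas$truth <- acc$truth
    emit(write_bed(atlas$peaks[, c("chrom", "start", "end", "name",
                                   "score", "strand", "summit_offset")],
                   file.path(config$out_dir, "atlas_peaks.bed")))
    emit(write_tsv(atlas$peaks[, c("name", "partition", "nearest_gene",
                                   "distance")],
                   file.path(config$out_dir, "atlas_annotation.tsv")))
    emit(write_count_table(atlas$counts,
                           file.path(config$out_dir, "atlas_counts.tsv"),
                           id_col = "peak_id"))
  }

  if ("dynamics" %in% config$stages) {
    need("dynamics", "atlas")
    log_stage("dynamics: differential accessibility and fuzzy clustering")
    # peak-level counts follow the simulated union set (one column per
    # condition); promoter peaks use the lower fold threshold
    counts <- atlas$counts
    part <- partition_atlas(acc$peaks, atlas$genes, config$promoter_window)
    # unreplicated condition columns: assume the conventional BCV 0.1
    diff_pro <- differential_features(counts, min_cpm = config$min_cpm,
                                      min_fold = config$fold_promoter,
                                      alpha = config$alpha,
                                      dispersion = 0.01)
    diff_dst <- differential_features(counts, min_cpm = config$min_cpm,
                                      min_fold = config$fold_distal,
                                      alpha = config$alpha,
                                      dispersion = 0.01)
    da <- ifelse(part == "promoter", diff_pro$passes, diff_dst$passes)
    nm <- cpm_normalize(counts)
    z <- zscore_profiles(nm)
    keep <- da & apply(z, 1, function(r) any(r != 0))
    pc <- fuzzy_cmeans(z[keep, , drop = FALSE], c = config$n_clusters,
                       seed = sim$seed)
    mg <- merge_clusters(pc, target_K = config$target_K)
    dyn <- list(differential = diff_dst, partition = part, z = z,
                keep = keep, clustering = pc, merged = mg)
    lab <- data.frame(peak_id = rownames(z[keep, , drop = FALSE]),
                      cluster = pc$hard_label,
                      merged_cluster = mg$merged_label,
                      stringsAsFactors = FALSE)
    emit(write_tsv(lab, file.path(config$out_dir, "dynamics_clusters.tsv")))
    emit(write_tsv(data.frame(cluster = seq_len(nrow(pc$centroids)),
                              pc$centroids),
                   file.path(config$out_dir, "dynamics_centroids.tsv")))
    emit(write_tsv(diff_dst,
                   file.path(config$out_dir, "dynamics_differential.tsv")))
  }

  if ("footprint" %in% config$stages) {
    log_stage("footprint: bivariate footprinting")
    fp <- simulate_cut_profiles(sim)
    panel <- footprint_panel(fp$occurrences, fp$cuts[[1]], fp$cuts[[2]],
                             halfwidth = fp$halfwidth,
                             motif_width = fp$motif_width,
                             fence_factor = config$fence_factor)
    emit(write_tsv(panel, file.path(config$out_dir, "footprint_stats.tsv")))
    bag <- attr(panel, "bagplot")
    jsonlite::write_json(
      list(bag = bag$bag, fence = bag$fence,
           depth_median = bag$depth_median),
      file.path(config$out_dir, "footprint_bagplot.json"),
      auto_unbox = TRUE, digits = NA)
    emit(file.path(config$out_dir, "footprint_bagplot.json"))
  }

  sc <- NULL
  if ("single_cell" %in% config$stages) {
    log_stage("single_cell: QC, HVGs, co-expression, regulon activity")
    scd <- simulate_single_cells(sim)
    pass <- qc_cells(scd$counts, n_mads = config$qc_mads)
    kept_genes <- filter_genes(scd$counts, pass, config$gene_min_mean)
    mat <- scd$counts[pass, kept_genes, drop = FALSE]
    norm <- sc_normalize(mat)
    hv <- hvg_select(norm$cpm, fdr = config$hvg_fdr)
    # order cells on HVGs independent of the regulon under study
    ordering_genes <- setdiff(attr(hv, "hvgs"),
                              c(scd$regulon, scd$regulon_repressed,
                                scd$driver_gene))
    pt <- pseudotime_rank(norm$cpm, ordering_genes,
                          condition = scd$cell_truth$condition[pass])
    reg <- intersect(scd$regulon, kept_genes)
    auc <- regulon_auc(norm$cpm, reg,
                       top_fraction = config$auc_top_fraction,
                       seed = sim$seed)
    zscore <- coexpression_score(norm$binary, reg,
                                 condition = scd$cell_truth$condition[pass])
    pb <- pseudobulk(scd$counts, scd$cell_truth$condition, pass)
    sc <- list(data = scd, qc_pass = pass, genes = kept_genes,
               norm = norm, hvg = hv, pseudotime = pt, auc = auc,
               coexpr_z = zscore, pseudobulk = pb)
    emit(write_tsv(attr(pass, "qc_metrics"),
                   file.path(config$out_dir, "sc_qc.tsv")))
    emit(write_tsv(hv, file.path(config$out_dir, "sc_hvg.tsv")))
    emit(write_tsv(data.frame(cell_id = names(pt), pseudotime = pt,
                              coexpression_z = as.numeric(zscore)),
                   file.path(config$out_dir, "sc_cells.tsv")))
    emit(write_tsv(auc, file.path(config$out_dir, "sc_regulon_auc.tsv")))
    emit(write_count_table(pb, file.path(config$out_dir,
                                         "sc_pseudobulk.tsv"),
                           id_col = "gene_id"))
  }

  if ("integration" %in% config$stages) {
    need("integration", "dynamics")
    need("integration", "single_cell")
    log_stage("integration: concordance grid and direct targets")
    genes <- atlas$genes
    kept <- which(dyn$keep)
    atac_cl <- split(acc$peaks[kept, , drop = FALSE],
                     paste0("A", dyn$merged$merged_label))
    # expression clusters from pseudo-bulk temporal profiles
    pbn <- cpm_normalize(sc$pseudobulk)
    pbz <- zscore_profiles(pbn)
    ok <- apply(pbz, 1, function(r) any(r != 0))
    pcc <- fuzzy_cmeans(pbz[ok, , drop = FALSE], c = config$target_K,
                        seed = sim$seed)
    rna_cl <- split(rownames(pbz)[ok], paste0("R", pcc$hard_label))
    grid <- distance_binned_enrichment(atac_cl, rna_cl, genes,
                                       bins_kb = config$bins_kb)
    emit(write_tsv(grid, file.path(config$out_dir,
                                   "integration_concordance.tsv")))
    kd <- simulate_knockdown(sim, regulon_truth = sc$data)
    de <- differential_expression(kd$counts, kd$pairs)
    bound <- unique(assign_nearest_gene(kd$tf_peaks, kd$genes)$gene_id)
    targets <- call_direct_targets(bound, de)
    emit(write_tsv(targets$targets,
                   file.path(config$out_dir, "integration_targets.tsv")))
    emit(write_tsv(de, file.path(config$out_dir, "integration_de.tsv")))
  }

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write the full synthetic dataset to disk
#'
#' Emits the BED/TSV/MTX dialects the readers in this package accept, plus
#' truth tables for every planted structure.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return character vector of written files, invisibly.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  acc <- simulate_accessibility(config)
  files <- c(files,
             write_bed(acc$peaks, file.path(out_dir, "peaks.bed")),
             write_count_table(acc$counts,
                               file.path(out_dir, "peak_counts.tsv"),
                               id_col = "peak_id"),
             write_tsv(acc$truth, file.path(out_dir, "peak_truth.tsv")),
             write_tsv(data.frame(gene_id = acc$genes$gene_id,
                                  chrom = acc$genes$chrom,
                                  start = acc$genes$body_start,
                                  end = acc$genes$body_end,
                                  strand = acc$genes$strand),
                       file.path(out_dir, "genes.tsv")))
  fp <- simulate_cut_profiles(config)
  occ <- fp$occurrences
  files <- c(files, write_tsv(occ, file.path(out_dir, "motif_occurrences.tsv")),
             write_tsv(fp$truth, file.path(out_dir, "motif_truth.tsv")))
  for (cond in names(fp$cuts)) {
    p <- file.path(out_dir, paste0("cuts_", cond, ".tsv"))
    write.table(data.frame(occurrence_id = rownames(fp$cuts[[cond]]),
                           fp$cuts[[cond]], check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  sc <- simulate_single_cells(config)
  mm <- file.path(out_dir, "sc_counts.mtx")
  Matrix::writeMM(Matrix::Matrix(t(sc$counts), sparse = TRUE), mm)
  writeLines(colnames(sc$counts), file.path(out_dir, "sc_genes.txt"))
  writeLines(rownames(sc$counts), file.path(out_dir, "sc_cells.txt"))
  files <- c(files, mm, file.path(out_dir, "sc_genes.txt"),
             file.path(out_dir, "sc_cells.txt"),
             write_tsv(sc$cell_truth, file.path(out_dir, "sc_cell_truth.tsv")),
             write_tsv(sc$gene_truth, file.path(out_dir, "sc_gene_truth.tsv")))
  kd <- simulate_knockdown(config, regulon_truth = sc)
  files <- c(files,
             write_count_table(kd$counts, file.path(out_dir, "kd_counts.tsv"),
                               id_col = "gene_id"),
             write_tsv(kd$pairs, file.path(out_dir, "kd_pairs.tsv")),
             write_tsv(kd$truth, file.path(out_dir, "kd_truth.tsv")),
             write_bed(kd$tf_peaks, file.path(out_dir, "tf_peaks.bed")))
  invisible(files)
}
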