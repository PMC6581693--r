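#' Distance-binned concordance of accessibility and expression clusters
#'
#' For every accessibility cluster Ai, distance bin b and expression
#' cluster Rj: K is the set of genes whose TSS lies within +/- b of the
#' center of any peak in Ai, and the overlap x = |K intersect Rj| is tested
#' for enrichment with the hypergeometric upper tail
#' `P(X >= x)` over the gene universe (the exact form of the
#' random-expected-set comparison). Bins are independent half-widths, each
#' with its own K-set.
#'
#' @param atac_clusters named list of interval sets (peak clusters).
#' @param rna_clusters named list of gene-id vectors (expression clusters);
#'   must lie within the gene universe.
#' @param genes gene models defining the TSS positions and the universe.
#' @param bins_kb distance half-widths in kb (default the 8 bins spanning
#'   +/- 10 to +/- 250 kb).
#' @param randomized optionally estimate the expected overlap by `n_draws`
#'   random gene draws instead of the exact tail (fidelity check; slower).
#' @param n_draws draws for the randomized check.
#' @return `data.frame` grid with `atac_cluster`, `rna_cluster`, `bin_kb`,
#'   `K`, `n`, `x`, `N`, `p`, `neg_log10_p` (and `p_randomized` when
#'   requested).
#' @export
distance_binned_enrichment <- function(atac_clusters, rna_clusters, genes,
                                       bins_kb = c(10, 25, 50, 75, 100,
                                                   150, 200, 250),
                                       randomized = FALSE, n_draws = 1000) {
  stopifnot(is.list(atac_clusters), is.list(rna_clusters))
  universe <- genes$gene_id
  N <- length(universe)
  for (nm in names(rna_clusters)) {
    missing <- setdiff(rna_clusters[[nm]], universe)
    if (length(missing))
      stop("expression cluster '", nm, "' has genes outside the universe: ",
           paste(head(missing, 5), collapse = ", "))
  }
  out <- list()
  for (ai in names(atac_clusters)) {
    peaks <- atac_clusters[[ai]]
    check_intervals(peaks, ai)
    centers <- interval_center(peaks)
    for (b in bins_kb) {
      half <- b * 1000
      near <- logical(N)
      for (ch in unique(peaks$chrom)) {
        gi <- which(genes$chrom == ch)
        if (!length(gi)) next
        cc <- sort(centers[peaks$chrom == ch])
        pos <- findInterval(genes$tss[gi], cc)
        lo <- ifelse(pos >= 1, genes$tss[gi] - cc[pmax(pos, 1)], Inf)
        hi <- ifelse(pos < length(cc),
                     cc[pmin(pos + 1L, length(cc))] - genes$tss[gi], Inf)
        near[gi] <- pmin(lo, hi) <= half
      }
      K <- sum(near)
      kset <- universe[near]
      for (rj in names(rna_clusters)) {
        set <- rna_clusters[[rj]]
        n <- length(set)
        x <- length(intersect(kset, set))
        p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
        row <- data.frame(atac_cluster = ai, rna_cluster = rj, bin_kb = b,
                          K = K, n = n, x = x, N = N, p = p,
                          neg_log10_p = -log10(pmax(p, 1e-320)),
                          stringsAsFactors = FALSE)
        if (randomized) {
          draws <- vapply(seq_len(n_draws), function(i)
            length(intersect(sample(universe, n), kset)), 0L)
          row$p_randomized <- (sum(draws >= x) + 1) / (n_draws + 1)
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  do.call(rbind, out)
}

#' Call direct targets of a transcription factor
#'
#' Direct targets are genes both bound (a TF peak assigned to the gene)
#' and differentially expressed upon factor depletion. Genes going down in
#' the knockdown are classified `activated` (the factor was needed for
#' their expression); genes going up are `repressed`.
#'
#' @param bound_genes gene ids bound by the factor (e.g. from
#'   [assign_nearest_gene()] on TF peaks).
#' @param de_results `data.frame` from [differential_expression()] (needs
#'   `feature_id`, `de`, `direction`).
#' @return list with `targets` (`data.frame`: `gene_id`, `de_direction`,
#'   `class`) and `summary` (`n_total`, `n_activated`, `n_repressed`,
#'   `percent_activated` rounded to integer percent).
#' @export
call_direct_targets <- function(bound_genes, de_results) {
  de <- de_results[de_results$de %in% TRUE, , drop = FALSE]
  hit <- de[de$feature_id %in% bound_genes, , drop = FALSE]
  targets <- data.frame(
    gene_id = hit$feature_id, de_direction = hit$direction,
    class = ifelse(hit$direction == "down_in_kd", "activated", "repressed"),
    stringsAsFactors = FALSE)
  n_tot <- nrow(targets)
  n_act <- sum(targets$class == "activated")
  list(targets = targets,
       summary = list(
         n_total = n_tot, n_activated = n_act,
         n_repressed = n_tot - n_act,
         percent_activated = if (n_tot) round(100 * n_act / n_tot) else 0))
}

#' Overlap of a regulon with stage-specific marker sets
#'
#' Reports, per developmental stage set, the proportion of its genes
#' contained in the regulon, and the regulon's own composition across the
#' stages.
#'
#' @param regulon gene-id set.
#' @param stage_sets named list of gene-id sets.
#' @return list with `per_stage` (`data.frame`: `stage`, `size`, `overlap`,
#'   `proportion`; empty sets give `NA`) and `composition` (share of the
#'   regulon-stage overlaps attributable to each stage).
#' @export
stage_marker_overlap <- function(regulon, stage_sets) {
  stopifnot(is.list(stage_sets), !is.null(names(stage_sets)))
  per <- do.call(rbind, lapply(names(stage_sets), function(nm) {
    s <- stage_sets[[nm]]
    ov <- length(intersect(regulon, s))
    data.frame(stage = nm, size = length(s), overlap = ov,
               proportion = if (length(s)) ov / length(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tot <- sum(per$overlap)
  comp <- if (tot > 0) per$overlap / tot else rep(NA_real_, nrow(per))
  names(comp) <- per$stage
  list(per_stage = per, composition = comp)
}
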