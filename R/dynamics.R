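#' Counts-per-million normalization
#'
#' @param counts a [count_table()] or numeric matrix with dimnames.
#' @param pseudocount added before the log2 transform.
#' @return list with `cpm` and `log_cpm` matrices, class
#'   `normalized_matrix`.
#' @export
cpm_normalize <- function(counts, pseudocount = 1) {
  ct <- if (inherits(counts, "count_table")) counts else count_table(counts)
  if (any(ct$lib_sizes <= 0)) stop("zero library size")
  cpm <- sweep(ct$counts, 2, ct$lib_sizes, "/") * 1e6
  structure(list(cpm = cpm, log_cpm = log2(cpm + pseudocount),
                 pseudocount = pseudocount),
            class = "normalized_matrix")
}

# method-of-moments common NB dispersion on library-size-adjusted counts,
# floored at 1e-4; with replicated groups the within-group moments are used
moment_dispersion <- function(adj, groups = NULL, floor = 1e-4) {
  est_rows <- function(m) {
    mu <- rowMeans(m)
    s2 <- apply(m, 1, var)
    ok <- mu > 0
    (s2[ok] - mu[ok]) / mu[ok]^2
  }
  if (!is.null(groups) && any(table(groups) >= 2)) {
    phis <- unlist(lapply(unique(groups), function(g) {
      cols <- which(groups == g)
      if (length(cols) >= 2) est_rows(adj[, cols, drop = FALSE])
    }))
  } else {
    phis <- est_rows(adj)
  }
  max(floor, median(phis, na.rm = TRUE))
}

# two-sided conditional NB exact test: given the total s = y1 + y2 of two
# equal-mean NB variables, sum the conditional probabilities of outcomes no
# more likely than the observed split
nb_exact_test <- function(y1, y2, dispersion, n1 = 1, n2 = 1) {
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  mu <- s / (n1 + n2)
  lp <- dnbinom(k, size = n1 / dispersion, mu = n1 * mu, log = TRUE) +
    dnbinom(s - k, size = n2 / dispersion, mu = n2 * mu, log = TRUE)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[y1 + 1] * (1 + 1e-8)])
}

#' Differentially accessible / expressed features across conditions
#'
#' For every pair of conditions a negative-binomial exact test is run on
#' library-size-adjusted counts (common dispersion estimated by the method
#' of moments across features, floored at 1e-4), with BH correction over
#' features per pair. A feature passes when its CPM reaches `min_cpm` in
#' some condition and some pair shows fold >= `min_fold` with q < `alpha`
#' (the CPM >= 4, q < 0.05, fold >= 2 promoter / >= 2.5 distal filter).
#'
#' @param counts [count_table()] or matrix, features x samples.
#' @param groups condition assignment per column (defaults to one condition
#'   per column).
#' @param min_cpm minimum CPM required in at least one condition.
#' @param min_fold minimum pairwise fold change (on CPM + pseudocount).
#' @param alpha BH-adjusted significance threshold.
#' @param pseudocount pseudocount for fold changes.
#' @param dispersion optional fixed NB dispersion. By default a common
#'   dispersion is moment-estimated from the data; supply a value (e.g.
#'   `0.01`, BCV 0.1) for unreplicated designs where condition effects
#'   would inflate the estimate.
#' @return `data.frame` with `feature_id`, `max_cpm`, `max_pairwise_fold`,
#'   `p`, `q` (minima over pairs at the maximizing pair), `best_pair`,
#'   `direction`, `passes`.
#' @export
differential_features <- function(counts, groups = NULL, min_cpm = 4,
                                  min_fold = 2, alpha = 0.05,
                                  pseudocount = 1, dispersion = NULL) {
  ct <- if (inherits(counts, "count_table")) counts else count_table(counts)
  y <- ct$counts
  if (is.null(groups)) groups <- colnames(y)
  groups <- as.character(groups)
  conds <- unique(groups)
  if (length(conds) < 2) stop("need >= 2 conditions")
  if (any(!table(factor(groups, conds)) >= 1)) stop("empty condition group")
  lib <- ct$lib_sizes
  ref <- exp(mean(log(lib)))
  adj <- sweep(y, 2, ref / lib, "*")
  phi <- if (is.null(dispersion)) moment_dispersion(adj, groups)
         else max(dispersion, 1e-4)
  # per-condition mean CPM and adjusted sums
  cpm <- sweep(y, 2, lib, "/") * 1e6
  cond_cpm <- sapply(conds, function(g)
    rowMeans(cpm[, groups == g, drop = FALSE]))
  cond_sum <- sapply(conds, function(g)
    rowSums(adj[, groups == g, drop = FALSE]))
  nrep <- as.integer(table(factor(groups, conds)))
  names(nrep) <- conds

  pairs <- utils::combn(conds, 2, simplify = FALSE)
  n <- nrow(y)
  best <- data.frame(feature_id = rownames(y),
                     max_cpm = apply(cond_cpm, 1, max),
                     max_pairwise_fold = rep(1, n), p = rep(1, n),
                     q = rep(1, n), best_pair = NA_character_,
                     direction = NA_character_,
                     stringsAsFactors = FALSE)
  pair_pass <- rep(FALSE, n)
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    ya <- round(cond_sum[, a]); yb <- round(cond_sum[, b])
    pv <- vapply(seq_len(n), function(i)
      nb_exact_test(ya[i], yb[i], phi, nrep[a], nrep[b]), 0)
    qv <- p.adjust(pv, "BH")
    fa <- (cond_cpm[, a] + pseudocount) / (cond_cpm[, b] + pseudocount)
    fold <- pmax(fa, 1 / fa)
    better <- fold > best$max_pairwise_fold |
      (fold == best$max_pairwise_fold & qv < best$q)
    best$max_pairwise_fold[better] <- fold[better]
    best$p[better] <- pv[better]
    best$q[better] <- qv[better]
    best$best_pair[better] <- paste(a, b, sep = ":")
    best$direction[better] <- ifelse(fa[better] > 1, paste0("up_in_", a),
                                     paste0("up_in_", b))
    pair_pass <- pair_pass | (fold >= min_fold & qv < alpha)
  }
  best$passes <- best$max_cpm >= min_cpm & pair_pass
  attr(best, "dispersion") <- phi
  best
}

#' Paired differential expression with consistency rescue
#'
#' Genes are tested on per-pair log2 CPM differences with a paired t test.
#' A gene is differential when `|mean fold| > min_fold` and `p < alpha`, or
#' is *rescued* when every replicate pair changes in the same direction and
#' the mean fold still exceeds `min_fold` (the > 1.2-fold, p < 0.05 rule
#' with the paired-consistency rescue).
#'
#' @param counts [count_table()] or matrix, genes x samples.
#' @param pairs `data.frame` with `control` and `knockdown` column names,
#'   one row per replicate pair.
#' @param min_fold fold-change threshold (strict `>`).
#' @param alpha p-value threshold.
#' @param pseudocount pseudocount for CPM fold changes.
#' @return `data.frame` with `feature_id`, `log2_fold` (knockdown vs
#'   control mean), `fold`, `p`, `consistent`, `rescue`, `de`, `direction`
#'   (`down_in_kd` / `up_in_kd`).
#' @export
differential_expression <- function(counts, pairs, min_fold = 1.2,
                                    alpha = 0.05, pseudocount = 1) {
  ct <- if (inherits(counts, "count_table")) counts else count_table(counts)
  if (!all(c(pairs$control, pairs$knockdown) %in% colnames(ct$counts)))
    stop("pairing names samples absent from the count table")
  if (nrow(pairs) < 2) stop("need >= 2 replicate pairs")
  nm <- cpm_normalize(ct, pseudocount)
  d <- nm$log_cpm[, pairs$knockdown, drop = FALSE] -
    nm$log_cpm[, pairs$control, drop = FALSE]
  m <- rowMeans(d)
  pv <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    if (sd(x) == 0) return(if (all(x == 0)) 1 else 0)
    t.test(x)$p.value
  }, 0)
  consistent <- apply(d, 1, function(x) all(x > 0) || all(x < 0))
  big <- abs(m) > log2(min_fold)
  primary <- big & pv < alpha
  rescue <- !primary & consistent & big
  data.frame(feature_id = rownames(nm$cpm), log2_fold = m, fold = 2^abs(m),
             p = pv, consistent = consistent, rescue = rescue,
             de = primary | rescue,
             direction = ifelse(m < 0, "down_in_kd", "up_in_kd"),
             stringsAsFactors = FALSE)
}

#' z-score temporal profiles
#'
#' Per feature, the condition-mean log2 CPM vector is centered and divided
#' by its population standard deviation; constant profiles map to the zero
#' vector.
#'
#' @param normalized a `normalized_matrix` from [cpm_normalize()] (or a
#'   plain matrix of log values).
#' @param condition_order column names giving the temporal order; when
#'   columns are replicated samples, supply `groups` to average first.
#' @param groups optional condition per column for replicate averaging.
#' @return features x T matrix of z-profiles.
#' @export
zscore_profiles <- function(normalized, condition_order = NULL,
                            groups = NULL) {
  m <- if (inherits(normalized, "normalized_matrix")) normalized$log_cpm
       else as.matrix(normalized)
  if (!is.null(groups)) {
    conds <- unique(as.character(groups))
    m <- sapply(conds, function(g)
      rowMeans(m[, groups == g, drop = FALSE]))
  }
  if (!is.null(condition_order)) m <- m[, condition_order, drop = FALSE]
  if (ncol(m) < 2) stop("need >= 2 conditions")
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))          # population SD
  z <- (m - mu) / ifelse(s == 0, Inf, s)
  z
}

#' Motif enrichment per accessibility cluster
#'
#' For each motif and cluster, counts cluster peaks containing at least one
#' motif occurrence, compares against the occurrence rate in background
#' peaks with a binomial survival test, and z-normalizes `-log10 p` per
#' motif across clusters. `-log10 p` is capped at 320 where the tail
#' underflows.
#'
#' @param cluster_peaksets named list of interval sets (one per cluster).
#' @param motif_occurrences intervals with a `motif_id` column.
#' @param background_peaks intervals supplying the background rate.
#' @return list with `neg_log10_p` and `z` (motif x cluster matrices) and
#'   `background_rate` per motif. Empty clusters give `NA` columns.
#' @export
cluster_motif_enrichment <- function(cluster_peaksets, motif_occurrences,
                                     background_peaks) {
  stopifnot(is.list(cluster_peaksets))
  if (is.null(names(cluster_peaksets)))
    names(cluster_peaksets) <- paste0("cluster", seq_along(cluster_peaksets))
  check_intervals(motif_occurrences, "occurrences")
  motifs <- sort(unique(motif_occurrences$motif_id))
  has_occ <- function(peaks) {
    # peaks containing >= 1 occurrence of each motif (any overlap)
    res <- matrix(FALSE, nrow(peaks), length(motifs),
                  dimnames = list(NULL, motifs))
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      oi <- which(motif_occurrences$chrom == ch)
      if (!length(oi)) next
      pr <- IRanges::IRanges(peaks$start[pi] + 1L, peaks$end[pi])
      or <- IRanges::IRanges(motif_occurrences$start[oi] + 1L,
                             motif_occurrences$end[oi])
      hits <- IRanges::findOverlaps(pr, or)
      if (!length(hits)) next
      mi <- match(motif_occurrences$motif_id[oi][S4Vectors::subjectHits(hits)],
                  motifs)
      res[cbind(pi[S4Vectors::queryHits(hits)], mi)] <- TRUE
    }
    res
  }
  bg <- has_occ(background_peaks)
  rate <- colMeans(bg)
  nl <- matrix(NA_real_, length(motifs), length(cluster_peaksets),
               dimnames = list(motifs, names(cluster_peaksets)))
  for (j in seq_along(cluster_peaksets)) {
    cl <- cluster_peaksets[[j]]
    if (is.null(cl) || !nrow(cl)) next
    fg <- has_occ(cl)
    k <- colSums(fg)
    n <- nrow(cl)
    p <- pbinom(k - 1, n, rate, lower.tail = FALSE)
    nl[, j] <- pmin(-log10(pmax(p, 1e-320)), 320)
  }
  z <- t(apply(nl, 1, function(r) {
    ok <- !is.na(r)
    if (sum(ok) < 2 || sd(r[ok]) == 0) return(ifelse(ok, 0, NA_real_))
    (r - mean(r[ok])) / sd(r[ok])
  }))
  dimnames(z) <- dimnames(nl)
  list(neg_log10_p = nl, z = z, background_rate = rate)
}
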