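#' Concordant peaks between two replicates
#'
#' Retains peaks of `rep1` that reciprocally overlap some peak of `rep2` by
#' at least `min_frac` of *both* peak lengths (the `intersectBed -f 0.50 -r`
#' criterion used to build high-confidence replicate peak sets).
#'
#' @param rep1,rep2 interval sets (see [genomic_intervals()]).
#' @param min_frac required overlap fraction of both lengths, in `(0, 1]`.
#' @return the retained subset of `rep1`, in input order.
#' @export
concordant_peaks <- function(rep1, rep2, min_frac = 0.5) {
  check_intervals(rep1, "rep1")
  check_intervals(rep2, "rep2")
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]")
  keep <- logical(nrow(rep1))
  for (ch in unique(rep1$chrom)) {
    i1 <- which(rep1$chrom == ch)
    i2 <- which(rep2$chrom == ch)
    if (!length(i2)) next
    r1 <- IRanges::IRanges(rep1$start[i1] + 1L, rep1$end[i1])
    r2 <- IRanges::IRanges(rep2$start[i2] + 1L, rep2$end[i2])
    hits <- IRanges::findOverlaps(r1, r2)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(r1[q], r2[s]))
    w1 <- IRanges::width(r1[q])
    w2 <- IRanges::width(r2[s])
    ok <- ov >= min_frac * w1 & ov >= min_frac * w2
    keep[i1[unique(q[ok])]] <- TRUE
  }
  rep1[keep, , drop = FALSE]
}

#' Merge condition peak sets into a union atlas
#'
#' Single-linkage merge of peaks whose anchor (summit when present, midpoint
#' otherwise) lies strictly less than `max_gap` bp from another peak's
#' anchor on the same chromosome (the `mergePeaks d = 100` union-set rule).
#' Merged intervals span the min start / max end of their members; the
#' contributing source sets are recorded in `sources`.
#'
#' @param condition_peaksets a list of interval sets, optionally named by
#'   condition.
#' @param max_gap anchor-to-anchor merge distance in bp (strict `<`).
#' @return merged intervals with `name`, `summit_offset` (mean anchor) and
#'   `sources` columns, sorted by chromosome and start.
#' @export
merge_union <- function(condition_peaksets, max_gap = 100) {
  if (!length(condition_peaksets)) stop("need >= 1 peakset")
  if (is.null(names(condition_peaksets)))
    names(condition_peaksets) <- paste0("set", seq_along(condition_peaksets))
  all <- do.call(rbind, lapply(names(condition_peaksets), function(nm) {
    x <- condition_peaksets[[nm]]
    check_intervals(x, nm)
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               anchor = interval_anchor(x), source = nm,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (ch in unique(all$chrom)) {
    a <- all[all$chrom == ch, , drop = FALSE]
    a <- a[order(a$anchor, a$start), , drop = FALSE]
    # on sorted 1-D anchors single-linkage groups are runs of gaps < max_gap
    grp <- cumsum(c(1, diff(a$anchor) >= max_gap))
    merged <- lapply(split(seq_len(nrow(a)), grp), function(ii) {
      data.frame(chrom = ch, start = min(a$start[ii]), end = max(a$end[ii]),
                 anchor = round(mean(a$anchor[ii])),
                 sources = paste(sort(unique(a$source[ii])), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, merged)
  }
  m <- do.call(rbind, out)
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  res <- genomic_intervals(m$chrom, m$start, m$end,
                           name = sprintf("union_%05d", seq_len(nrow(m))),
                           summit_offset = pmin(m$anchor - m$start,
                                                m$end - m$start - 1L))
  res$sources <- m$sources
  rownames(res) <- NULL
  res
}

#' Partition atlas peaks by genomic context
#'
#' A peak is `promoter` when its center falls in
#' `[TSS - upstream, TSS + downstream)` of any gene in TSS-oriented
#' coordinates, else `intragenic` when its center lies within any gene body,
#' else `intergenic` (precedence promoter > intragenic > intergenic).
#' Defaults follow the -2 kb / +0.5 kb promoter window used for
#' accessibility partitioning; widen `upstream` to 2,500 for the annotation
#' convention used for TF-binding peaks.
#'
#' @param peaks intervals.
#' @param genes gene models (see [gene_models()]).
#' @param promoter_window `c(upstream_bp, downstream_bp)`.
#' @return character vector of labels, one per peak.
#' @export
partition_atlas <- function(peaks, genes, promoter_window = c(2000, 500)) {
  check_intervals(peaks)
  if (!nrow(genes)) stop("genes must be non-empty")
  center <- interval_center(peaks)
  label <- rep("intergenic", nrow(peaks))
  intra <- logical(nrow(peaks))
  promo <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    for (g in gi) {
      sgn <- if (genes$strand[g] == "+") 1L else -1L
      d <- (center[pi] - genes$tss[g]) * sgn
      promo[pi] <- promo[pi] |
        (d >= -promoter_window[1] & d < promoter_window[2])
      intra[pi] <- intra[pi] |
        (center[pi] >= genes$body_start[g] & center[pi] < genes$body_end[g])
    }
  }
  label[intra] <- "intragenic"
  label[promo] <- "promoter"
  label
}

#' Assign each peak to its nearest gene TSS
#'
#' Distance is measured from the peak center to the TSS; ties on absolute
#' distance break to the lexicographically smaller `gene_id`. The signed
#' distance is positive downstream of the TSS in gene orientation. Peaks on
#' chromosomes without genes get `NA`.
#'
#' @param peaks intervals.
#' @param genes gene models.
#' @return `data.frame` with `gene_id` and `distance` per peak.
#' @export
assign_nearest_gene <- function(peaks, genes) {
  check_intervals(peaks)
  if (!nrow(genes)) stop("genes must be non-empty")
  center <- interval_center(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    gg <- genes[gi, , drop = FALSE]
    ord <- order(gg$gene_id)           # lexicographic tie-break
    gg <- gg[ord, , drop = FALSE]
    for (p in pi) {
      d <- abs(center[p] - gg$tss)
      k <- which.min(d)                # first (lexicographically smallest) min
      sgn <- if (gg$strand[k] == "+") 1L else -1L
      gene_id[p] <- gg$gene_id[k]
      distance[p] <- (center[p] - gg$tss[k]) * sgn
    }
  }
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}

#' Subset query peaks whose summit is near an atlas summit
#'
#' Retains query peaks whose anchor (summit, else midpoint) lies within
#' `max_gap` bp (inclusive) of any atlas peak anchor on the same chromosome
#' (the `mergePeaks d = 250` intersection rule used to subset TF-binding
#' peaks by differentially accessible regions).
#'
#' @param query_peaks,atlas interval sets.
#' @param max_gap maximum summit distance in bp.
#' @return retained subset of `query_peaks`, in input order.
#' @export
intersect_with_atlas <- function(query_peaks, atlas, max_gap = 250) {
  check_intervals(query_peaks, "query")
  check_intervals(atlas, "atlas")
  qa <- interval_anchor(query_peaks)
  aa <- interval_anchor(atlas)
  keep <- logical(nrow(query_peaks))
  for (ch in unique(query_peaks$chrom)) {
    qi <- which(query_peaks$chrom == ch)
    ai <- which(atlas$chrom == ch)
    if (!length(ai)) next
    s <- sort(aa[ai])
    pos <- findInterval(qa[qi], s)
    lo <- ifelse(pos >= 1, qa[qi] - s[pmax(pos, 1)], Inf)
    hi <- ifelse(pos < length(s), s[pmin(pos + 1L, length(s))] - qa[qi], Inf)
    keep[qi] <- pmin(lo, hi) <= max_gap
  }
  query_peaks[keep, , drop = FALSE]
}

#' Build a peak atlas from replicate peak sets
#'
#' Convenience wrapper: per-condition replicate concordance, union merging,
#' genomic partitioning and nearest-gene assignment in one call.
#'
#' @param replicate_sets named list (one element per condition) of lists of
#'   replicate interval sets; a condition may also map directly to a single
#'   interval set.
#' @param genes gene models.
#' @param min_frac reciprocal-overlap fraction for replicate concordance.
#' @param merge_gap summit merge distance for the union set.
#' @param promoter_window promoter window passed to [partition_atlas()].
#' @param counts optional [count_table()] aligned to the merged peaks.
#' @return list with `peaks` (merged intervals + `partition`, `nearest_gene`,
#'   `distance`) and `counts`, class `peak_atlas`.
#' @export
build_atlas <- function(replicate_sets, genes, min_frac = 0.5,
                        merge_gap = 100, promoter_window = c(2000, 500),
                        counts = NULL) {
  condition_sets <- lapply(replicate_sets, function(reps) {
    if (is.data.frame(reps)) return(reps)
    if (length(reps) == 1) return(reps[[1]])
    conc <- reps[[1]]
    for (k in 2:length(reps)) conc <- concordant_peaks(conc, reps[[k]],
                                                       min_frac)
    conc
  })
  peaks <- merge_union(condition_sets, max_gap = merge_gap)
  peaks$partition <- partition_atlas(peaks, genes, promoter_window)
  ng <- assign_nearest_gene(peaks, genes)
  peaks$nearest_gene <- ng$gene_id
  peaks$distance <- ng$distance
  structure(list(peaks = peaks, counts = counts, genes = genes),
            class = "peak_atlas")
}
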