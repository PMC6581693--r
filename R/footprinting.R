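#' Aggregate cut-site profiles around motif occurrences
#'
#' Averages per-base cut counts over the occurrences of a motif, reversing
#' minus-strand occurrences so that aggregate profiles are in motif
#' orientation, and scales to cuts per base per 10 million library cuts.
#'
#' @param occurrences intervals of one motif's occurrences (rows of the cut
#'   table are matched by `name`); a `motif_id` column, when present, must
#'   be constant.
#' @param cut_counts occurrence x position count matrix whose columns span
#'   the window.
#' @param halfwidth window half-width in bp on each side of the motif.
#' @param motif_width motif width in bp.
#' @param libsize total cuts in the library (defaults to `sum(cut_counts)`).
#' @param condition label stored on the profile.
#' @param restrict_to optional intervals (e.g. an atlas subset); only
#'   occurrences overlapping them are aggregated.
#' @return list of class `cut_profile`: `motif_id`, `condition`,
#'   `halfwidth`, `motif_width`, `profile` (length
#'   `2 * halfwidth + motif_width`), `n_occurrences`, `n_skipped`,
#'   `libsize`.
#' @export
aggregate_cuts <- function(occurrences, cut_counts, halfwidth, motif_width,
                           libsize = NULL, condition = NA_character_,
                           restrict_to = NULL) {
  check_intervals(occurrences, "occurrences")
  motif_id <- if ("motif_id" %in% names(occurrences))
    unique(occurrences$motif_id) else NA_character_
  if (length(motif_id) != 1)
    stop("aggregate_cuts expects occurrences of a single motif")
  L <- 2L * halfwidth + motif_width
  if (ncol(cut_counts) != L)
    stop("cut table has ", ncol(cut_counts), " columns; window needs ", L)
  if (is.null(libsize)) libsize <- sum(cut_counts)
  occ <- occurrences
  if (!is.null(restrict_to)) {
    keep <- logical(nrow(occ))
    for (ch in unique(occ$chrom)) {
      oi <- which(occ$chrom == ch)
      ai <- which(restrict_to$chrom == ch)
      if (!length(ai)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(occ$start[oi] + 1L, occ$end[oi]),
        IRanges::IRanges(restrict_to$start[ai] + 1L, restrict_to$end[ai]))
      keep[oi[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    occ <- occ[keep, , drop = FALSE]
  }
  idx <- match(occ$name, rownames(cut_counts))
  skipped <- sum(is.na(idx))
  if (skipped) warning(skipped, " occurrence(s) outside the cut table; skipped")
  occ <- occ[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no occurrences covered by the cut table")
  m <- cut_counts[idx, , drop = FALSE]
  rev_rows <- occ$strand == "-"
  if (any(rev_rows))
    m[rev_rows, ] <- m[rev_rows, L:1, drop = FALSE]
  profile <- colMeans(m) * 1e7 / libsize
  structure(list(motif_id = motif_id, condition = condition,
                 halfwidth = halfwidth, motif_width = motif_width,
                 profile = unname(profile), n_occurrences = nrow(m),
                 n_skipped = skipped, libsize = libsize),
            class = "cut_profile")
}

profile_regions <- function(L, motif_width, flank_margin) {
  center <- (L + 1) / 2
  pos <- seq_len(L) - center
  interior <- abs(pos) <= motif_width / 2
  flank <- abs(pos) > motif_width / 2 + flank_margin
  if (!any(flank)) stop("window leaves no flanking positions")
  list(interior = interior, flank = flank)
}

#' Footprint depth and flanking accessibility for a condition pair
#'
#' For each condition, flanking accessibility FA is the mean normalized cut
#' density in the flanks (positions more than `motif_width/2 + flank_margin`
#' from the window center) and footprint depth is
#' `FPD = log2((FA + eps) / (interior mean + eps))`. The comparison returns
#' `delta_fa = log2(FA_b / FA_a)` and `delta_fpd = FPD_b - FPD_a`, the two
#' coordinates of the bivariate footprinting plane.
#'
#' @param profile_a,profile_b `cut_profile`s of the same motif in the two
#'   conditions (a = reference, b = comparison).
#' @param flank_margin bp excluded between motif edge and flank.
#' @param epsilon stabilizer of the log ratios.
#' @return `data.frame` row with `motif_id`, `fa_a`, `fa_b`, `fpd_a`,
#'   `fpd_b`, `delta_fa`, `delta_fpd`.
#' @export
footprint_stats <- function(profile_a, profile_b, flank_margin = 10,
                            epsilon = 0.1) {
  stopifnot(inherits(profile_a, "cut_profile"),
            inherits(profile_b, "cut_profile"))
  if (length(profile_a$profile) != length(profile_b$profile) ||
      profile_a$motif_width != profile_b$motif_width)
    stop("profiles have mismatched windows")
  if (epsilon <= 0) stop("epsilon must be > 0")
  L <- length(profile_a$profile)
  reg <- profile_regions(L, profile_a$motif_width, flank_margin)
  one <- function(p) {
    fa <- mean(p[reg$flank])
    int <- mean(p[reg$interior])
    c(fa = fa, fpd = log2((fa + epsilon) / (int + epsilon)))
  }
  a <- one(profile_a$profile)
  b <- one(profile_b$profile)
  data.frame(motif_id = profile_a$motif_id,
             fa_a = a["fa"], fa_b = b["fa"],
             fpd_a = a["fpd"], fpd_b = b["fpd"],
             delta_fa = log2(b["fa"] / a["fa"]),
             delta_fpd = unname(b["fpd"] - a["fpd"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run bivariate footprinting over a motif panel
#'
#' Aggregates cuts per motif in two conditions, computes footprint
#' statistics and classifies motifs on the (delta FA, delta FPD) plane with
#' [bagplot_classify()].
#'
#' @param occurrences intervals with `motif_id` for all motifs.
#' @param cuts_a,cuts_b occurrence x position cut tables for the two
#'   conditions.
#' @param halfwidth,motif_width window geometry (bp).
#' @param libsize_a,libsize_b library totals (default: table sums).
#' @param flank_margin,epsilon see [footprint_stats()].
#' @param fence_factor see [bagplot_classify()].
#' @param restrict_to optional atlas subset restriction.
#' @return `data.frame` of footprint statistics with a `classification`
#'   column; bag/fence polygons in `attr(, "bagplot")`.
#' @export
footprint_panel <- function(occurrences, cuts_a, cuts_b, halfwidth,
                            motif_width, libsize_a = NULL, libsize_b = NULL,
                            flank_margin = 10, epsilon = 0.1,
                            fence_factor = 3, restrict_to = NULL) {
  motifs <- unique(occurrences$motif_id)
  rows <- lapply(motifs, function(mid) {
    occ <- occurrences[occurrences$motif_id == mid, , drop = FALSE]
    pa <- aggregate_cuts(occ, cuts_a, halfwidth, motif_width,
                         libsize = libsize_a, condition = "a",
                         restrict_to = restrict_to)
    pb <- aggregate_cuts(occ, cuts_b, halfwidth, motif_width,
                         libsize = libsize_b, condition = "b",
                         restrict_to = restrict_to)
    footprint_stats(pa, pb, flank_margin, epsilon)
  })
  res <- do.call(rbind, rows)
  bag <- bagplot_classify(cbind(res$delta_fa, res$delta_fpd),
                          fence_factor = fence_factor)
  res$classification <- bag$classification
  attr(res, "bagplot") <- bag
  res
}
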