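#' Cell quality control by median absolute deviation
#'
#' A cell fails when its library size falls below `median - n_mads * MAD`,
#' when its number of detected genes falls below the analogous threshold,
#' or when its library size exceeds `median + n_mads * MAD` (doublet
#' filter; applied to library size only). Inequalities are strict, so a
#' dataset of identical cells (MAD 0) passes entirely.
#'
#' @param counts cells x genes count matrix.
#' @param n_mads number of MADs.
#' @param mad_scale scale the MAD by 1.4826 (normal consistency), the
#'   convention of standard single-cell QC.
#' @return logical `qc_pass` per cell with a `qc_metrics` attribute
#'   (`data.frame` of library sizes, detected genes, and the three flags).
#' @export
qc_cells <- function(counts, n_mads = 3, mad_scale = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 10) stop("need >= 10 cells for MAD-based QC")
  const <- if (mad_scale) 1.4826 else 1
  lib <- rowSums(counts)
  ngene <- rowSums(counts > 0)
  th <- function(v) {
    m <- median(v)
    d <- mad(v, constant = const)
    c(lo = m - n_mads * d, hi = m + n_mads * d)
  }
  tl <- th(lib)
  tg <- th(ngene)
  low_lib <- lib < tl["lo"]
  low_genes <- ngene < tg["lo"]
  high_lib <- lib > tl["hi"]
  pass <- !(low_lib | low_genes | high_lib)
  attr(pass, "qc_metrics") <- data.frame(
    cell_id = rownames(counts), library_size = lib, detected_genes = ngene,
    low_library = low_lib, low_genes = low_genes, high_library = high_lib,
    stringsAsFactors = FALSE)
  pass
}

#' Filter lowly expressed genes
#'
#' Keeps genes whose mean raw count across QC-passing cells reaches
#' `min_mean` (0.05 by default: detection in ~5% of cells at 1 count).
#'
#' @param counts cells x genes counts.
#' @param qc_pass logical per cell; defaults to all cells.
#' @param min_mean minimum mean raw count.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(counts, qc_pass = NULL, min_mean = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(qc_pass)) qc_pass <- rep(TRUE, nrow(counts))
  mu <- colMeans(counts[qc_pass, , drop = FALSE])
  colnames(counts)[mu >= min_mean]
}

#' Size factors and CPM for single cells
#'
#' Size factors are the library sizes centered to unit mean over the
#' QC-passing cells; CPM divides by the effective library size
#' (`size_factor * mean library`).
#'
#' @param counts cells x genes counts (QC-passing cells, filtered genes).
#' @return list with `size_factor`, `cpm`, `log_cpm` (log2(cpm+1)) and
#'   `binary` detection indicators.
#' @export
sc_normalize <- function(counts) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  if (any(lib <= 0)) stop("cell with empty library; run QC first")
  sf <- lib / mean(lib)
  cpm <- counts / (sf * mean(lib)) * 1e6
  list(size_factor = sf, cpm = cpm, log_cpm = log2(cpm + 1),
       binary = counts > 0)
}

#' Highly variable genes by mean-variance trend decomposition
#'
#' Fits a technical trend of variance against mean of `log2(cpm + 1)` by a
#' running median followed by loess, decomposes each gene's variance into
#' trend (technical) and residual (biological) components, and tests the
#' variance ratio on the scaled chi-square law
#' `var * (n-1) / trend ~ chi2(n-1)` with BH correction. HVGs have positive
#' biological variance and `q < fdr`.
#'
#' @param cpm cells x genes CPM matrix.
#' @param fdr BH threshold.
#' @param span loess span of the trend.
#' @return `data.frame` per gene (`mean`, `total`, `technical`,
#'   `biological`, `p`, `q`, `hvg`), with the selected ids in
#'   `attr(, "hvgs")`.
#' @export
hvg_select <- function(cpm, fdr = 0.05, span = 0.3) {
  y <- log2(as.matrix(cpm) + 1)
  ncell <- nrow(y)
  if (ncol(y) < 50) stop("need >= 50 genes to fit a mean-variance trend")
  mu <- colMeans(y)
  v <- apply(y, 2, var)
  ord <- order(mu)
  k <- min(51L, (length(mu) %/% 2) * 2 + 1)
  vmed <- runmed(v[ord], k)
  fit <- loess(vmed ~ mu[ord], span = span, degree = 2,
               family = "symmetric")
  tech <- predict(fit, mu)
  # clamp extrapolation and keep the trend positive
  tech[is.na(tech)] <- predict(fit, pmin(pmax(mu[is.na(tech)],
                                              min(mu[ord])), max(mu[ord])))
  tech <- pmax(tech, 1e-8)
  bio <- v - tech
  p <- pchisq(v * (ncell - 1) / tech, df = ncell - 1, lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  res <- data.frame(gene_id = colnames(y), mean = mu, total = v,
                    technical = tech, biological = bio, p = p, q = q,
                    hvg = bio > 0 & q < fdr, stringsAsFactors = FALSE)
  attr(res, "hvgs") <- res$gene_id[res$hvg]
  res
}

#' Binary co-expression score per cell
#'
#' Sums detection indicators over a gene set per cell and z-transforms the
#' sums over all (QC-passing) cells pooled, using the population standard
#' deviation. Optionally also reports per-condition summaries in which
#' every condition carries equal weight.
#'
#' @param binary cells x genes detection matrix.
#' @param gene_set gene ids scored.
#' @param condition optional condition label per cell; when given, a
#'   `condition_summary` attribute holds per-condition mean/median z.
#' @return numeric z score per cell (`score` attribute holds the raw sums).
#' @export
coexpression_score <- function(binary, gene_set, condition = NULL) {
  binary <- as.matrix(binary)
  missing <- setdiff(gene_set, colnames(binary))
  if (length(missing))
    stop("gene set outside universe: ", paste(head(missing, 5),
                                              collapse = ", "))
  s <- if (length(gene_set)) rowSums(binary[, gene_set, drop = FALSE])
       else rep(0, nrow(binary))
  sdev <- sqrt(mean((s - mean(s))^2))      # population SD
  if (sdev == 0) {
    warning("constant co-expression score; z set to 0")
    z <- rep(0, length(s))
  } else z <- (s - mean(s)) / sdev
  names(z) <- rownames(binary)
  attr(z, "score") <- s
  if (!is.null(condition)) {
    attr(z, "condition_summary") <- do.call(rbind, lapply(
      unique(condition), function(g) data.frame(
        condition = g, mean_z = mean(z[condition == g]),
        median_z = median(z[condition == g]), n = sum(condition == g),
        stringsAsFactors = FALSE)))
  }
  z
}

coexpr_order <- function(mat, how = c("hclust", "pc1")) {
  how <- match.arg(how)
  if (how == "hclust") {
    hclust(dist(mat), method = "average")$order
  } else {
    order(prcomp(mat, center = TRUE, scale. = FALSE)$x[, 1])
  }
}

#' Jaccard similarity matrix of binary co-expression
#'
#' For genes g, h the Jaccard distance is
#' `JD = 1 - |both detected| / |either detected|` and the similarity is
#' `JSI = 1 - JD^2`. Rows/columns are ordered by average-linkage
#' hierarchical clustering of the reference condition's matrix; pass that
#' ordering via `reference_order` to plot other conditions in the same
#' order.
#'
#' @param binary cells x genes detection matrix (already subset to the
#'   condition of interest).
#' @param gene_list genes to correlate.
#' @param reference_order optional ordering (gene ids or indices) inherited
#'   from the reference condition.
#' @return symmetric JSI matrix with attributes `order` (the ordering
#'   used), `statistic`, and `undetected` (genes with no detecting cell,
#'   whose rows are NA).
#' @export
jsi_matrix <- function(binary, gene_list, reference_order = NULL) {
  b <- as.matrix(binary[, gene_list, drop = FALSE]) * 1
  det <- colSums(b) > 0
  inter <- crossprod(b)
  tot <- outer(colSums(b), colSums(b), "+")
  un <- tot - inter
  jd <- ifelse(un > 0, 1 - inter / un, 1)
  jsi <- 1 - jd^2
  jsi[!det, ] <- NA_real_
  jsi[, !det] <- NA_real_
  diag(jsi)[det] <- 1
  ord <- resolve_order(reference_order, gene_list,
                       default = function() {
                         m <- jsi
                         m[is.na(m)] <- 0
                         coexpr_order(m, "hclust")
                       })
  out <- jsi[ord, ord]
  attr(out, "order") <- gene_list[ord]
  attr(out, "statistic") <- "JSI"
  attr(out, "undetected") <- gene_list[!det]
  out
}

#' Matthews correlation matrix of binary co-expression
#'
#' Per gene pair, the Matthews correlation coefficient of the two detection
#' vectors (the phi coefficient of their 2 x 2 contingency table; equal to
#' the Pearson correlation of the binary vectors). Pairs with a zero margin
#' (a gene detected in all or no cells) are set to 0 and flagged. The
#' reference ordering is by the first principal component of the matrix.
#'
#' @inheritParams jsi_matrix
#' @return symmetric MCC matrix with `order`, `statistic` and
#'   `zero_margin` attributes.
#' @export
mcc_matrix <- function(binary, gene_list, reference_order = NULL) {
  b <- as.matrix(binary[, gene_list, drop = FALSE]) * 1
  n <- nrow(b)
  cs <- colSums(b)
  margin0 <- cs == 0 | cs == n
  tp <- crossprod(b)
  mcc <- matrix(0, ncol(b), ncol(b), dimnames = list(gene_list, gene_list))
  num <- n * tp - outer(cs, cs)
  den <- sqrt(outer(cs * (n - cs), cs * (n - cs)))
  ok <- den > 0
  mcc[ok] <- num[ok] / den[ok]
  diag(mcc)[!margin0] <- 1
  ord <- resolve_order(reference_order, gene_list,
                       default = function() coexpr_order(mcc, "pc1"))
  out <- mcc[ord, ord]
  attr(out, "order") <- gene_list[ord]
  attr(out, "statistic") <- "MCC"
  attr(out, "zero_margin") <- gene_list[margin0]
  out
}

resolve_order <- function(reference_order, gene_list, default) {
  if (is.null(reference_order)) return(default())
  if (is.character(reference_order)) {
    ord <- match(reference_order, gene_list)
    if (anyNA(ord)) stop("reference_order names genes absent from gene_list")
    return(ord)
  }
  as.integer(reference_order)
}

#' Regulon activity as area under the recovery curve
#'
#' Ranks genes per cell by decreasing expression (ties broken by a seeded
#' shuffle), walks the top `top_fraction` of the ranking accumulating
#' regulon genes, and normalizes the area under this recovery curve by its
#' maximum possible value. Cells are called active when the AUC exceeds a
#' threshold chosen by Otsu's method on the AUC distribution (or a manual
#' `threshold`).
#'
#' @param cpm cells x genes expression matrix.
#' @param regulon gene set.
#' @param top_fraction fraction of the ranking integrated.
#' @param seed seed of the tie-breaking shuffle.
#' @param threshold optional manual activity threshold.
#' @return `data.frame` with `cell_id`, `auc`, `active`; the threshold in
#'   `attr(, "threshold")`.
#' @export
regulon_auc <- function(cpm, regulon, top_fraction = 0.05, seed = 1,
                        threshold = NULL) {
  cpm <- as.matrix(cpm)
  G <- ncol(cpm)
  members <- colnames(cpm) %in% regulon
  if (!any(members)) stop("regulon has no genes in the expression universe")
  kmax <- ceiling(top_fraction * G)
  if (kmax < 1) stop("top_fraction too small for the gene universe")
  R <- sum(members)
  max_area <- sum(pmin(seq_len(kmax), R))
  set.seed(seed)
  tie <- matrix(runif(length(cpm)), nrow(cpm))
  auc <- vapply(seq_len(nrow(cpm)), function(i) {
    ord <- order(-cpm[i, ], tie[i, ])[seq_len(kmax)]
    sum(cumsum(members[ord])) / max_area
  }, 0)
  if (is.null(threshold)) threshold <- otsu_threshold(auc)
  if (is.null(rownames(cpm))) rownames(cpm) <- seq_len(nrow(cpm))
  res <- data.frame(cell_id = rownames(cpm), auc = auc,
                    active = auc > threshold, stringsAsFactors = FALSE)
  attr(res, "threshold") <- threshold
  res
}

# Otsu's between-class variance maximizer on a 256-bin histogram
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Rank-based pseudotime along the first principal component
#'
#' A deliberately simple trajectory summary: the first principal component
#' of z-scored log2 CPM over the highly variable genes, min-max rescaled to
#' `[0, 1]` and oriented so that pseudotime increases with the condition
#' order when conditions are supplied. Graph-based trajectory methods are
#' out of scope; this stub provides the ordering the downstream summaries
#' need.
#'
#' @param cpm cells x genes CPM.
#' @param hvgs highly variable gene ids (>= 2).
#' @param condition optional ordered condition index/factor per cell used
#'   to orient the axis.
#' @return numeric pseudotime per cell in `[0, 1]`.
#' @export
pseudotime_rank <- function(cpm, hvgs, condition = NULL) {
  hvgs <- intersect(hvgs, colnames(cpm))
  if (length(hvgs) < 2) stop("need >= 2 highly variable genes")
  y <- log2(as.matrix(cpm)[, hvgs, drop = FALSE] + 1)
  s <- apply(y, 2, sd)
  y <- y[, s > 0, drop = FALSE]
  if (ncol(y) < 2) stop("degenerate expression: fewer than 2 variable genes")
  z <- scale(y)
  pc1 <- prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  if (!is.null(condition)) {
    # factors orient by their level order (permutation invariant);
    # character vectors fall back to order of first appearance
    ci <- if (is.numeric(condition)) condition
          else if (is.factor(condition)) as.integer(condition)
          else as.integer(factor(condition, levels = unique(condition)))
    if (cor(pc1, ci) < 0) pc1 <- -pc1
  }
  pt <- (pc1 - min(pc1)) / (max(pc1) - min(pc1))
  names(pt) <- rownames(cpm)
  pt
}

#' Regulon expression along the trajectory, stratified by a driver gene
#'
#' Per cell, the fraction of regulon genes detected, z-transformed over all
#' cells (population SD), reported alongside pseudotime and split by
#' whether the driver gene is detected.
#'
#' @param binary cells x genes detection matrix.
#' @param regulon regulon gene ids.
#' @param pseudotime numeric per cell.
#' @param driver driver gene id (stratifies cells by its detection) or a
#'   logical vector per cell.
#' @return `data.frame` with `cell_id`, `pseudotime`, `fraction`, `z`,
#'   `driver_positive`.
#' @export
regulon_trajectory <- function(binary, regulon, pseudotime, driver) {
  binary <- as.matrix(binary)
  frac <- rowMeans(binary[, intersect(regulon, colnames(binary)),
                          drop = FALSE])
  sdev <- sqrt(mean((frac - mean(frac))^2))
  z <- if (sdev == 0) rep(0, length(frac)) else (frac - mean(frac)) / sdev
  dp <- if (is.character(driver)) binary[, driver] > 0 else as.logical(driver)
  data.frame(cell_id = rownames(binary), pseudotime = pseudotime,
             fraction = frac, z = z, driver_positive = dp,
             stringsAsFactors = FALSE)
}

#' Aggregate single cells into pseudo-bulk condition profiles
#'
#' Sums counts over QC-passing cells per condition; the result feeds the
#' bulk machinery (CPM filters, fuzzy clustering).
#'
#' @param counts cells x genes counts.
#' @param condition condition per cell.
#' @param qc_pass logical per cell (default all).
#' @return a [count_table()], genes x conditions.
#' @export
pseudobulk <- function(counts, condition, qc_pass = NULL) {
  counts <- as.matrix(counts)
  if (is.null(qc_pass)) qc_pass <- rep(TRUE, nrow(counts))
  conds <- unique(as.character(condition))
  agg <- sapply(conds, function(g) {
    rows <- qc_pass & condition == g
    if (!any(rows)) stop("condition '", g, "' has no QC-passing cells")
    colSums(counts[rows, , drop = FALSE])
  })
  count_table(agg)
}
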