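# Independent brute-force oracles used to validate the fast implementations.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                             width = 50:500, with_summit = TRUE) {
  w <- sample(width, n, replace = TRUE)
  s <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), s, s + w,
                    name = sprintf("iv%04d", seq_len(n)),
                    summit_offset = if (with_summit) w %/% 2L else NA)
}

# all-pairs reciprocal-overlap oracle
oracle_concordant <- function(rep1, rep2, min_frac) {
  keep <- vapply(seq_len(nrow(rep1)), function(i) {
    any(vapply(seq_len(nrow(rep2)), function(j) {
      if (rep1$chrom[i] != rep2$chrom[j]) return(FALSE)
      ov <- min(rep1$end[i], rep2$end[j]) - max(rep1$start[i], rep2$start[j])
      w1 <- rep1$end[i] - rep1$start[i]
      w2 <- rep2$end[j] - rep2$start[j]
      ov >= min_frac * w1 && ov >= min_frac * w2
    }, TRUE))
  }, TRUE)
  rep1[keep, , drop = FALSE]
}

# union-find transitive-closure oracle for summit-distance merging
oracle_merge_groups <- function(chrom, anchor, max_gap) {
  n <- length(anchor)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        abs(anchor[i] - anchor[j]) < max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# exhaustive nearest-TSS oracle with lexicographic tie-break
oracle_nearest <- function(peaks, genes) {
  center <- (peaks$start + peaks$end) %/% 2L
  out <- data.frame(gene_id = rep(NA_character_, nrow(peaks)),
                    distance = rep(NA_integer_, nrow(peaks)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(center[i] - g$tss)
    cand <- g[d == min(d), , drop = FALSE]
    best <- cand[order(cand$gene_id)[1], ]
    sgn <- if (best$strand == "+") 1L else -1L
    out$gene_id[i] <- best$gene_id
    out$distance[i] <- (center[i] - best$tss) * sgn
  }
  out
}

# O(n^3) Tukey-depth oracle: halfplanes through every point pair, probed
# just off each boundary direction
oracle_tukey_depth <- function(x) {
  n <- nrow(x)
  eps <- 1e-9
  vapply(seq_len(n), function(i) {
    rel <- sweep(x, 2, x[i, ])
    r <- sqrt(rowSums(rel^2))
    others <- which(r > 1e-12)
    if (!length(others)) return(n)
    best <- n
    for (j in others) {
      base <- atan2(rel[j, 2], rel[j, 1])
      for (phi in c(base + pi / 2, base - pi / 2)) {
        for (dphi in c(-eps, eps)) {
          u <- c(cos(phi + dphi), sin(phi + dphi))
          cnt <- sum(rel %*% u >= 0)
          best <- min(best, cnt)
        }
      }
    }
    as.integer(best)
  }, 0L)
}

# two-sided conditional NB exact-test oracle by direct summation
oracle_nb_exact <- function(y1, y2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  pr <- vapply(0:s, function(k)
    dnbinom(k, size = 1 / phi, mu = s / 2) *
      dnbinom(s - k, size = 1 / phi, mu = s / 2), 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[y1 + 1] * (1 + 1e-8)])
}

# hypergeometric upper-tail oracle by term-wise enumeration
oracle_hyper_tail <- function(x, K, N, n) {
  xs <- x:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}
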