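#' Fuzzy c-means clustering of temporal profiles
#'
#' Alternating-update fuzzy c-means with fuzzifier `m`: centroids are
#' membership^m-weighted means, memberships follow the inverse-distance
#' rule `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`. A profile coinciding
#' with a centroid gets membership 1 there. The best of `n_starts` random
#' restarts (by the objective `sum u^m d^2`) is returned; convergence is
#' declared when the largest membership change falls below `tol`.
#'
#' @param z_profiles numeric matrix, features x time points (typically from
#'   [zscore_profiles()]).
#' @param c number of clusters (`>= 2`, `< n`).
#' @param m fuzzifier (`> 1`).
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap per restart.
#' @param n_starts random restarts.
#' @param seed integer seed for the restarts.
#' @param init optional c x T matrix of starting centroids (then a single
#'   run from that initialization is performed).
#' @return list of class `profile_clustering`: `membership` (n x c),
#'   `centroids` (c x T), `hard_label`, `m`, `objective`, `objective_trace`
#'   of the winning run, `iterations`.
#' @export
fuzzy_cmeans <- function(z_profiles, c, m = 2, tol = 1e-6, max_iter = 500,
                         n_starts = 5, seed = 1, init = NULL) {
  x <- as.matrix(z_profiles)
  n <- nrow(x)
  if (c < 2) stop("c must be >= 2")
  if (n <= c) stop("need more profiles than clusters")
  if (m <= 1) stop("fuzzifier m must be > 1")
  set.seed(seed)
  starts <- if (is.null(init)) {
    lapply(seq_len(n_starts), function(s)
      x[sample.int(n, c), , drop = FALSE] +
        matrix(rnorm(c * ncol(x), sd = 1e-3), c))
  } else list(as.matrix(init))

  run_one <- function(v) {
    u_old <- NULL
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- sq_dist(x, v)
      u <- membership_from_dist(d2, m)
      v <- update_centroids(x, u, m, v)
      obj <- sum(u^m * d2)
      trace <- c(trace, obj)
      if (!is.null(u_old) && max(abs(u - u_old)) < tol) break
      u_old <- u
    }
    d2 <- sq_dist(x, v)
    u <- membership_from_dist(d2, m)
    list(u = u, v = v, objective = sum(u^m * d2), trace = trace,
         iterations = it)
  }
  fits <- lapply(starts, run_one)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  colnames(best$u) <- rownames(best$v) <- paste0("c", seq_len(c))
  rownames(best$u) <- rownames(x)
  structure(list(membership = best$u, centroids = best$v, m = m,
                 hard_label = max.col(best$u, ties.method = "first"),
                 objective = best$objective,
                 objective_trace = best$trace,
                 iterations = best$iterations),
            class = "profile_clustering")
}

sq_dist <- function(x, v) {
  # n x c matrix of squared Euclidean distances
  outer(rowSums(x^2), rep(1, nrow(v))) +
    outer(rep(1, nrow(x)), rowSums(v^2)) - 2 * x %*% t(v)
}

membership_from_dist <- function(d2, m) {
  d2 <- pmax(d2, 0)
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < 1e-12
  hit <- rowSums(zero) > 0
  if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    dd <- d2[!hit, , drop = FALSE]
    # normalize by the row minimum so small fuzzifiers cannot overflow
    r <- dd / apply(dd, 1, min)
    w <- r^(-1 / (m - 1))
    u[!hit, ] <- w / rowSums(w)
  }
  u
}

update_centroids <- function(x, u, m, v_prev) {
  um <- u^m
  w <- colSums(um)
  v <- crossprod(um, x) / w
  dead <- w < 1e-12
  v[dead, ] <- v_prev[dead, , drop = FALSE]
  v
}

#' Merge fuzzy clusters into broader groups
#'
#' Either applies an explicit cluster -> group mapping (reproducing a
#' manual merge) or agglomerates centroids by average linkage on
#' `1 - Pearson correlation` until `target_K` groups remain.
#'
#' @param clustering a `profile_clustering` from [fuzzy_cmeans()].
#' @param target_K number of merged groups.
#' @param mapping optional integer vector of length `c` mapping each
#'   cluster to a group in `1..target_K`.
#' @return list with `merged_label` per feature, `mapping` per cluster and
#'   `centroids` of the merged groups (membership-weighted means).
#' @export
merge_clusters <- function(clustering, target_K = 4, mapping = NULL) {
  stopifnot(inherits(clustering, "profile_clustering"))
  cc <- nrow(clustering$centroids)
  if (target_K > cc) stop("target_K must be <= number of clusters")
  if (!is.null(mapping)) {
    if (length(mapping) != cc || anyNA(mapping))
      stop("mapping must cover all clusters")
    map <- as.integer(mapping)
  } else if (target_K == cc) {
    map <- seq_len(cc)
  } else {
    d <- as.dist(1 - cor(t(clustering$centroids)))
    map <- cutree(hclust(d, method = "average"), k = target_K)
  }
  merged <- unname(map[clustering$hard_label])
  wts <- colSums(clustering$membership)
  cent <- t(sapply(sort(unique(map)), function(k) {
    j <- which(map == k)
    colSums(clustering$centroids[j, , drop = FALSE] * wts[j]) / sum(wts[j])
  }))
  list(merged_label = merged, mapping = map, centroids = cent)
}
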