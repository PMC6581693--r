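#' Tukey halfspace depth of each point within a bivariate sample
#'
#' The depth of a point is the smallest number of sample points (itself
#' included) contained in a closed halfplane whose boundary passes through
#' it. For `n <= exact_max` an exact rotational sweep over the directions
#' defined by the other points is used; larger samples are approximated
#' with seeded random directions.
#'
#' @param points numeric n x 2 matrix.
#' @param exact_max sample-size cap for the exact algorithm.
#' @param n_directions directions for the approximate algorithm.
#' @param seed seed for the approximate directions.
#' @return integer vector of depths.
#' @export
tukey_depth <- function(points, exact_max = 2000, n_directions = 1024,
                        seed = 1) {
  x <- as.matrix(points)
  stopifnot(ncol(x) == 2)
  n <- nrow(x)
  if (n > exact_max) return(tukey_depth_directions(x, n_directions, seed))
  scale <- max(1e-12, max(abs(x)))
  eps <- 1e-9
  vapply(seq_len(n), function(i) {
    rel <- sweep(x, 2, x[i, ])
    r <- sqrt(rowSums(rel^2))
    coincident <- r < 1e-12 * scale
    m <- sum(coincident)
    if (m == n) return(n)
    a <- atan2(rel[!coincident, 2], rel[!coincident, 1]) %% (2 * pi)
    # candidate boundary directions: just off every point direction and its
    # opposite, so every open angular arc between events is visited
    cand <- c(a + eps, a - eps, a + pi + eps, a + pi - eps) %% (2 * pi)
    a2 <- sort(c(a, a + 2 * pi))
    cnt <- findInterval(cand + pi, a2) - findInterval(cand, a2)
    as.integer(m + min(cnt))
  }, 0L)
}

tukey_depth_directions <- function(x, n_directions, seed) {
  n <- nrow(x)
  set.seed(seed)
  th <- runif(n_directions, 0, pi)
  u <- rbind(cos(th), sin(th))
  proj <- x %*% u
  d <- rep(n, n)
  for (k in seq_len(n_directions)) {
    p <- proj[, k]
    le <- rank(p, ties.method = "max")
    ge <- n - rank(p, ties.method = "min") + 1L
    d <- pmin(d, le, ge)
  }
  as.integer(d)
}

point_in_hull <- function(points, hull, tol) {
  # hull: vertex coordinates (closed implicitly); convex, any orientation
  nh <- nrow(hull)
  if (nh == 1)
    return(sqrt(rowSums(sweep(points, 2, hull[1, ])^2)) <= tol)
  inside <- rep(TRUE, nrow(points))
  # orientation sign from the polygon's signed area
  v2 <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
  area2 <- sum(hull[, 1] * v2[, 2] - v2[, 1] * hull[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  for (e in seq_len(nh)) {
    aa <- hull[e, ]
    bb <- hull[if (e == nh) 1 else e + 1, ]
    if (all(aa == bb)) next
    cross <- (bb[1] - aa[1]) * (points[, 2] - aa[2]) -
      (bb[2] - aa[2]) * (points[, 1] - aa[1])
    inside <- inside & (sgn * cross >= -tol)
  }
  inside
}

#' Classify bivariate footprinting points with a bagplot
#'
#' Computes Tukey depths, takes the deepest point as depth median (centroid
#' of the deepest set on ties), forms the bag as the convex hull of the
#' `ceiling(n/2)` deepest points and the fence by inflating the bag by
#' `fence_factor` about the depth median. Points inside the bag are
#' `"bag"`, outside the fence `"outlier"`, otherwise `"fence"`. Collinear
#' samples fall back to per-axis quartile fences (flagged in `fallback`).
#'
#' @param points numeric n x 2 matrix (n >= 10), e.g. (delta FA, delta FPD)
#'   per motif.
#' @param fence_factor bag inflation factor.
#' @param exact_max,n_directions,seed passed to [tukey_depth()].
#' @return list with `classification` (character per point), `depths`,
#'   `depth_median`, `bag` and `fence` polygon coordinates, `fallback`.
#' @export
bagplot_classify <- function(points, fence_factor = 3, exact_max = 2000,
                             n_directions = 1024, seed = 1) {
  x <- as.matrix(points)
  stopifnot(ncol(x) == 2)
  n <- nrow(x)
  if (n < 10) stop("bagplot classification needs >= 10 points")
  scale <- max(1, max(abs(x)))
  tol <- 1e-9 * scale
  if (all(abs(sweep(x, 2, x[1, ])) <= tol)) {
    return(list(classification = rep("bag", n), depths = rep(n, n),
                depth_median = x[1, ], bag = x[1, , drop = FALSE],
                fence = x[1, , drop = FALSE], fallback = FALSE))
  }
  ctr <- sweep(x, 2, colMeans(x))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  collinear <- sv[2] <= 1e-10 * sv[1]
  if (!collinear) {
    depths <- tukey_depth(x, exact_max, n_directions, seed)
    deepest <- which(depths == max(depths))
    dm <- colMeans(x[deepest, , drop = FALSE])
    # ties at the bag boundary resolve toward the depth median
    ord <- order(-depths, rowSums(sweep(x, 2, dm)^2), seq_len(n))
    bag_idx <- ord[seq_len(ceiling(n / 2))]
    bag_pts <- x[bag_idx, , drop = FALSE]
    hull <- bag_pts[chull(bag_pts), , drop = FALSE]
    if (nrow(unique(hull)) >= 3) {
      fence <- sweep(sweep(hull, 2, dm) * fence_factor, 2, dm, "+")
      cls <- rep("fence", n)
      cls[point_in_hull(x, hull, tol)] <- "bag"
      cls[!point_in_hull(x, fence, tol)] <- "outlier"
      return(list(classification = cls, depths = depths, depth_median = dm,
                  bag = hull, fence = fence, fallback = FALSE))
    }
  }
  # collinear (or degenerate bag): 1-D quartile fences per axis
  cls <- rep("fence", n)
  in_bag <- rep(TRUE, n)
  in_fence <- rep(TRUE, n)
  for (j in 1:2) {
    q <- quantile(x[, j], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    in_bag <- in_bag & x[, j] >= q[1] - tol & x[, j] <= q[2] + tol
    in_fence <- in_fence & x[, j] >= q[1] - fence_factor * iqr - tol &
      x[, j] <= q[2] + fence_factor * iqr + tol
  }
  cls[in_bag] <- "bag"
  cls[!in_fence] <- "outlier"
  list(classification = cls, depths = tukey_depth(x, exact_max,
                                                  n_directions, seed),
       depth_median = apply(x, 2, median), bag = NULL, fence = NULL,
       fallback = TRUE)
}
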