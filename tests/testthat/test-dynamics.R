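make_ct <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_table(m)
}

test_that("CPM normalization scales to library size", {
  ct <- count_table(matrix(c(4, 1e6 - 4, 8, 2e6 - 8), 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))))
  nm <- cpm_normalize(ct)
  expect_equal(nm$cpm["a", "s1"], 4)
  expect_equal(unname(colSums(nm$cpm)), c(1e6, 1e6))
  # all-zero feature
  ct2 <- make_ct(rbind(c(0, 0), c(10, 10)))
  nm2 <- cpm_normalize(ct2)
  expect_equal(unname(nm2$cpm[1, ]), c(0, 0))
  expect_equal(unname(nm2$log_cpm[1, ]), c(0, 0))  # log2(pseudocount = 1)
  expect_error(cpm_normalize(make_ct(rbind(c(0, 1)))), "library")
})

test_that("NB exact test matches direct tail summation on small tables", {
  for (case in list(c(3, 9), c(0, 7), c(12, 12), c(1, 30))) {
    for (phi in c(0.01, 0.1, 0.5)) {
      got <- cadence:::nb_exact_test(case[1], case[2], phi)
      expect_equal(got, oracle_nb_exact(case[1], case[2], phi),
                   tolerance = 1e-12)
    }
  }
  expect_equal(cadence:::nb_exact_test(0, 0, 0.1), 1)
})

test_that("differential filter clauses combine as specified", {
  # low-CPM feature fails regardless of fold; identical counts give fold 1
  counts <- rbind(
    lowcpm = c(1, 8, 1),          # huge fold, tiny CPM
    flat = c(1000, 1000, 1000),
    strong = c(2000, 250, 2000),
    balance = c(0, 1743, 0))      # equalizes library sizes
  filler <- matrix(rep(rpois(300, 500), 3), 300)
  rownames(filler) <- paste0("bg", 1:300)
  ct <- make_ct(rbind(counts, filler))
  stopifnot(length(unique(colSums(ct$counts))) == 1)
  res <- differential_features(ct, min_cpm = 4000, min_fold = 2,
                               dispersion = 0.01)
  r <- res[match(c("lowcpm", "flat", "strong"), res$feature_id), ]
  expect_false(r$passes[1])                      # CPM clause
  expect_equal(r$max_pairwise_fold[2], 1, tolerance = 1e-6)
  expect_false(r$passes[2])
  expect_true(r$max_pairwise_fold[3] > 2)
  expect_true(r$q[3] < 0.05)
  # with an attainable CPM threshold the strong feature passes
  res2 <- differential_features(ct, min_cpm = 4, min_fold = 2,
                                dispersion = 0.01)
  expect_true(res2$passes[match("strong", res2$feature_id)])
  expect_error(differential_features(ct, groups = rep("one", 3)),
               "conditions")
})

test_that("null differential calibration stays below the nominal FDR", {
  cfg <- simulation_config(seed = 21, effect_fold = 1, n_peaks = 1000L)
  acc <- simulate_accessibility(cfg)
  res <- differential_features(acc$counts, min_cpm = 0, min_fold = 1)
  frac <- mean(res$q < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("paired DE applies the fold, p and consistency-rescue rules", {
  lib <- 1e6
  base <- 1000
  mk <- function(l2fc) round(base * 2^l2fc)
  filler <- matrix(rpois(200 * 6, 800), 200)
  rownames(filler) <- paste0("bg", 1:200)
  counts <- rbind(
    rescue = c(base, mk(0.8), base, mk(0.1), base, mk(0.3)),
    incons = c(base, mk(1.5), base, mk(-1.5), base, mk(1.5)),
    small = c(base, mk(0.25), base, mk(0.25), base, mk(0.25)),
    filler)
  colnames(counts) <- c("c1", "k1", "c2", "k2", "c3", "k3")
  rownames(counts)[1:3] <- c("rescue", "incons", "small")
  pairs <- data.frame(control = c("c1", "c2", "c3"),
                      knockdown = c("k1", "k2", "k3"))
  de <- differential_expression(count_table(counts), pairs)
  r <- de[match(c("rescue", "incons", "small"), de$feature_id), ]
  expect_true(r$de[1])
  expect_true(r$rescue[1])       # consistent direction, p above alpha
  expect_true(r$p[1] > 0.05)
  expect_false(r$de[2])          # inconsistent directions
  expect_false(r$de[3])          # fold below the > 1.2 threshold
  expect_error(differential_expression(count_table(counts),
                                       data.frame(control = "c9",
                                                  knockdown = "k1")),
               "absent")
})

test_that("z-profiles are centered, unit-scale and safe on constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_profiles(m)
  expect_equal(unname(z["a", ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(2)
  r <- matrix(rnorm(50 * 4), 50)
  zr <- zscore_profiles(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 50), tolerance = 1e-12)
  expect_equal(unname(apply(zr, 1, function(x) sqrt(mean(x^2)))),
               rep(1, 50), tolerance = 1e-12)
  # replicate averaging by groups
  mm <- cbind(a1 = c(1, 0), a2 = c(3, 0), b1 = c(10, 0), b2 = c(10, 0))
  zz <- zscore_profiles(mm, groups = c("a", "a", "b", "b"))
  expect_equal(ncol(zz), 2)
})

test_that("cluster motif enrichment matches the exact binomial tail", {
  set.seed(30)
  # 200 disjoint 200-bp peaks; occurrences planted in 60 of them
  bg <- genomic_intervals("chr1", (0:199) * 1000, (0:199) * 1000 + 200,
                          name = paste0("pk", 1:200))
  cl <- bg[1:40, ]
  hit <- sort(sample(200, 60))
  occ <- genomic_intervals("chr1", (hit - 1) * 1000 + 50,
                           (hit - 1) * 1000 + 60,
                           name = paste0("o", seq_along(hit)))
  occ$motif_id <- "m1"
  res <- cluster_motif_enrichment(list(c1 = cl, c2 = bg[41:200, ]), occ, bg)
  k <- sum(hit <= 40)
  p_exact <- sum(dbinom(k:40, 40, 0.3))
  expect_equal(res$neg_log10_p["m1", "c1"], -log10(p_exact),
               tolerance = 1e-9)
  # foreground at the background rate -> p near 0.5
  expect_true(abs(10^-res$neg_log10_p["m1", "c2"] - 0.5) < 0.35)
  # motif absent from background but present in all foreground: capped
  far <- genomic_intervals("chr2", (0:99) * 1000, (0:99) * 1000 + 200)
  res2 <- cluster_motif_enrichment(list(fg = bg[hit[1:30], ]), occ, far)
  expect_equal(unname(res2$neg_log10_p["m1", "fg"]), 320)
  # empty cluster gives NA column
  res3 <- cluster_motif_enrichment(list(ok = cl, empty = cl[0, ]), occ, bg)
  expect_true(all(is.na(res3$neg_log10_p[, "empty"])))
})
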