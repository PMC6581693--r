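grid_genes <- function(n = 40, spacing = 10000) {
  gene_models(sprintf("g%03d", seq_len(n)), "chr1",
              seq_len(n) * spacing, seq_len(n) * spacing + 2000,
              rep("+", n))
}

test_that("hypergeometric tails reproduce closed forms and edge cases", {
  genes <- grid_genes()
  peaks <- genomic_intervals("chr1", 9 * 10000 - 50, 9 * 10000 + 50)
  # x = 0: P(X >= 0) = 1, -log10 p = 0
  grid <- distance_binned_enrichment(
    list(A = peaks), list(R = c("g030", "g031")), genes, bins_kb = 1)
  expect_equal(grid$x, 0)
  expect_equal(grid$p, 1)
  expect_equal(grid$neg_log10_p, 0)
  # N=20, K=5, n=5, x=5 -> 1/choose(20,5)
  g20 <- grid_genes(20)
  pk <- genomic_intervals("chr1", 1 * 10000 - 10, 1 * 10000 + 10)
  grid2 <- distance_binned_enrichment(
    list(A = pk), list(R = sprintf("g%03d", 1:5)), g20, bins_kb = 45)
  expect_equal(grid2$K, 5)                   # genes 1..5 within 45 kb
  expect_equal(grid2$x, 5)
  expect_equal(grid2$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(distance_binned_enrichment(
    list(A = pk), list(R = "nope"), g20), "outside the universe")
})

test_that("hypergeometric p equals term-wise enumeration for all N <= 60", {
  max_err <- 0
  for (N in c(5, 10, 20, 35, 47, 60)) {
    for (K in unique(round(seq(0, N, length.out = 8)))) {
      for (n in unique(round(seq(1, N, length.out = 8)))) {
        for (x in 0:min(K, n)) {
          p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
          o <- oracle_hyper_tail(x, K, N, n)
          max_err <- max(max_err, abs(p - o))
        }
      }
    }
  }
  expect_lt(max_err, 1e-10)
})

test_that("the enrichment grid is monotone under nesting and super-uniform", {
  genes <- grid_genes(60)
  set.seed(71)
  peaks <- genomic_intervals("chr1", s <- sample.int(6e5, 10), s + 100)
  kgrid <- distance_binned_enrichment(list(A = peaks),
                                      list(R = genes$gene_id[1:10]),
                                      genes, bins_kb = 20)
  near <- genes$gene_id[vapply(genes$tss, function(t)
    any(abs(t - (peaks$start + peaks$end) %/% 2) <= 20000), TRUE)]
  # enlarging R only with K-set members cannot decrease x
  if (length(setdiff(near, genes$gene_id[1:10]))) {
    r2 <- union(genes$gene_id[1:10], near[1:min(5, length(near))])
    g2 <- distance_binned_enrichment(list(A = peaks), list(R = r2),
                                     genes, bins_kb = 20)
    expect_gte(g2$x, kgrid$x)
  }
  # null calibration: random gene sets give super-uniform p
  set.seed(72)
  ps <- replicate(2000, {
    r <- sample(genes$gene_id, 8)
    distance_binned_enrichment(list(A = peaks), list(R = r), genes,
                               bins_kb = 20)$p
  })
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 2000))
  }
  # the randomized expected-set route agrees with the exact tail
  gr <- distance_binned_enrichment(list(A = peaks),
                                   list(R = genes$gene_id[seq(2, 20, 2)]),
                                   genes, bins_kb = 20, randomized = TRUE,
                                   n_draws = 4000)
  expect_equal(gr$p_randomized, gr$p, tolerance = 0.05)
})

test_that("direct-target calling splits activated and repressed classes", {
  # the worked arithmetic: 207 targets of which 135 down-in-knockdown
  de <- data.frame(
    feature_id = sprintf("g%04d", 1:300),
    de = c(rep(TRUE, 207), rep(FALSE, 93)),
    direction = c(rep("down_in_kd", 135), rep("up_in_kd", 72),
                  rep("down_in_kd", 93)),
    stringsAsFactors = FALSE)
  res <- call_direct_targets(sprintf("g%04d", 1:250), de)
  expect_equal(res$summary$n_total, 207)
  expect_equal(res$summary$n_activated, 135)
  expect_equal(res$summary$percent_activated, 65)
  expect_true(all(res$targets$class[res$targets$de_direction ==
                                      "down_in_kd"] == "activated"))
  # bound but not DE genes are excluded; empty intersection gives zeros
  expect_false("g0208" %in% res$targets$gene_id)
  none <- call_direct_targets("absent", de)
  expect_equal(none$summary$n_total, 0)
  expect_equal(none$summary$percent_activated, 0)
})

test_that("planted direct targets are recovered exactly from the generator", {
  cfg <- simulation_config(seed = 17)
  sc <- simulate_single_cells(cfg)
  kd <- simulate_knockdown(cfg, regulon_truth = sc)
  de <- differential_expression(kd$counts, kd$pairs)
  bound <- unique(assign_nearest_gene(kd$tf_peaks, kd$genes)$gene_id)
  res <- call_direct_targets(bound, de)
  truth <- kd$truth$gene_id[kd$truth$planted_class != "null"]
  expect_setequal(res$targets$gene_id, truth)
  dir_truth <- kd$truth$direction[match(res$targets$gene_id,
                                        kd$truth$gene_id)]
  expect_identical(res$targets$de_direction, dir_truth)
})

test_that("stage-marker overlaps report proportions and composition", {
  reg <- paste0("g", 1:15)
  stages <- list(icm = paste0("g", 1:10),
                 pre = paste0("g", c(11:15, 100:134)),
                 post = paste0("g", 200:210),
                 empty = character(0))
  res <- stage_marker_overlap(reg, stages)
  expect_equal(res$per_stage$proportion,
               c(1, 5 / 40, 0, NA))
  expect_equal(unname(res$composition[c("icm", "pre", "post")]),
               c(10, 5, 0) / 15)
})
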