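toy_counts <- function(n_cells = 100, n_genes = 60, seed = 1, mu = 5) {
  set.seed(seed)
  matrix(rpois(n_cells * n_genes, mu), n_cells,
         dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                         sprintf("g%03d", seq_len(n_genes))))
}

test_that("MAD-based QC applies the three filters with strict inequalities", {
  same <- matrix(3, 20, 10, dimnames = list(paste0("c", 1:20),
                                            paste0("g", 1:10)))
  expect_true(all(qc_cells(same)))          # MAD 0, strict comparisons
  x <- toy_counts()
  x[1, ] <- x[1, ] * 10                      # 10x library cell
  pass <- qc_cells(x)
  expect_false(pass[1])
  m <- attr(pass, "qc_metrics")
  expect_true(m$high_library[1])
  expect_error(qc_cells(x[1:5, ]), ">= 10 cells")
})

test_that("QC fails exactly the planted outliers on generator defaults", {
  sc <- simulate_single_cells(simulation_config(seed = 17))
  pass <- qc_cells(sc$counts)
  expect_identical(as.logical(!pass), sc$cell_truth$outlier != "none")
})

test_that("gene filtering thresholds the mean raw count", {
  x <- toy_counts(n_cells = 100, mu = 0)
  x[, "g001"] <- c(rep(1, 5), rep(0, 95))    # mean exactly 0.05 -> kept
  x[, "g002"] <- c(rep(1, 4), rep(0, 96))    # mean 0.04 -> dropped
  x[, "g003"] <- 1
  keep <- filter_genes(x)
  expect_true("g001" %in% keep)
  expect_false("g002" %in% keep)
  expect_true(all(colnames(x) %in% filter_genes(x, min_mean = 0)))
})

test_that("size factors center to unity and CPM matches library scaling", {
  x <- toy_counts(30, 40, seed = 3)
  norm <- sc_normalize(x)
  expect_equal(mean(norm$size_factor), 1)
  expect_equal(norm$cpm, x / rowSums(x) * 1e6)
  expect_identical(norm$binary, x > 0)
})

test_that("HVG selection is calibrated on null data and finds real excess", {
  set.seed(61)
  mu <- exp(rnorm(2000, 1, 1))
  counts <- t(vapply(seq_len(300), function(i)
    rnbinom(2000, mu = mu, size = 5), numeric(2000)))
  dimnames(counts) <- list(sprintf("c%03d", 1:300),
                           sprintf("g%04d", 1:2000))
  cpm <- counts / rowSums(counts) * 1e6
  hv <- hvg_select(cpm)
  frac <- mean(hv$hvg)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  # a gene with strongly inflated variance is selected
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * rep(c(0, 2), length.out = 300)
  cpm2 <- counts2 / rowSums(counts2) * 1e6
  hv2 <- hvg_select(cpm2)
  expect_true(hv2$hvg[1])
  expect_error(hvg_select(cpm[, 1:20]), ">= 50")
})

test_that("co-expression z-scores use the pooled population SD", {
  b <- rbind(c(FALSE, FALSE, FALSE, FALSE),
             c(TRUE, TRUE, TRUE, TRUE))
  dimnames(b) <- list(c("c1", "c2"), paste0("g", 1:4))
  z <- coexpression_score(b, paste0("g", 1:4))
  expect_equal(unname(as.numeric(z)), c(-1, 1))
  expect_equal(unname(attr(z, "score")), c(0, 4))
  # two-cell toy with population SD: z = +-0.7071 after rescaling s=(0,4)/...
  z2 <- coexpression_score(b, c("g1", "g2"))
  expect_equal(unname(as.numeric(z2)), c(-1, 1))
  # empty set: all zero with warning-free constant handling
  expect_warning(z0 <- coexpression_score(b, character(0)), "constant")
  expect_true(all(z0 == 0))
  # pooled mean 0, sd 1 (population) on random data
  set.seed(62)
  bb <- matrix(runif(500) > 0.5, 50, dimnames = list(NULL, paste0("g", 1:10)))
  zz <- coexpression_score(bb, paste0("g", 1:6))
  expect_equal(mean(zz), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((zz - mean(zz))^2)), 1, tolerance = 1e-9)
  # per-condition summary is reported when conditions are given
  zc <- coexpression_score(bb, paste0("g", 1:6),
                           condition = rep(c("a", "b"), each = 25))
  expect_equal(nrow(attr(zc, "condition_summary")), 2)
})

test_that("JSI follows 1 - JD^2 with its identity and disjoint cases", {
  b <- cbind(g1 = c(TRUE, TRUE, FALSE, FALSE),
             g2 = c(TRUE, TRUE, FALSE, FALSE),
             g3 = c(FALSE, FALSE, TRUE, TRUE),
             g4 = c(TRUE, FALSE, TRUE, FALSE))
  j <- jsi_matrix(b, colnames(b))
  expect_equal(j["g1", "g2"], 1)             # identical -> JD 0
  expect_equal(j["g1", "g3"], 0)             # disjoint -> JD 1
  # overlap 1 of union 3: JD = 2/3, JSI = 1 - 4/9
  expect_equal(j["g1", "g4"], 1 - (2 / 3)^2)
  expect_true(isSymmetric(unclass(j)[, ]))
  # overlap 1 of union 2 gives 0.75
  b2 <- cbind(gA = c(TRUE, TRUE, FALSE), gB = c(TRUE, FALSE, FALSE))
  j2 <- jsi_matrix(b2, colnames(b2))
  expect_equal(j2["gA", "gB"], 0.75)
  # reference ordering is a pure permutation
  ord <- attr(j, "order")
  j_ref <- jsi_matrix(b, colnames(b), reference_order = rev(ord))
  expect_equal(unclass(j_ref)[rev(ord), rev(ord)][ord, ord],
               unclass(j)[ord, ord])
})

test_that("MCC equals the Pearson correlation of binary vectors", {
  b <- cbind(g1 = c(TRUE, TRUE, FALSE, FALSE),
             g2 = c(TRUE, TRUE, FALSE, FALSE),
             g3 = c(FALSE, FALSE, TRUE, TRUE))
  m <- mcc_matrix(b, colnames(b))
  expect_equal(m["g1", "g2"], 1)
  expect_equal(m["g1", "g3"], -1)            # complementary
  set.seed(63)
  bb <- matrix(runif(30 * 6) > 0.4, 30, dimnames = list(NULL,
                                                        paste0("g", 1:6)))
  mm <- mcc_matrix(bb, colnames(bb))
  ref <- cor(bb * 1)
  expect_equal(unclass(mm)[colnames(bb), colnames(bb)],
               ref[colnames(bb), colnames(bb)], tolerance = 1e-12)
  # zero margins are flagged and set to 0
  bz <- cbind(gAll = rep(TRUE, 10), gX = runif(10) > 0.5)
  mz <- mcc_matrix(bz, colnames(bz))
  expect_equal(unname(mz["gAll", "gX"]), 0)
  expect_true("gAll" %in% attr(mz, "zero_margin"))
})

test_that("regulon AUC hits its extremes and ignores monotone transforms", {
  G <- 20
  cpm <- matrix(0, 2, G, dimnames = list(c("top", "none"),
                                         sprintf("g%02d", 1:G)))
  regulon <- c("g01", "g02", "g03")
  cpm["top", 1:3] <- c(30, 20, 10)           # regulon occupies top ranks
  cpm["top", 4:G] <- 1
  cpm["none", ] <- seq(G, 1)                 # regulon at the bottom
  cpm["none", 1:3] <- 0
  res <- regulon_auc(cpm, regulon, top_fraction = 0.2, seed = 1)
  expect_equal(res$auc[1], 1)
  expect_equal(res$auc[2], 0)
  # hand enumeration: regulon ranks 2, 4 within top 4 of 20
  cpm2 <- matrix(seq(G, 1), 1, G,
                 dimnames = list("c", sprintf("g%02d", 1:G)))
  res2 <- regulon_auc(cpm2, c("g02", "g04"), top_fraction = 0.2, seed = 1)
  # recovery curve over k=1..4: hits (0,1,1,2); max curve (1,2,2,2)
  expect_equal(res2$auc, sum(c(0, 1, 1, 2)) / sum(c(1, 2, 2, 2)))
  # monotone transform of within-cell expression leaves the AUC unchanged
  set.seed(64)
  big <- matrix(rexp(50 * 200), 50, dimnames = list(NULL,
                                                    paste0("g", 1:200)))
  reg <- paste0("g", sample(200, 12))
  a1 <- regulon_auc(big, reg, seed = 2)$auc
  a2 <- regulon_auc(log1p(big)^3, reg, seed = 2)$auc
  expect_equal(a1, a2)
  expect_error(regulon_auc(big, "absent"), "universe")
})

test_that("pseudotime orders a gradient and is permutation invariant", {
  sc <- simulate_single_cells(simulation_config(seed = 17))
  pass <- qc_cells(sc$counts)
  genes <- filter_genes(sc$counts, pass)
  norm <- sc_normalize(sc$counts[pass, genes])
  hv <- hvg_select(norm$cpm)
  ordset <- setdiff(attr(hv, "hvgs"),
                    c(sc$regulon, sc$regulon_repressed, sc$driver_gene))
  ct <- sc$cell_truth[pass, ]
  cond <- factor(ct$condition, levels = c("esc", "d1", "d2"))
  pt <- pseudotime_rank(norm$cpm, ordset, condition = cond)
  expect_gte(cor(pt, ct$t, method = "spearman"), 0.9)
  expect_true(all(pt >= 0 & pt <= 1))
  # reversing the cell order yields the same values per cell
  rev_idx <- rev(seq_len(nrow(norm$cpm)))
  pt_rev <- pseudotime_rank(norm$cpm[rev_idx, ], ordset,
                            condition = cond[rev_idx])
  expect_equal(pt_rev[names(pt)], pt, tolerance = 1e-8)
  # orientation: the later condition has the higher mean pseudotime
  expect_gt(mean(pt[ct$condition == "d2"]), mean(pt[ct$condition == "esc"]))

  # regulon trajectory: driver-positive cells trend, driver-negative do not
  reg <- intersect(sc$regulon, genes)
  tr <- regulon_trajectory(norm$binary, reg, pt, sc$driver_gene)
  pos <- tr$driver_positive
  expect_gte(cor(tr$pseudotime[pos], tr$fraction[pos],
                 method = "spearman"), 0.5)
  expect_lt(abs(cor(tr$pseudotime[!pos], tr$fraction[!pos],
                    method = "spearman")), 0.2)
  # full detection gives fraction one; an empty stratum is not an error
  bfull <- matrix(TRUE, 2, length(reg), dimnames = list(c("a", "b"), reg))
  trf <- regulon_trajectory(bfull, reg, c(0.1, 0.9), c(TRUE, TRUE))
  expect_equal(trf$fraction, c(1, 1))
  expect_equal(sum(!trf$driver_positive), 0)
})

test_that("pseudobulk sums QC-passing cells per condition", {
  x <- toy_counts(6, 5, seed = 4)
  cond <- rep(c("a", "b"), each = 3)
  pb <- pseudobulk(x, cond)
  expect_equal(unname(pb$counts[, "a"]), unname(colSums(x[1:3, ])))
  expect_equal(sum(pb$counts), sum(x))
  qc <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_error(pseudobulk(x, cond, qc), "no QC-passing")
})
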