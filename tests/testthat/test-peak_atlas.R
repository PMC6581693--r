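test_that("reciprocal overlap uses >= min_frac of both peak lengths", {
  r1 <- genomic_intervals("chr1", 0, 100)
  # overlap 50 = exactly 50% of both -> retained at the boundary
  r2 <- genomic_intervals("chr1", 50, 150)
  expect_equal(nrow(concordant_peaks(r1, r2)), 1)
  # overlap 10 = 10% of rep1 -> dropped
  r3 <- genomic_intervals("chr1", 90, 300)
  expect_equal(nrow(concordant_peaks(r1, r3)), 0)
  expect_error(concordant_peaks(r1, r2, min_frac = 0), "min_frac")
  expect_error(concordant_peaks(r1, r2, min_frac = 1.5), "min_frac")
})

test_that("concordant_peaks equals the all-pairs oracle and is reflexive", {
  set.seed(42)
  a <- random_intervals(200)
  b <- random_intervals(200)
  for (frac in c(0.3, 0.5, 0.9)) {
    expect_identical(concordant_peaks(a, b, frac),
                     oracle_concordant(a, b, frac))
  }
  expect_identical(concordant_peaks(a, a), a)
})

test_that("merge_union applies the strict < max_gap summit rule", {
  p1 <- genomic_intervals("chr1", 900, 1100, summit_offset = 100)  # summit 1000
  p2 <- genomic_intervals("chr1", 999, 1199, summit_offset = 100)  # summit 1099
  m <- merge_union(list(a = p1, b = p2), max_gap = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 900L)
  expect_equal(m$end, 1199L)
  expect_equal(m$sources, "a,b")

  p3 <- genomic_intervals("chr1", 1000, 1200, summit_offset = 100) # summit 1100
  m2 <- merge_union(list(a = p1, b = p3), max_gap = 100)
  expect_equal(nrow(m2), 2)
})

test_that("merge_union equals the union-find oracle and is idempotent", {
  set.seed(7)
  sets <- lapply(1:3, function(i) random_intervals(500, max_pos = 2e5))
  m <- merge_union(sets, max_gap = 100)
  all <- do.call(rbind, lapply(sets, function(x)
    data.frame(chrom = x$chrom, anchor = x$start + x$summit_offset)))
  grp <- oracle_merge_groups(all$chrom, all$anchor, 100)
  expect_equal(nrow(m), length(unique(grp)))
  m2 <- merge_union(list(m), max_gap = 100)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
})

test_that("partition_atlas applies the promoter window with precedence", {
  genes <- gene_models(c("gA", "gB"), "chr1", c(50000, 90000),
                       c(70000, 110000), c("+", "-"))
  peaks <- genomic_intervals(
    c("chr1", "chr1", "chr1", "chr2"),
    c(48950, 59950, 30000, 100),
    c(49050, 60050, 30100, 200))
  # centers: 49000 (TSS-1000 of gA), 60000 (mid body), 30050 (far), chr2
  lab <- partition_atlas(peaks, genes)
  expect_equal(lab, c("promoter", "intragenic", "intergenic", "intergenic"))
  # promoter window is oriented: TSS+600 downstream of gA is not promoter
  p <- genomic_intervals("chr1", 50550, 50650)
  expect_equal(partition_atlas(p, genes), "intragenic")
  # minus-strand gene gB: TSS at 109999, center at TSS-1000 genomic +1000
  pm <- genomic_intervals("chr1", 110950, 111050)
  expect_equal(partition_atlas(pm, genes), "promoter")
  # partition labels are exhaustive over a random atlas
  set.seed(1)
  rnd <- random_intervals(300)
  lab <- partition_atlas(rnd, genes)
  expect_true(all(lab %in% c("promoter", "intragenic", "intergenic")))
})

test_that("nearest-gene assignment signs distances and breaks ties", {
  g <- gene_models("gA", "chr1", 100000, 110000, "+")
  pk <- genomic_intervals("chr1", 94950, 95050)  # center 95000, 5 kb upstream
  res <- assign_nearest_gene(pk, g)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$distance, -5000L)
  # equidistant genes -> lexicographically smaller id
  g2 <- gene_models(c("gB", "gA"), "chr1", c(90000, 100000),
                    c(95000, 110000), c("+", "+"))
  pk2 <- genomic_intervals("chr1", 94950, 95050)
  expect_equal(assign_nearest_gene(pk2, g2)$gene_id, "gA")
  # 300 random peaks match the exhaustive oracle
  set.seed(9)
  genes <- gene_models(sprintf("g%03d", 1:40),
                       sample(c("chr1", "chr2"), 40, replace = TRUE),
                       s <- sample.int(9e5, 40), s + 10000,
                       sample(c("+", "-"), 40, replace = TRUE))
  peaks <- random_intervals(300)
  expect_identical(assign_nearest_gene(peaks, genes),
                   oracle_nearest(peaks, genes))
})

test_that("intersect_with_atlas keeps peaks with summits within max_gap", {
  atlas <- genomic_intervals("chr1", 10000, 10200, summit_offset = 100)
  q249 <- genomic_intervals("chr1", 10249, 10449, summit_offset = 100)
  q251 <- genomic_intervals("chr1", 10251, 10451, summit_offset = 100)
  expect_equal(nrow(intersect_with_atlas(q249, atlas)), 1)
  expect_equal(nrow(intersect_with_atlas(q251, atlas)), 0)
  # random sets match the brute-force oracle
  set.seed(12)
  qs <- random_intervals(300)
  at <- random_intervals(200)
  got <- intersect_with_atlas(qs, at, max_gap = 500)
  qa <- qs$start + qs$summit_offset
  aa <- at$start + at$summit_offset
  keep <- vapply(seq_len(nrow(qs)), function(i)
    any(qs$chrom[i] == at$chrom & abs(qa[i] - aa) <= 500), TRUE)
  expect_identical(got, qs[keep, , drop = FALSE])
})

test_that("build_atlas assembles concordance, union, partition and genes", {
  set.seed(3)
  genes <- gene_models(c("gA", "gB"), c("chr1", "chr2"), c(1e5, 2e5),
                       c(1e5 + 1e4, 2e5 + 1e4), c("+", "-"))
  reps <- list(
    esc = list(random_intervals(80, max_pos = 5e5),
               random_intervals(80, max_pos = 5e5)),
    d1 = random_intervals(60, max_pos = 5e5))
  at <- build_atlas(reps, genes)
  expect_s3_class(at, "peak_atlas")
  expect_true(all(c("partition", "nearest_gene", "distance") %in%
                    names(at$peaks)))
  expect_true(all(table(at$peaks$partition) >= 0))
})
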