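test_that("normalization factor is target over deduplicated total", {
  tags <- tibble::tibble(chrom = "chr1", pos = 1:7)
  expect_equal(normalization_factor(tags, target = 21), 3)
  expect_equal(normalization_factor(tags, target = 7), 1)
  big <- tibble::tibble(chrom = "chr1", pos = seq_len(1e4))
  expect_equal(normalization_factor(big, target = 2e4), 2)
  empty <- tibble::tibble(chrom = character(), pos = numeric())
  expect_error(normalization_factor(empty), "empty")
})

test_that("window occupancy counts distinct positions, half-open, scaled", {
  win <- genomic_intervals("chr1", 100, 200)
  expect_equal(window_occupancy(win, tibble::tibble(chrom = "chr1",
                                                    pos = 500),
                                scale = 1)$occupancy, 0)
  tags <- tibble::tibble(chrom = "chr1", pos = 100:109)
  expect_equal(window_occupancy(win, tags, scale = 2)$occupancy, 20)
  # clonal collapse: 10 tags, 3 at one bp -> 8 distinct
  tags2 <- tibble::tibble(chrom = "chr1", pos = c(100:106, 150, 150, 150))
  expect_equal(window_occupancy(win, tags2, scale = 1)$occupancy, 8)
  # a tag at the end coordinate is excluded (half-open)
  expect_equal(window_occupancy(win, tibble::tibble(chrom = "chr1",
                                                    pos = c(199, 200)),
                                scale = 1)$occupancy, 1)
  # per-bp mode divides by window length
  expect_equal(window_occupancy(win, tags, scale = 1,
                                per_bp = TRUE)$occupancy, 0.1)
  # absent chromosome counts zero
  win2 <- genomic_intervals("chrX", 0, 100)
  expect_equal(window_occupancy(win2, tags, scale = 1)$occupancy, 0)
})

test_that("occupancy ratios between windows are scale invariant", {
  tags <- tibble::tibble(chrom = "chr1",
                         pos = c(100:119, 300:304))
  wins <- genomic_intervals("chr1", c(100, 300), c(200, 400))
  o1 <- window_occupancy(wins, tags, scale = 1)$occupancy
  o2 <- window_occupancy(wins, tags, scale = 57.3)$occupancy
  expect_equal(o1[1] / o1[2], o2[1] / o2[2])
})

test_that("anchor matrices bin correctly and respect strand flips", {
  anchor <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           tss = 100000)
  none <- anchor_matrix(anchor, tibble::tibble(chrom = "chr2", pos = 1),
                        scale = 1)
  expect_equal(dim(none), c(1L, 200L))
  expect_true(all(none == 0))
  # a tag exactly at the TSS lands in bin index 100 (0-based)
  tss_tag <- tibble::tibble(chrom = "chr1", pos = 100000)
  m <- anchor_matrix(anchor, tss_tag, scale = 1)
  expect_equal(which(m[1, ] > 0) - 1L, 100L)
  # minus-strand anchor reverses the row
  tags <- tibble::tibble(chrom = "chr1", pos = c(95001, 99990, 100700))
  plus <- anchor_matrix(anchor, tags, scale = 1)
  minus <- anchor_matrix(dplyr::mutate(anchor, strand = "-"), tags,
                         scale = 1)
  expect_equal(minus[1, ], rev(plus[1, ]))
  expect_error(anchor_matrix(anchor, tags, flank = 5000, bin_size = 33),
               "divisible")
})

test_that("anchor row sums equal raw deduplicated counts in the flank window", {
  sim <- default_sim()
  genes <- sim$truth$genes[1:25, c("gene_id", "chrom", "strand", "tss")]
  tags <- sim_tags(sim, "H3K4me3", "control")
  scale <- 3.7
  m <- anchor_matrix(genes, tags, scale = scale)
  wins <- genomic_intervals(genes$chrom, pmax(0, genes$tss - 5000),
                            genes$tss + 5000)
  raw <- window_occupancy(wins, tags, scale = 1)$occupancy
  expect_equal(unname(rowSums(m)) / scale, raw)
})

test_that("delta matrices subtract elementwise and demand matching grids", {
  anchors <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                            strand = "+", tss = c(50000, 80000))
  tags <- tibble::tibble(chrom = "chr1",
                         pos = c(49000, 50100, 79000, 80010, 80020))
  m1 <- anchor_matrix(anchors, tags, scale = 1)
  zero <- delta_matrix(m1, m1)
  expect_true(all(zero == 0))
  empty <- anchor_matrix(anchors, tibble::tibble(chrom = "chrZ", pos = 1),
                         scale = 1)
  expect_equal(unclass(delta_matrix(m1, empty)), unclass(m1))
  # random matrices against an elementwise loop
  m2 <- anchor_matrix(anchors, tibble::tibble(chrom = "chr1",
                                              pos = 49500:49600), scale = 1)
  d <- delta_matrix(m1, m2)
  for (i in seq_len(nrow(d))) {
    expect_equal(d[i, ], m1[i, ] - m2[i, ])
  }
  m3 <- anchor_matrix(anchors[1, ], tags, scale = 1)
  expect_error(delta_matrix(m1, m3), "rows or bin grid")
})

test_that("average profiles are column means", {
  anchors <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                            strand = "+", tss = c(50000, 80000))
  tags <- tibble::tibble(chrom = "chr1", pos = c(50010, 80010))
  m <- anchor_matrix(anchors, tags, scale = 2)
  prof <- average_profile(m)
  expect_equal(nrow(prof), ncol(m))
  expect_equal(prof$occupancy, unname(colMeans(unclass(m))))
  expect_equal(average_profile(m[1, , drop = FALSE])$occupancy,
               unname(m[1, ]))
  expect_error(average_profile(m[0, , drop = FALSE]), "empty")
})

test_that("tidy() flattens occupancy matrices to long form", {
  anchors <- tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                            tss = 50000)
  m <- anchor_matrix(anchors, tibble::tibble(chrom = "chr1", pos = 50000),
                     scale = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 200L)
  expect_equal(sum(td$occupancy), 1)
  expect_equal(range(td$offset), c(-4975, 4975))
})
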