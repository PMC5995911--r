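test_that("promoter classes follow the two-mark rule", {
  prom <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                         chrom = "chr1",
                         start = c(1000, 5000, 9000, 13000),
                         end = c(3000, 7000, 11000, 15000))
  k4 <- genomic_intervals("chr1", c(0, 4000), c(3500, 7500))
  k27 <- genomic_intervals("chr1", c(500, 8500), c(3200, 11500))
  st <- classify_promoters(prom, k4, k27)
  expect_equal(st$class, c("bivalent", "active", "neither", "neither"))
  expect_error(classify_promoters(prom[c(1, 1), ], k4, k27), "duplicate")
})

test_that("promoter classes agree with the per-base intersection oracle", {
  withr::with_seed(51, {
    for (rep in 1:10) {
      prom <- random_intervals(50, len = 5000) |>
        dplyr::mutate(gene_id = sprintf("g%02d", dplyr::row_number()))
      k4 <- random_intervals(20, len = 5000)
      k27 <- random_intervals(20, len = 5000)
      st <- classify_promoters(prom, k4, k27)
      for (i in seq_len(nrow(prom))) {
        cov <- bf_coverage(prom[i, ], "chrT", 5000)
        has4 <- any(cov & bf_coverage(k4, "chrT", 5000))
        has27 <- any(cov & bf_coverage(k27, "chrT", 5000))
        expect_equal(st$has_k4me3[i], has4)
        expect_equal(st$has_k27me3[i], has27)
      }
    }
  })
})

test_that("min_frac classification requires the stated promoter coverage", {
  prom <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 0, end = 2000)
  k4 <- genomic_intervals("chr1", 0, 900)   # 45% covered
  none <- genomic_intervals("chr2", 0, 10)
  expect_equal(classify_promoters(prom, k4, none, min_frac = 0.5)$class,
               "neither")
  expect_equal(classify_promoters(prom, k4, none, min_frac = 0.4)$class,
               "active")
})

test_that("bivalent split applies inclusive thresholds and partitions", {
  st <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                       class = c(rep("bivalent", 4), "active"))
  de <- tibble::tibble(gene_id = sprintf("g%d", 1:5),
                       log2FC = c(1.5, 1.0, 0.99, -1.2, 3),
                       FDR = c(0.01, 0.05, 0.001, 0.04, 0.01),
                       baseline = 1)
  sp <- split_bivalent(st, de)
  expect_equal(nrow(sp), 4L) # the active gene is excluded
  expect_equal(sp$group, c("up", "up", "no_change", "down"))
  expect_equal(sp$category,
               c("up_bivalent", "up_bivalent", "other_bivalent",
                 "other_bivalent"))
  # genes absent from the DE table become no_change
  st2 <- tibble::tibble(gene_id = c("g1", "gX"), class = "bivalent")
  expect_message(sp2 <- split_bivalent(st2, de), "missing")
  expect_equal(sp2$group[sp2$gene_id == "gX"], "no_change")
  # partition invariant
  expect_equal(sum(table(sp$group)), nrow(sp))
})

test_that("signatures are built by inclusive log2FC threshold", {
  de <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       log2FC = c(6, 5, 4.9), FDR = 0, baseline = 1)
  sig <- build_signature(de, lfc_min = 5)
  expect_equal(sort(sig$genes), c("g1", "g2"))
  expect_error(build_signature(dplyr::mutate(de, log2FC = 0)), "empty|reach")
})

test_that("a low-dispersion simulation recovers planted signature genes", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                          archetype = "active",
                          true_log2FC = c(rep(6, 20), rep(0, 180)),
                          baseline_mean = 300)
  cfg <- simulation_config(seed = 17L, dispersion = 0.005)
  de <- simulate_expression(genes, cfg)
  sig <- build_signature(de, lfc_min = 5)
  expect_gte(sum(sprintf("g%03d", 1:20) %in% sig$genes), 18)
})

test_that("enrichment scores match exhaustive running-sum enumeration", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      metric <- sort(round(rnorm(10), 2), decreasing = TRUE)
      names(metric) <- sprintf("g%02d", 1:10)
      hit_genes <- sample(names(metric), 3)
      for (w in c(0, 1)) {
        res <- enrichment_score(
          tibble::tibble(gene_id = names(metric), metric = metric),
          hit_genes, weight = w, n_perm = 100, seed = 1)
        expect_equal(res$es,
                     bf_es(metric, names(metric) %in% hit_genes, weight = w),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("enrichment extremes behave as documented", {
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                           metric = seq(2, -2, length.out = 20))
  top <- enrichment_score(ranked, sprintf("g%02d", 1:4), n_perm = 200,
                          seed = 3)
  expect_gt(top$es, 0.8)
  expect_lte(top$pvalue, 1 / (sum(top$null_es >= 0) + 1) + 1e-12)
  # the whole list as signature: degenerate ES = 1
  all_in <- enrichment_score(ranked, ranked$gene_id, n_perm = 100, seed = 3)
  expect_equal(all_in$es, 1)
  expect_error(enrichment_score(ranked, c("zz1", "zz2"), n_perm = 100),
               "common")
  expect_error(enrichment_score(ranked, "g01", n_perm = 10), "n_perm")
})

test_that("enrichment agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(71, {
    metric <- sort(rnorm(60), decreasing = TRUE)
    names(metric) <- sprintf("g%02d", 1:60)
    sel <- sample(names(metric), 10)
  })
  mine <- enrichment_score(tibble::tibble(gene_id = names(metric),
                                          metric = metric),
                           sel, weight = 1, n_perm = 100, seed = 1)
  ref <- fgsea::calcGseaStat(metric, which(names(metric) %in% sel),
                             gseaParam = 1)
  expect_equal(mine$es, unname(ref), tolerance = 1e-8)
})

test_that("planted enrichment gives positive NES at the permutation floor", {
  withr::with_seed(81, {
    metric <- c(runif(15, 1, 2), runif(85, -1, 1))
  })
  ranked <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                           metric = sort(metric, decreasing = TRUE))
  res <- enrichment_score(ranked, sprintf("g%03d", 1:15), n_perm = 500,
                          seed = 5)
  expect_gt(res$nes, 1)
  expect_lte(res$pvalue, 1 / (sum(res$null_es >= 0) + 1))
})
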