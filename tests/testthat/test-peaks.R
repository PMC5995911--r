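random_peaks <- function(n, len = 20000, wmin = 300, wmax = 1500) {
  start <- sample.int(len - wmax - 1L, n, replace = TRUE) - 1L
  tibble::tibble(chrom = "chrT", start = start,
                 end = start + sample(wmin:wmax, n, replace = TRUE))
}

# consensus regions as runs of a per-base coverage vector
bf_consensus <- function(peaks, len = 20000) {
  cov <- bf_coverage(peaks, "chrT", len)
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = "chrT", start = starts[r$values],
                 end = ends[r$values])
}

bf_flag <- function(peaks, region, min_overlap) {
  any(pmax(0, pmin(peaks$end, region$end) -
             pmax(peaks$start, region$start)) > min_overlap)
}

test_that("Poisson tail decisions match pmf summation", {
  # spec-style example: 25 tags in one 300 bp window at lambda = 1
  expect_lt(bf_poisson_tail(25, 1), 1e-8)
  genome <- tibble::tibble(chrom = "chrT", size = 3000)
  lam_for <- function(total) total * 300 / 3000
  for (k in c(3, 5, 8, 12, 20, 25)) {
    total <- 40 # lambda = 4
    tags <- tibble::tibble(
      chrom = "chrT",
      pos = c(seq(0, 2999, length.out = total - k), 1000 + seq_len(k)))
    pk <- call_peaks_poisson(tags, genome, window = 300, step = 100)
    called <- nrow(pk) > 0 && any(pk$start <= 1000 & pk$end >= 1100)
    # oracle on the densest window's count
    dedup <- unique(round(tags$pos))
    counts <- vapply(seq(0, 2700, 100), function(s)
      sum(dedup >= s & dedup < s + 300), numeric(1))
    oracle <- any(vapply(counts, function(kk)
      bf_poisson_tail(kk, lam_for(length(dedup))) <= 1e-8, logical(1)))
    expect_equal(called, oracle)
  }
})

test_that("pure background at p <= 1e-8 yields essentially no peaks", {
  withr::with_seed(21, {
    tags <- tibble::tibble(chrom = "chrB",
                           pos = floor(runif(2000, 0, 1e6)))
  })
  pk <- call_peaks_poisson(tags, tibble::tibble(chrom = "chrB", size = 1e6))
  expect_equal(nrow(pk), 0L)
})

test_that("the caller recovers simulated promoter signal", {
  sim <- default_sim()
  pk <- call_peaks_poisson(sim_tags(sim, "H3K4me3", "control"), sim$genome)
  truth <- sim$truth$peaks
  truth <- truth[truth$mark == "H3K4me3" & truth$condition == "control", ]
  hit <- bivalentr:::overlap_pairs(truth, pk)
  frac <- length(unique(hit$q)) / nrow(truth)
  expect_gte(frac, 0.9)
  expect_true(all(pk$score >= -log10(1e-8) - 1e-9))
})

test_that("caller rejects invalid inputs and handles empty tags", {
  genome <- tibble::tibble(chrom = "chr1", size = 0)
  tags <- tibble::tibble(chrom = "chr1", pos = 1:10)
  expect_error(call_peaks_poisson(tags, genome), "> 0")
  empty <- tibble::tibble(chrom = character(), pos = numeric())
  expect_equal(nrow(call_peaks_poisson(
    empty, tibble::tibble(chrom = "chr1", size = 1e5))), 0L)
  expect_error(call_peaks_poisson(tags,
                                  tibble::tibble(chrom = "chr1", size = 1e5),
                                  window = 100, step = 200), "window")
})

test_that("consensus overlap implements the strict >500 bp rule", {
  a <- genomic_intervals("chr1", 0, 1000)
  b <- genomic_intervals("chr1", 400, 1400)
  res <- consensus_overlap(a, b)
  expect_equal(res$fraction_a, 1)
  # overlap of exactly 500 bp with the consensus does not count
  res2 <- consensus_overlap(genomic_intervals("chr1", 0, 500),
                            genomic_intervals("chr1", 0, 500))
  expect_equal(res2$n_a_overlapping, 0L)
  # 501 passes
  res3 <- consensus_overlap(genomic_intervals("chr1", 0, 501),
                            genomic_intervals("chr1", 0, 501))
  expect_equal(res3$n_a_overlapping, 1L)
  # identical 2 kb peaks overlap
  p2k <- genomic_intervals("chr1", 10000, 12000)
  expect_equal(consensus_overlap(p2k, p2k)$fraction_a, 1)
  expect_error(consensus_overlap(p2k[0, ], p2k), "empty")
})

test_that("overlap fraction ignores B duplication and falls with min_overlap", {
  withr::with_seed(31, {
    a <- random_peaks(25)
    b <- random_peaks(25)
  })
  r1 <- consensus_overlap(a, b)
  r2 <- consensus_overlap(a, dplyr::bind_rows(b, b[1:10, ]))
  expect_equal(r1$fraction_a, r2$fraction_a)
  fr <- vapply(c(0, 250, 500, 750),
               function(m) consensus_overlap(a, b, min_overlap = m)$fraction_a,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("Venn compartments match brute-force enumeration and sum to the total", {
  s1 <- genomic_intervals("chr1", 0, 1000)
  s2 <- genomic_intervals("chr1", 5000, 6000)
  r <- venn_counts(list(A = s1, B = s2), min_overlap = 500)
  expect_equal(r$n[r$compartment == "A"], 1L)
  expect_equal(r$n[r$compartment == "B"], 1L)
  expect_equal(r$n[r$compartment == "A&B"], 0L)
  r_id <- venn_counts(list(A = s1, B = s1), min_overlap = 500)
  expect_equal(r_id$n[r_id$compartment == "A&B"], 1L)
  expect_equal(sum(r_id$n), 1L)

  withr::with_seed(41, {
    sets <- list(A = random_peaks(30), B = random_peaks(30),
                 C = random_peaks(30))
  })
  res <- venn_counts(sets, min_overlap = 500)
  consensus <- bf_consensus(dplyr::bind_rows(sets))
  expect_equal(sum(res$n), nrow(consensus))
  flags <- t(vapply(seq_len(nrow(consensus)), function(i) {
    vapply(sets, bf_flag, logical(1), region = consensus[i, ],
           min_overlap = 500)
  }, logical(3)))
  pattern <- apply(flags, 1, function(row)
    if (!any(row)) "none" else paste(names(sets)[row], collapse = "&"))
  oracle <- table(pattern)
  for (comp in names(oracle)) {
    expect_equal(res$n[res$compartment == comp], unname(oracle[[comp]]),
                 label = comp)
  }
})
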