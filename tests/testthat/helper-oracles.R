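# Brute-force reference implementations used as independent oracles.

# Per-base boolean union membership over a toy chromosome.
bf_coverage <- function(intervals, chrom, len) {
  cov <- logical(len)
  sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- max(0, sub$start[i]); hi <- min(len, sub$end[i])
    if (hi > lo) cov[(lo + 1):hi] <- TRUE
  }
  cov
}

# Per-base intersection count of two intervals on one chromosome.
bf_overlap_len <- function(a, b, len = 2000) {
  if (a$chrom != b$chrom) return(0)
  sum(bf_coverage(a, a$chrom, len) & bf_coverage(b, b$chrom, len))
}

# KS-style running-sum enrichment by explicit prefix enumeration.
bf_es <- function(metric, hit, weight = 1) {
  n <- length(metric)
  nh <- sum(hit)
  if (nh == n) return(1)
  mw <- abs(metric)^weight
  dev <- vapply(seq_len(n), function(i) {
    p_hit <- sum(mw[seq_len(i)][hit[seq_len(i)]]) / sum(mw[hit])
    p_miss <- sum(!hit[seq_len(i)]) / (n - nh)
    p_hit - p_miss
  }, numeric(1))
  mx <- max(dev); mn <- min(dev)
  if (mx >= abs(mn) - 1e-12) mx else mn
}

# Exact two-sided Wilcoxon p by full enumeration of rank assignments.
bf_wilcoxon_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  u_null <- apply(combos, 2, function(idx) {
    sum(seq_len(n)[idx]) - length(a) * (length(a) + 1) / 2
  })
  lo <- mean(u_null <= u_obs)
  hi <- mean(u_null >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Step-up BH by direct arithmetic.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Upper-tail Poisson probability by pmf summation.
bf_poisson_tail <- function(k, lambda, upto = 500) {
  sum(stats::dpois(k:upto, lambda))
}

random_intervals <- function(n, chroms = "chrT", len = 1000) {
  start <- sample.int(len - 2L, n, replace = TRUE) - 1L
  width <- sample.int(100L, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = pmin(len, start + width))
}

small_sim_config <- function(seed = 301L, ...) {
  simulation_config(
    n_genes = c(active = 40, bivalent_up = 10, bivalent_other = 15,
                silent = 10),
    n_chroms = 2, chrom_length = 5e5, seed = seed, ...)
}

# Default-scale simulation shared across test files (computed once).
.fixture_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_tags(simulation_config(seed = 424243L))
  }
  .fixture_env$sim
}
default_sim_de <- function() {
  if (is.null(.fixture_env$de)) {
    .fixture_env$de <- simulate_expression(default_sim())
  }
  .fixture_env$de
}
sim_promoters <- function(sim) {
  promoter_windows(sim$truth$genes[c("gene_id", "chrom", "strand", "tss")])
}
sim_tags <- function(sim, mk, cond) {
  sim$tags[sim$tags$mark == mk & sim$tags$condition == cond,
           c("chrom", "pos")]
}
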