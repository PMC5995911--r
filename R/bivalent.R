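#' Classify promoters as active, bivalent or neither
#'
#' A promoter "has" a mark when it intersects at least one peak of that
#' mark by `min_bp` bases (default 1), or — when `min_frac` is given — when
#' peaks of the mark cover at least that fraction of the promoter.
#' Promoters with both H3K4me3 and H3K27me3 are `bivalent`, H3K4me3 only
#' is `active`, anything else `neither`.
#'
#' @param promoters Promoter windows with `gene_id` (e.g. from
#'   [promoter_windows()]); gene ids must be unique.
#' @param k4_peaks,k27_peaks Peak tibbles for H3K4me3 and H3K27me3.
#' @param min_bp Minimum intersection in bp (inclusive, default 1).
#' @param min_frac Optional minimum covered fraction of the promoter;
#'   overrides `min_bp`.
#' @return Tibble `gene_id`, `has_k4me3`, `has_k27me3`, `class`.
#' @export
classify_promoters <- function(promoters, k4_peaks, k27_peaks,
                               min_bp = 1, min_frac = NULL) {
  promoters <- validate_intervals(promoters)
  if (anyDuplicated(promoters$gene_id) > 0) {
    abort("duplicate gene ids in `promoters`.")
  }
  has_mark <- function(peaks) {
    peaks <- validate_intervals(peaks)
    covered <- rep(0, nrow(promoters))
    if (nrow(peaks) > 0L) {
      merged <- merge_intervals(peaks[c("chrom", "start", "end")])
      pairs <- overlap_pairs(promoters, merged) |>
        group_by(.data$q) |>
        summarise(bp = sum(.data$bp), .groups = "drop")
      covered[pairs$q] <- pairs$bp
    }
    if (is.null(min_frac)) {
      covered >= min_bp
    } else {
      covered / (promoters$end - promoters$start) >= min_frac
    }
  }
  k4 <- has_mark(k4_peaks)
  k27 <- has_mark(k27_peaks)
  tibble(gene_id = promoters$gene_id,
         has_k4me3 = k4, has_k27me3 = k27,
         class = dplyr::case_when(k4 & k27 ~ "bivalent",
                                  k4 ~ "active",
                                  TRUE ~ "neither"))
}

#' Split bivalent genes by knockdown expression response
#'
#' Partitions the bivalent genes into `up` (`log2FC >= lfc` and
#' `FDR <= fdr`, thresholds inclusive), `down` (`log2FC <= -lfc`,
#' `FDR <= fdr`) and `no_change`; `down` and `no_change` together form
#' the "other" category. Bivalent genes absent from the DE table are
#' assigned `no_change` (with a message).
#'
#' @param states Promoter-state tibble from [classify_promoters()] (or any
#'   tibble with `gene_id` and `class`).
#' @param de DE tibble (`gene_id`, `log2FC`, `FDR`).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param fdr FDR threshold (default 0.05).
#' @return Tibble of bivalent genes: `gene_id`, `log2FC`, `FDR`, `group`
#'   (up/down/no_change), `category` (`up_bivalent` / `other_bivalent`).
#' @export
split_bivalent <- function(states, de, lfc = 1, fdr = 0.05) {
  bi <- as_tibble(states) |> filter(.data$class == "bivalent")
  de <- as_tibble(de)
  out <- bi |>
    select("gene_id") |>
    left_join(de[c("gene_id", "log2FC", "FDR")], by = "gene_id")
  n_missing <- sum(is.na(out$log2FC))
  if (n_missing > 0L) {
    message(n_missing,
            " bivalent gene(s) missing from the DE table; assigned no_change.")
  }
  out |>
    mutate(group = dplyr::case_when(
      is.na(.data$log2FC) | is.na(.data$FDR) ~ "no_change",
      .data$log2FC >= lfc & .data$FDR <= fdr ~ "up",
      .data$log2FC <= -lfc & .data$FDR <= fdr ~ "down",
      TRUE ~ "no_change"),
      category = if_else(.data$group == "up", "up_bivalent",
                         "other_bivalent"))
}

new_gene_signature <- function(name, genes, rule) {
  if (length(genes) == 0L) abort("empty signature.")
  structure(list(name = name, genes = unique(genes), rule = rule),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene signature '%s': %d genes (%s)\n",
              x$name, length(x$genes), x$rule))
  invisible(x)
}

#' Build a gene signature from a differential-expression contrast
#'
#' Selects genes at or above a log2 fold-change threshold (inclusive),
#' e.g. the genes most strongly upregulated during embryoid-body
#' differentiation relative to undifferentiated cells.
#'
#' @param de DE tibble (`gene_id`, `log2FC`).
#' @param lfc_min Inclusive log2FC threshold (default 5).
#' @param name Signature name.
#' @return A `gene_signature` object.
#' @export
build_signature <- function(de, lfc_min = 5, name = "signature") {
  de <- as_tibble(de)
  members <- de$gene_id[!is.na(de$log2FC) & de$log2FC >= lfc_min]
  if (length(members) == 0L) {
    abort(sprintf("no genes reach log2FC >= %g; signature is empty.",
                  lfc_min))
  }
  new_gene_signature(name = name, genes = members,
                     rule = sprintf("log2FC >= %g", lfc_min))
}

# Weighted running-sum enrichment statistic on a 0/1 hit vector.
running_sum_es <- function(hit, metric_w) {
  n <- length(hit)
  nh <- sum(hit)
  if (nh == n) return(list(es = 1, running = rep(1, n)))
  inc <- numeric(n)
  inc[hit] <- metric_w[hit] / sum(metric_w[hit])
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  mx <- max(rs); mn <- min(rs)
  # signed extremum; an exact magnitude tie resolves to the positive side
  es <- if (mx >= abs(mn) - 1e-12) mx else mn
  list(es = es, running = rs)
}

#' Weighted running-sum gene-set enrichment
#'
#' The classic GSEA statistic: walking down the ranked list, the running
#' sum rises by `|metric|^weight` (normalized over the set) at set
#' members and falls by `1/(N - Nh)` elsewhere; the enrichment score (ES)
#' is the signed extremum. The null distribution comes from gene-label
#' permutations under a seed-fixed stream; NES is the ES divided by the
#' mean magnitude of same-sign null scores and the nominal p is the
#' add-one-corrected fraction of same-sign null scores at least as
#' extreme. When the set spans the whole list (no misses) the ES is
#' defined as 1.
#'
#' @param ranked Tibble with `gene_id` and `metric` (ranking statistic,
#'   e.g. knockdown log2FC), or a named numeric vector. Sorted internally
#'   by decreasing metric.
#' @param signature A `gene_signature` (or character vector of gene ids).
#'   Members absent from `ranked` are dropped with a message.
#' @param weight Exponent on `|metric|` (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov form).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Seed for the permutation stream.
#' @return An `enrichment_result` with elements `es`, `nes`, `pvalue`,
#'   `fdr`, `n_perm`, `seed`, `n_genes`, `n_hits`, `running` (per-rank
#'   tibble) and `null_es`. `tidy()` returns the running sum, `glance()`
#'   the one-row summary.
#' @export
enrichment_score <- function(ranked, signature, weight = 1,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(gene_id = names(ranked), metric = unname(ranked))
  }
  ranked <- as_tibble(ranked)
  if (anyDuplicated(ranked$gene_id) > 0) {
    abort("duplicate gene ids in `ranked`.")
  }
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else unique(as.character(signature))
  dropped <- setdiff(genes, ranked$gene_id)
  if (length(dropped) > 0L) {
    message(length(dropped), " signature gene(s) not in the ranked list; dropped.")
  }
  genes <- intersect(genes, ranked$gene_id)
  if (length(genes) == 0L) {
    abort("signature has no genes in common with the ranked list.")
  }
  ranked <- ranked |> arrange(dplyr::desc(.data$metric))
  hit <- ranked$gene_id %in% genes
  mw <- abs(ranked$metric)^weight
  obs <- running_sum_es(hit, mw)
  nh <- sum(hit)
  null_es <- with_seed(derive_seed(seed, "gsea-permutations"), {
    vapply(seq_len(n_perm), function(i) {
      ph <- logical(length(hit))
      ph[sample.int(length(hit), nh)] <- TRUE
      running_sum_es(ph, mw)$es
    }, numeric(1))
  })
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0L) {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  } else {
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (length(same) + 1)
  }
  structure(list(
    es = obs$es, nes = nes, pvalue = p, fdr = p,
    n_perm = n_perm, seed = seed, weight = weight,
    n_genes = length(hit), n_hits = nh,
    running = tibble(rank = seq_along(hit), gene_id = ranked$gene_id,
                     metric = ranked$metric, hit = hit,
                     running_sum = obs$running),
    null_es = null_es
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: ES = %.3f, NES = %.3f, p = %.4g (%d/%d genes in set, %d perms)\n",
    x$es, x$nes, x$pvalue, x$n_hits, x$n_genes, x$n_perm))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) x$running

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, pvalue = x$pvalue, fdr = x$fdr,
         n_genes = x$n_genes, n_hits = x$n_hits, n_perm = x$n_perm,
         seed = x$seed)
}
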