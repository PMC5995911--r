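# All pairwise (query, subject) overlaps with their shared base counts.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble(q = integer(), s = integer(), bp = numeric()))
  }
  qgr <- intervals_to_granges(query)
  sgr <- intervals_to_granges(subject)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(qgr, sgr, ignore.strand = TRUE))
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(qgr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(sgr)[S4Vectors::subjectHits(hits)]))
  tibble(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits),
         bp = as.numeric(ov))
}

#' Poisson background peak caller
#'
#' A deliberately simple sliding-window caller: the genome-wide background
#' rate is `total_tags x window / genome_length`, a window is significant
#' when the upper-tail Poisson probability `P(X >= k)` is at or below
#' `p_threshold`, and overlapping or adjacent significant windows merge
#' into one peak whose score is the maximum `-log10 p` (capped at 1000).
#' There is no local-lambda model or control-input subtraction; externally
#' called peaks can be supplied as BED wherever a peak set is accepted.
#'
#' @param tags Tag tibble (`chrom`, `pos`) for one sample; duplicate
#'   positions are collapsed.
#' @param genome Tibble `chrom`, `size`.
#' @param window Sliding-window width in bp (default 300).
#' @param step Window step in bp (default 100); `window >= step > 0`.
#' @param p_threshold Poisson upper-tail threshold (default 1e-8).
#' @return Peak tibble: `chrom`, `start`, `end`, `score` (`-log10 p`),
#'   `summit` (offset of the best window centre from `start`).
#' @export
call_peaks_poisson <- function(tags, genome, window = 300, step = 100,
                               p_threshold = 1e-8) {
  if (!(window >= step && step > 0)) abort("need window >= step > 0.")
  genome_length <- sum(genome$size)
  if (genome_length <= 0) abort("genome length must be > 0.")
  tags <- dedup_tags(tags)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  score = numeric(), summit = numeric())
  if (nrow(tags) == 0L) return(empty)
  lambda <- nrow(tags) * window / genome_length
  log_thr <- log(p_threshold)
  out <- purrr::map(seq_len(nrow(genome)), function(ci) {
    chrom <- genome$chrom[ci]
    size <- genome$size[ci]
    pos <- sort(tags$pos[tags$chrom == chrom])
    if (length(pos) == 0L || size < window) return(NULL)
    starts <- seq(0, size - window, by = step)
    k <- findInterval(starts + window - 0.5, pos) -
      findInterval(starts - 0.5, pos)
    logp <- stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE)
    sig <- which(logp <= log_thr)
    if (length(sig) == 0L) return(NULL)
    score <- pmin(-logp[sig] / log(10), 1000)
    ws <- starts[sig]
    # merge overlapping/adjacent significant windows into peaks
    grp <- cumsum(c(1, ifelse(ws[-1] <= ws[-length(ws)] + window, 0, 1)))
    tibble(chrom = chrom, wstart = ws, score = score, grp = grp) |>
      group_by(.data$grp) |>
      summarise(chrom = .data$chrom[1],
                start = min(.data$wstart),
                end = max(.data$wstart) + window,
                summit = .data$wstart[which.max(.data$score)] +
                  window / 2 - min(.data$wstart),
                score = max(.data$score),
                .groups = "drop") |>
      select("chrom", "start", "end", "score", "summit")
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty else arrange(res, .data$chrom, .data$start)
}

#' Consensus-region peak overlap
#'
#' Implements the consensus-merge overlap rule: peaks of both sets are
#' merged into consensus regions; a peak of set A counts as "overlapped"
#' if some consensus region receives **more than** `min_overlap` bp from
#' it and more than `min_overlap` bp from at least one B peak (strictly
#' greater: 501 bp passes, 500 bp does not). `mode = "pairwise"` instead
#' requires a direct A-vs-B overlap exceeding `min_overlap`.
#'
#' @param peaks_a,peaks_b Peak or interval tibbles (`chrom`, `start`,
#'   `end`).
#' @param min_overlap Minimum shared bases, exclusive (default 500).
#' @param mode `"consensus"` (default) or `"pairwise"`.
#' @return One-row tibble: `n_a`, `n_b`, `n_a_overlapping`, `fraction_a`,
#'   `min_overlap`, `mode`. The per-A-peak logical flags are attached as
#'   attribute `"overlapped"`.
#' @export
consensus_overlap <- function(peaks_a, peaks_b, min_overlap = 500,
                              mode = c("consensus", "pairwise")) {
  mode <- match.arg(mode)
  peaks_a <- validate_intervals(peaks_a)
  peaks_b <- validate_intervals(peaks_b)
  if (nrow(peaks_a) == 0L) abort("`peaks_a` is empty; fraction undefined.")
  if (mode == "pairwise") {
    pairs <- overlap_pairs(peaks_a, peaks_b) |> filter(.data$bp > min_overlap)
    flags <- seq_len(nrow(peaks_a)) %in% pairs$q
  } else {
    consensus <- merge_intervals(bind_rows(
      peaks_a[c("chrom", "start", "end")], peaks_b[c("chrom", "start", "end")]))
    a_pairs <- overlap_pairs(peaks_a, consensus) |>
      filter(.data$bp > min_overlap)
    b_regions <- overlap_pairs(peaks_b, consensus) |>
      filter(.data$bp > min_overlap) |>
      pull("s") |> unique()
    flags <- seq_len(nrow(peaks_a)) %in%
      a_pairs$q[a_pairs$s %in% b_regions]
  }
  res <- tibble(n_a = nrow(peaks_a), n_b = nrow(peaks_b),
                n_a_overlapping = sum(flags),
                fraction_a = sum(flags) / nrow(peaks_a),
                min_overlap = min_overlap, mode = mode)
  attr(res, "overlapped") <- flags
  res
}

#' Venn compartment counts over consensus regions
#'
#' Merges the peaks of all sets into consensus regions and flags, per
#' region, which input sets contribute more than `min_overlap` bp through
#' at least one peak. Compartments are named by the sets present
#' (`"A&B"`, ...; `"none"` when no set passes the threshold for a
#' region); compartment counts sum to the number of consensus regions.
#'
#' @param sets Named list of 2 or 3 (or more) peak tibbles.
#' @param min_overlap Minimum shared bases, exclusive (default 500).
#' @return Tibble `compartment`, `n`, plus the per-region membership table
#'   as attribute `"membership"`.
#' @export
venn_counts <- function(sets, min_overlap = 500) {
  if (length(sets) < 2L || is.null(names(sets))) {
    abort("`sets` must be a named list of at least two peak tables.")
  }
  sets <- purrr::map(sets, validate_intervals)
  consensus <- merge_intervals(bind_rows(
    purrr::map(sets, ~ .x[c("chrom", "start", "end")])))
  member <- purrr::map(sets, function(pk) {
    hit <- overlap_pairs(pk, consensus) |> filter(.data$bp > min_overlap)
    seq_len(nrow(consensus)) %in% hit$s
  })
  mtab <- as_tibble(member)
  pattern <- apply(as.matrix(mtab), 1L, function(row) {
    if (!any(row)) "none" else paste(names(sets)[row], collapse = "&")
  })
  all_patterns <- c(
    unlist(purrr::map(seq_along(sets), function(k) {
      utils::combn(names(sets), k, FUN = paste, collapse = "&")
    })), "none")
  counts <- tibble(compartment = factor(pattern, levels = all_patterns)) |>
    count(.data$compartment, .drop = FALSE) |>
    mutate(compartment = as.character(.data$compartment))
  attr(counts, "membership") <- dplyr::bind_cols(consensus, mtab)
  counts
}
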