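single_sample_tags <- function(tags) {
  tags <- as_tibble(tags)
  for (col in c("mark", "condition")) {
    if (col %in% names(tags) && length(unique(tags[[col]])) > 1L) {
      abort(sprintf(
        "`tags` mixes several values of `%s`; filter to one sample first.",
        col))
    }
  }
  tags
}

# Clonal-read removal: identical (chrom, position) tags collapse to one.
dedup_tags <- function(tags) {
  single_sample_tags(tags) |> distinct(.data$chrom, .data$pos)
}

#' Depth-normalization factor
#'
#' The scale that takes a sample's deduplicated tag total to the common
#' normalization target (20,000,000 by default); all per-window and
#' per-bin counts downstream are multiplied by it so samples of different
#' depth are comparable.
#'
#' @param tags Tag tibble (`chrom`, `pos`) for one sample; duplicate
#'   positions are collapsed before counting.
#' @param target Normalization target in tags (default 2e7).
#' @return A single number, `target / total_count`.
#' @examples
#' tags <- tibble::tibble(chrom = "chr1", pos = 1:7)
#' normalization_factor(tags, target = 21)  # 3
#' @export
normalization_factor <- function(tags, target = 2e7) {
  assert_scalar_number(target, "target", positive = TRUE)
  total <- nrow(dedup_tags(tags))
  if (total == 0L) abort("empty tag collection: no tags to normalize.")
  target / total
}

#' Normalized tag occupancy in genomic windows
#'
#' Counts, per window, the deduplicated tags whose position falls in
#' `[start, end)` and multiplies by the normalization scale. With
#' `per_bp = TRUE` the count is further divided by the window length
#' (average density rather than summed occupancy).
#'
#' @param windows Interval tibble (e.g. from [promoter_windows()]).
#' @param tags Tag tibble (`chrom`, `pos`) for one sample.
#' @param scale Normalization scale; defaults to
#'   `normalization_factor(tags, target)`.
#' @param target Normalization target used when `scale` is `NULL`.
#' @param per_bp Divide by window length (default FALSE).
#' @return The `windows` tibble with an `occupancy` column appended.
#' @export
window_occupancy <- function(windows, tags, scale = NULL, target = 2e7,
                             per_bp = FALSE) {
  windows <- validate_intervals(windows)
  tags <- dedup_tags(tags)
  if (is.null(scale)) {
    scale <- if (nrow(tags) == 0L) 1 else target / nrow(tags)
  }
  assert_scalar_number(scale, "scale", positive = TRUE)
  counts <- count_in_windows(tags, windows)
  occ <- counts * scale
  if (per_bp) occ <- occ / (windows$end - windows$start)
  windows |> mutate(occupancy = occ)
}

count_in_windows <- function(tags, windows) {
  if (nrow(tags) == 0L || nrow(windows) == 0L) {
    return(rep(0, nrow(windows)))
  }
  wgr <- intervals_to_granges(windows)
  tgr <- GenomicRanges::GRanges(tags$chrom,
                                IRanges::IRanges(tags$pos + 1L, width = 1L))
  suppressWarnings(
    GenomicRanges::countOverlaps(wgr, tgr, ignore.strand = TRUE))
}

#' Anchor-centred occupancy matrix
#'
#' Bins normalized tag counts over `[anchor - flank, anchor + flank)` for
#' each anchor (typically TSSs). For minus-strand anchors the bin order is
#' reversed so that upstream is always on the left. Duplicate tag
#' positions are collapsed before binning.
#'
#' @param anchors Tibble of anchors: either gene models (`gene_id`,
#'   `chrom`, `strand`, `tss`) or intervals (`chrom`, `start`, `end`),
#'   whose midpoints are used (unstranded).
#' @param tags Tag tibble (`chrom`, `pos`) for one sample.
#' @param flank Half-window in bp (default 5000); must be divisible by
#'   `bin_size`.
#' @param bin_size Bin width in bp (default 50).
#' @param scale Normalization scale; defaults to
#'   `normalization_factor(tags, target)`.
#' @param target Normalization target used when `scale` is `NULL`.
#' @return An `occupancy_matrix`: a numeric matrix (anchors x bins) with
#'   `gene_id` rownames and attributes `bin_size`, `flank`, `scale`.
#' @export
anchor_matrix <- function(anchors, tags, flank = 5000, bin_size = 50,
                          scale = NULL, target = 2e7) {
  assert_scalar_number(flank, "flank", positive = TRUE)
  assert_scalar_number(bin_size, "bin_size", positive = TRUE)
  if (flank %% bin_size != 0) abort("`flank` must be divisible by `bin_size`.")
  anchors <- as_tibble(anchors)
  if (!"tss" %in% names(anchors)) {
    anchors <- validate_intervals(anchors) |>
      mutate(tss = floor((.data$start + .data$end) / 2),
             strand = if ("strand" %in% names(anchors)) .data$strand else "*")
    if (!"gene_id" %in% names(anchors)) {
      anchors$gene_id <- sprintf("anchor%04d", seq_len(nrow(anchors)))
    }
  }
  tags <- dedup_tags(tags)
  if (is.null(scale)) {
    scale <- if (nrow(tags) == 0L) 1 else target / nrow(tags)
  }
  nbins <- as.integer(2 * flank / bin_size)
  mat <- matrix(0, nrow = nrow(anchors), ncol = nbins,
                dimnames = list(anchors$gene_id, NULL))
  if (nrow(anchors) > 0L && nrow(tags) > 0L) {
    wins <- tibble(chrom = anchors$chrom,
                   start = pmax(0, anchors$tss - flank),
                   end = anchors$tss + flank)
    wgr <- intervals_to_granges(wins)
    tgr <- GenomicRanges::GRanges(tags$chrom,
                                  IRanges::IRanges(tags$pos + 1L, width = 1L))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(wgr, tgr, ignore.strand = TRUE))
    ai <- S4Vectors::queryHits(hits)
    pos <- tags$pos[S4Vectors::subjectHits(hits)]
    bin <- floor((pos - (anchors$tss[ai] - flank)) / bin_size)
    keep <- bin >= 0 & bin < nbins
    ai <- ai[keep]; bin <- bin[keep]
    flip <- anchors$strand[ai] == "-"
    bin[flip] <- nbins - 1L - bin[flip]
    counts <- table(factor(ai, levels = seq_len(nrow(anchors))),
                    factor(bin, levels = 0:(nbins - 1L)))
    mat <- unclass(counts) * scale
    dimnames(mat) <- list(anchors$gene_id, NULL)
  }
  structure(mat, class = c("occupancy_matrix", "matrix", "array"),
            bin_size = bin_size, flank = flank, scale = scale)
}

#' Knockdown-minus-control delta matrix
#'
#' Elementwise `kd - control` of two occupancy matrices on the identical
#' row set and bin grid; positive values mean gain under knockdown.
#'
#' @param kd,control `occupancy_matrix` objects from [anchor_matrix()].
#' @return An `occupancy_matrix` of differences.
#' @export
delta_matrix <- function(kd, control) {
  if (!identical(dim(kd), dim(control)) ||
      !identical(rownames(kd), rownames(control)) ||
      !identical(attr(kd, "bin_size"), attr(control, "bin_size")) ||
      !identical(attr(kd, "flank"), attr(control, "flank"))) {
    abort("matrices differ in rows or bin grid; cannot subtract.")
  }
  structure(unclass(kd) - unclass(control),
            class = class(kd), bin_size = attr(kd, "bin_size"),
            flank = attr(kd, "flank"), scale = attr(kd, "scale"))
}

#' Average occupancy profile
#'
#' The per-bin arithmetic mean across rows of an occupancy matrix — the
#' metagene profile around the anchor.
#'
#' @param mat An `occupancy_matrix`.
#' @return Tibble with `offset` (bp from the anchor, bin centre; negative
#'   is upstream), `occupancy` (mean over rows) and `n` (rows aggregated).
#' @export
average_profile <- function(mat) {
  if (nrow(mat) == 0L) abort("empty occupancy matrix: nothing to average.")
  bin <- attr(mat, "bin_size")
  flank <- attr(mat, "flank")
  tibble(offset = -flank + (seq_len(ncol(mat)) - 0.5) * bin,
         occupancy = colMeans(unclass(mat)),
         n = nrow(mat))
}

#' @export
tidy.occupancy_matrix <- function(x, ...) {
  bs <- attr(x, "bin_size")
  flank <- attr(x, "flank")
  offsets <- -flank + (seq_len(ncol(x)) - 0.5) * bs
  tibble(gene_id = rep(rownames(x), times = ncol(x)),
         bin = rep(seq_len(ncol(x)), each = nrow(x)),
         offset = rep(offsets, each = nrow(x)),
         occupancy = as.vector(unclass(x)))
}

#' @export
`[.occupancy_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    out <- structure(out, class = class(x), bin_size = attr(x, "bin_size"),
                     flank = attr(x, "flank"), scale = attr(x, "scale"))
  }
  out
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy matrix: %d anchors x %d bins (bin %d bp, flank %d bp)\n",
              nrow(x), ncol(x), as.integer(attr(x, "bin_size")),
              as.integer(attr(x, "flank"))))
  invisible(x)
}

#' Write an occupancy matrix as TSV
#'
#' Rows are anchors (`gene_id` first column), columns bin offsets; a `#`
#' header documents grid and normalization.
#'
#' @param mat An `occupancy_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_matrix <- function(mat, path) {
  bin <- attr(mat, "bin_size"); flank <- attr(mat, "flank")
  offs <- -flank + (seq_len(ncol(mat)) - 0.5) * bin
  df <- as_tibble(as.data.frame(unclass(mat)), .name_repair = "minimal")
  names(df) <- sprintf("bp_%g", offs)
  df <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), df)
  readr::write_lines(sprintf(
    "# 0-based half-open coordinates; bin %d bp, flank %d bp; scale %g",
    as.integer(bin), as.integer(flank), attr(mat, "scale")), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Estimate a knockdown signal multiplier from tag data
#'
#' Background-corrected ratio of mean promoter tag density, knockdown
#' over control, for one mark and one set of promoter windows. Duplicate
#' tag positions collapse to one (as everywhere in the package), which
#' under-counts dense windows; the estimator inverts that collision loss
#' analytically (`d = -log(1 - k/L)` for `k` distinct positions over `L`
#' bp, the Poisson-occupancy MLE). The background density per condition
#' is estimated from tags outside `exclude` and subtracted before taking
#' the ratio; the standard error combines the sampling variance of both
#' window means (delta method).
#'
#' @param windows Promoter windows of the gene group of interest.
#' @param tags_kd,tags_control Tag tibbles for the two conditions.
#' @param genome Tibble `chrom`, `size` (for background estimation).
#' @param exclude Intervals excluded from background estimation; defaults
#'   to all of `windows`, but pass every promoter in the genome when other
#'   promoters also carry signal.
#' @return Tibble with `estimate`, `se`, `n` (windows used).
#' @export
estimate_kd_multiplier <- function(windows, tags_kd, tags_control, genome,
                                   exclude = windows) {
  windows <- validate_intervals(windows)
  if (nrow(windows) == 0L) abort("no windows supplied.")
  excl <- merge_intervals(exclude[c("chrom", "start", "end")])
  genome_size <- sum(genome$size)
  excl_bases <- sum(excl$end - excl$start)
  len <- windows$end - windows$start
  one_side <- function(tags) {
    tags <- dedup_tags(tags)
    k <- count_in_windows(tags, windows)
    # invert clonal-collapse loss: distinct-per-bp -> tags-per-bp
    dens <- -log(pmax(1e-12, 1 - k / len))
    inside <- sum(count_in_windows(tags, excl))
    bg_raw <- (nrow(tags) - inside) / (genome_size - excl_bases)
    bg_density <- -log(max(1e-12, 1 - bg_raw))
    sig <- dens * len - bg_density * len
    list(mean = mean(sig), var = stats::var(sig) / length(sig))
  }
  kd <- one_side(tags_kd)
  ct <- one_side(tags_control)
  est <- kd$mean / ct$mean
  se <- abs(est) * sqrt(kd$var / kd$mean^2 + ct$var / ct$mean^2)
  tibble(estimate = est, se = se, n = nrow(windows))
}
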