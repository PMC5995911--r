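#' Genomic interval tables
#'
#' All genomic spans in this package travel as plain tibbles with columns
#' `chrom` (character), `start`, `end` (base pairs) and optionally `strand`
#' (`"+"`, `"-"` or `"*"`). Coordinates are **0-based, half-open**
#' (BED convention): a span covers bases `start, ..., end - 1`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, `0 <= start < end`.
#' @param strand Optional strand vector (`"+"`, `"-"`, `"*"`).
#' @return A tibble with one row per interval.
#' @examples
#' genomic_intervals("chr1", c(0, 500), c(1000, 2000))
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL) {
  df <- tibble(chrom = as.character(chrom),
               start = as.numeric(start),
               end = as.numeric(end))
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
}

#' Validate an interval tibble
#'
#' Checks the 0-based half-open invariants: non-empty `chrom`,
#' `0 <= start < end`.
#'
#' @param intervals A data frame with `chrom`, `start`, `end` columns.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_intervals <- function(intervals) {
  intervals <- as_tibble(intervals)
  req <- c("chrom", "start", "end")
  missing <- setdiff(req, names(intervals))
  if (length(missing)) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(intervals) == 0L) return(intervals)
  if (any(is.na(intervals$chrom) | intervals$chrom == "")) {
    abort("`chrom` must be non-empty.")
  }
  if (any(intervals$start < 0)) abort("`start` must be >= 0.")
  if (any(intervals$end <= intervals$start)) {
    abort("intervals must satisfy start < end (0-based half-open).")
  }
  intervals
}

intervals_to_granges <- function(intervals) {
  strand <- if ("strand" %in% names(intervals)) {
    ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end = as.numeric(GenomicRanges::end(gr)))
}

#' Promoter windows centred on transcription start sites
#'
#' A promoter is the fixed-width window centred at the TSS (2 kb by
#' default). The window is symmetric about the TSS regardless of strand, and
#' is clipped at position 0 (and at the chromosome end when a
#' `chrom_sizes` table is supplied); clipped windows are flagged.
#'
#' @param genes Tibble of gene models with columns `gene_id`, `chrom`,
#'   `strand`, `tss` (TSS base position, 0-based).
#' @param width Window width in bp; must be even and positive. Default 2000.
#' @param chrom_sizes Optional tibble with columns `chrom`, `size` used to
#'   clip windows at chromosome ends.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `clipped` (logical).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                         strand = "+", tss = 10000)
#' promoter_windows(genes)  # [9000, 11000)
#' @export
promoter_windows <- function(genes, width = 2000, chrom_sizes = NULL) {
  assert_scalar_number(width, "width", positive = TRUE)
  if (width %% 2 != 0) abort("`width` must be even.")
  genes <- as_tibble(genes)
  if (any(genes$tss < 0)) abort("`tss` must be >= 0.")
  half <- width / 2
  out <- genes |>
    mutate(start = pmax(0, .data$tss - half),
           end = .data$tss + half,
           clipped = .data$tss < half)
  if (!is.null(chrom_sizes)) {
    out <- out |>
      left_join(as_tibble(chrom_sizes), by = "chrom") |>
      mutate(clipped = .data$clipped | .data$end > .data$size,
             end = pmin(.data$end, .data$size)) |>
      select(-"size")
  }
  out |> select("gene_id", "chrom", "start", "end", "strand", "clipped")
}

#' Merge intervals into consensus regions
#'
#' Collapses a set of (possibly overlapping) intervals into the
#' non-overlapping union, the "consensus regions" against which the
#' >500 bp overlap rule is evaluated. Touching intervals
#' (`end == start`) are merged. Output is sorted by (chrom, start).
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @return Interval tibble of disjoint, sorted regions.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 20)))
#' @export
merge_intervals <- function(intervals) {
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  granges_to_intervals(GenomicRanges::sort(gr, ignore.strand = TRUE)) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Pairwise overlap length between intervals
#'
#' The number of shared bases between two half-open intervals:
#' `max(0, min(end) - max(start))`; intervals on different chromosomes
#' share 0 bases. Vectorized over rows (with recycling of length-1 inputs).
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end`.
#' @return Numeric vector of overlap lengths in bp.
#' @examples
#' a <- genomic_intervals("chr1", 0, 1000)
#' b <- genomic_intervals("chr1", 500, 2000)
#' overlap_length(a, b)  # 500
#' @export
overlap_length <- function(a, b) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  if (nrow(a) != nrow(b)) {
    abort("`a` and `b` must have the same number of rows (or one row).")
  }
  ol <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(a$chrom == b$chrom, ol, 0)
}
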