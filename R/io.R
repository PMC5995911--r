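#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open intervals. Lines starting with `#`,
#' `track` or `browser` are skipped. Columns beyond the sixth are ignored.
#'
#' @param path Path to a BED file.
#' @return Interval tibble with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = "c"), progress = FALSE))
  if (nrow(df) > 0L) df <- df[!grepl("^(track|browser)", df[[1]]), ]
  if (nrow(df) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (ncol(df) < 3L) abort("BED file must have at least 3 columns.")
  out <- tibble(chrom = df[[1]], start = as.numeric(df[[2]]),
                end = as.numeric(df[[3]]))
  if (ncol(df) >= 4L) out$name <- df[[4]]
  if (ncol(df) >= 5L) out$score <- as.numeric(df[[5]])
  if (ncol(df) >= 6L) out$strand <- df[[6]]
  validate_intervals(out)
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name`/`score`/`strand` columns are present.
#' Coordinates are written 0-based half-open. A `#` comment line documents
#' the convention.
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @param comment Logical; write the convention comment line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, comment = TRUE) {
  intervals <- validate_intervals(intervals)
  bed6 <- all(c("name", "score", "strand") %in% names(intervals))
  lines <- if (bed6) {
    sprintf("%s\t%d\t%d\t%s\t%g\t%s", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end),
            intervals$name, intervals$score, intervals$strand)
  } else {
    sprintf("%s\t%d\t%d", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end))
  }
  header <- if (comment) "# coordinates: 0-based half-open (BED)" else character()
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read ChIP tags from a BED file
#'
#' Each BED record is reduced to a single base-pair tag position: the 5'
#' end shifted `shift` bp toward 3' when a strand column is present, else
#' the interval midpoint. Single-bp records (`end == start + 1`) are used
#' as-is.
#'
#' @param path Path to a tag BED file.
#' @param shift 3'-ward shift applied to stranded records (default 100 bp,
#'   approximating the fragment-centre of a sequenced read).
#' @return Tibble with `chrom`, `pos` (one row per tag).
#' @export
read_tag_bed <- function(path, shift = 100) {
  bed <- read_bed(path)
  if (nrow(bed) == 0L) return(tibble(chrom = character(), pos = numeric()))
  width <- bed$end - bed$start
  pos <- if ("strand" %in% names(bed)) {
    ifelse(width == 1, bed$start,
           ifelse(bed$strand == "-", bed$end - 1 - shift, bed$start + shift))
  } else {
    ifelse(width == 1, bed$start, floor((bed$start + bed$end) / 2))
  }
  tibble(chrom = bed$chrom, pos = pmax(0, pos))
}

#' Write tags as single-bp BED3 records
#'
#' @param tags Tibble with `chrom`, `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_bed <- function(tags, path) {
  write_bed(tibble(chrom = tags$chrom, start = tags$pos, end = tags$pos + 1),
            path)
}

#' Read a TSS table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `strand`, `tss`
#' (0-based TSS position). `#` comment lines are skipped.
#'
#' @param path Path to the TSV.
#' @return Tibble of gene models.
#' @export
read_tss_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", chrom = "c", strand = "c", tss = "d"))
}

#' Extract one TSS per gene from a GTF annotation
#'
#' Uses the first listed transcript per gene; the TSS is the feature start
#' for `+` genes and `end - 1` for `-` genes (0-based). Requires the
#' `rtracklayer` package.
#'
#' @param path Path to a GTF file.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gtf_tss <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gtf_tss() requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("transcript", "gene")]
  df <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    # import() gives 1-based starts; convert to 0-based
    tss = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                 as.numeric(GenomicRanges::end(gr)) - 1,
                 as.numeric(GenomicRanges::start(gr)) - 1)
  )
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    message(sum(dup), " additional transcript(s) dropped; first listed ",
            "transcript per gene wins.")
  }
  df[!dup, ]
}

#' Read / write a differential-expression table
#'
#' Tab-separated with columns `gene_id`, `log2FC`, `FDR`, `baseline`
#' (baseline mean expression). `#` comment lines are skipped on read and a
#' convention comment is written.
#'
#' @param path File path.
#' @return `read_de_table()` returns the tibble; `write_de_table()` returns
#'   `path` invisibly.
#' @export
read_de_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", log2FC = "d", FDR = "d", baseline = "d"))
}

#' @rdname read_de_table
#' @param de DE tibble (`gene_id`, `log2FC`, `FDR`, `baseline`).
#' @export
write_de_table <- function(de, path) {
  readr::write_lines("# columns: gene_id, log2FC (KD vs control), FDR (BH), baseline mean",
                     path)
  readr::write_tsv(de, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a gene signature
#'
#' Accepts one-gene-per-line text, or GMT (first field the set name, second
#' a description, the rest member genes; only the first set is read).
#'
#' @param path Path to the signature file.
#' @param name Name for the signature (defaults to the file name or the GMT
#'   set name).
#' @return A `gene_signature` object (see [build_signature()]).
#' @export
read_signature <- function(path, name = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) abort("signature file is empty.")
  if (grepl("\t", lines[[1]])) {
    fields <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    genes <- unique(fields[-(1:2)])
    name <- name %||% fields[[1]]
  } else {
    genes <- unique(lines)
    name <- name %||% basename(path)
  }
  new_gene_signature(name = name, genes = genes, rule = paste0("file:", path))
}

#' Read a chromosome-sizes table
#'
#' Tab-separated `chrom`, `size` (bp), `#` comments allowed.
#'
#' @param path Path to the TSV.
#' @return Tibble with `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", size = "d"))
}
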