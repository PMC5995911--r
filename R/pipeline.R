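pipeline_param_defaults <- function() {
  list(
    normalization_target = 2e7, # tags
    promoter_width = 2000,      # bp, centred on the TSS
    flank = 5000,               # bp, TSS-centred matrices
    bin_size = 50,              # bp
    min_overlap = 500,          # bp, consensus overlap rule (exclusive)
    p_threshold = 1e-8,         # Poisson peak caller
    peak_window = 300,          # bp
    peak_step = 100,            # bp
    lfc = 1,                    # |log2FC| cutoff for the bivalent split
    fdr = 0.05,                 # FDR cutoff for the bivalent split
    signature_lfc_min = 5,      # log2FC cutoff for signature construction
    n_perm = 1000               # enrichment permutations
  )
}

#' Pipeline configuration
#'
#' Collects the input paths and every tunable of the end-to-end analysis.
#' Parameters not supplied keep their defaults (the printed thresholds of
#' the study design: 20,000,000-tag normalization, 2 kb promoters,
#' Poisson p <= 1e-8 peaks, >500 bp consensus overlap, |log2FC| >= 1 and
#' FDR <= 0.05 for the bivalent split, log2FC >= 5 for signature
#' construction). Unknown parameter names are an error.
#'
#' @param tags Tibble with columns `mark`, `condition`, `path` pointing at
#'   tag BED files (conditions `control` and `kd`).
#' @param tss Path to a TSS TSV (see [read_tss_table()]).
#' @param chrom_sizes Path to a chromosome-sizes TSV.
#' @param de Path to the knockdown DE TSV.
#' @param de_differentiation Optional path to a differentiation-contrast
#'   DE TSV used for signature construction.
#' @param params Named list overriding entries of the default parameter
#'   set.
#' @param seed Master seed for the permutation stream.
#' @param outdir Optional output directory; when given, [run_pipeline()]
#'   writes all artifacts there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tags, tss, chrom_sizes, de,
                            de_differentiation = NULL,
                            params = list(), seed = 1L, outdir = NULL) {
  defaults <- pipeline_param_defaults()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(params)] <- params
  tags <- as_tibble(tags)
  stopifnot(all(c("mark", "condition", "path") %in% names(tags)))
  structure(list(tags = tags, tss = tss, chrom_sizes = chrom_sizes,
                 de = de, de_differentiation = de_differentiation,
                 params = defaults, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Build a pipeline configuration for a written simulation
#'
#' Points [pipeline_config()] at the file layout produced by
#' [write_simulation()].
#'
#' @param dir Directory written by [write_simulation()].
#' @inheritParams pipeline_config
#' @return A `pipeline_config`.
#' @export
simulation_pipeline_config <- function(dir, params = list(), seed = 1L,
                                       outdir = NULL) {
  beds <- list.files(dir, pattern = "^tags_.*\\.bed$", full.names = TRUE)
  info <- sub("\\.bed$", "", basename(beds))
  parts <- strsplit(info, "_", fixed = TRUE)
  tags <- tibble(
    mark = vapply(parts, `[[`, "", 2L),
    condition = vapply(parts, `[[`, "", 3L),
    path = beds
  )
  pipeline_config(tags = tags, tss = file.path(dir, "tss.tsv"),
                  chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
                  de = file.path(dir, "de.tsv"),
                  params = params, seed = seed, outdir = outdir)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(tags = as_tibble(y$tags), tss = y$tss,
                  chrom_sizes = y$chrom_sizes, de = y$de,
                  de_differentiation = y$de_differentiation,
                  params = y$params %||% list(), seed = y$seed %||% 1L,
                  outdir = y$outdir)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$tags <- as.data.frame(y$tags)
  yaml::write_yaml(y, path)
  invisible(path)
}

stop_missing <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("missing %s input: %s", what, path %||% "<NULL>"))
  }
  path
}

#' Run the integrative promoter analysis end-to-end
#'
#' Executes, in dependency order: tag loading and depth normalization;
#' promoter occupancy per sample; Poisson peak calling; GAS41-vs-H2A.Z
#' consensus overlap (when both marks are present); bivalent/active
#' promoter classification from control H3K4me3/H3K27me3 peaks; the
#' Up/Other bivalent split against the knockdown DE table; TSS-centred
#' occupancy matrices, knockdown deltas and average profiles for H2A.Z,
#' H3K27me3 and H3K4me3 at Up-bivalent promoters with Wilcoxon tests on
#' promoter occupancy; and (when a differentiation contrast is supplied)
#' signature construction plus running-sum enrichment on the knockdown
#' ranking. With `outdir` set, all artifacts are written as TSV/JSON/BED
#' together with a run manifest; re-running the same config and seed
#' reproduces them byte-identically (timestamps only in the manifest).
#'
#' @param config A `pipeline_config`.
#' @return A named list of results (`occupancy`, `peaks`, `overlap`,
#'   `states`, `split`, `matrices`, `profiles`, `profile_tests`,
#'   `enrichment`, `manifest`), invisibly when writing to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  for (i in seq_len(nrow(config$tags))) {
    stop_missing(config$tags$path[i],
                 paste0("tag (", config$tags$mark[i], "/",
                        config$tags$condition[i], ")"))
  }
  genes <- read_tss_table(stop_missing(config$tss, "TSS table"))
  genome <- read_chrom_sizes(stop_missing(config$chrom_sizes, "chrom sizes"))
  de <- read_de_table(stop_missing(config$de, "DE table"))
  promoters <- promoter_windows(genes, width = p$promoter_width,
                                chrom_sizes = genome)

  tag_data <- purrr::pmap(config$tags, function(mark, condition, path) {
    read_tag_bed(path)
  })
  names(tag_data) <- paste(config$tags$mark, config$tags$condition, sep = "/")

  counts <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
  occupancy <- purrr::imap(tag_data, function(tg, id) {
    window_occupancy(promoters, tg, target = p$normalization_target) |>
      mutate(sample = id)
  }) |> bind_rows()

  peaks <- purrr::map(tag_data, call_peaks_poisson, genome = genome,
                      window = p$peak_window, step = p$peak_step,
                      p_threshold = p$p_threshold)

  overlap <- NULL
  if (all(c("GAS41/control", "H2A.Z/control") %in% names(peaks)) &&
      nrow(peaks[["GAS41/control"]]) > 0) {
    overlap <- consensus_overlap(peaks[["GAS41/control"]],
                                 peaks[["H2A.Z/control"]],
                                 min_overlap = p$min_overlap)
  }

  states <- NULL; split <- NULL
  if (all(c("H3K4me3/control", "H3K27me3/control") %in% names(peaks))) {
    states <- classify_promoters(promoters, peaks[["H3K4me3/control"]],
                                 peaks[["H3K27me3/control"]])
    split <- split_bivalent(states, de, lfc = p$lfc, fdr = p$fdr)
  }

  matrices <- list(); profiles <- list(); profile_tests <- list()
  if (!is.null(split)) {
    up_genes <- split$gene_id[split$category == "up_bivalent"]
    up_anchors <- genes |> filter(.data$gene_id %in% up_genes)
    up_prom <- promoters |> filter(.data$gene_id %in% up_genes)
    for (mk in intersect(c("H2A.Z", "H3K27me3", "H3K4me3"),
                         unique(config$tags$mark))) {
      ids <- paste0(mk, c("/kd", "/control"))
      if (!all(ids %in% names(tag_data)) || nrow(up_anchors) == 0) next
      m_kd <- anchor_matrix(up_anchors, tag_data[[ids[1]]],
                            flank = p$flank, bin_size = p$bin_size,
                            target = p$normalization_target)
      m_ct <- anchor_matrix(up_anchors, tag_data[[ids[2]]],
                            flank = p$flank, bin_size = p$bin_size,
                            target = p$normalization_target)
      matrices[[mk]] <- list(kd = m_kd, control = m_ct,
                             delta = delta_matrix(m_kd, m_ct))
      profiles[[mk]] <- bind_rows(
        average_profile(m_kd) |> mutate(condition = "kd"),
        average_profile(m_ct) |> mutate(condition = "control"))
      occ_kd <- window_occupancy(up_prom, tag_data[[ids[1]]],
                                 target = p$normalization_target)$occupancy
      occ_ct <- window_occupancy(up_prom, tag_data[[ids[2]]],
                                 target = p$normalization_target)$occupancy
      profile_tests[[mk]] <- wilcoxon_rank_sum(occ_kd, occ_ct) |>
        mutate(mark = mk, mean_delta = mean(occ_kd) - mean(occ_ct))
    }
  }

  enrichment <- NULL
  if (!is.null(config$de_differentiation) &&
      file.exists(config$de_differentiation)) {
    de_diff <- read_de_table(config$de_differentiation)
    sig <- build_signature(de_diff, lfc_min = p$signature_lfc_min,
                           name = "differentiation")
    ranked <- de |> select("gene_id", metric = "log2FC")
    enrichment <- enrichment_score(ranked, sig, n_perm = p$n_perm,
                                   seed = config$seed)
  }

  results <- list(promoters = promoters, occupancy = occupancy,
                  peaks = peaks, overlap = overlap, states = states,
                  split = split, matrices = matrices, profiles = profiles,
                  profile_tests = bind_rows(profile_tests),
                  enrichment = enrichment)

  manifest <- list(
    tool = paste0("bivalentr ",
                  as.character(utils::packageVersion("bivalentr"))),
    config_hash = digest::digest(unclass(config)[c("tags", "params", "seed")]),
    inputs = purrr::map_chr(
      c(config$tags$path, config$tss, config$chrom_sizes, config$de),
      ~ digest::digest(file = .x)),
    seed = config$seed,
    stage_rows = list(
      genes = nrow(genes), promoters = nrow(promoters),
      occupancy = nrow(occupancy),
      peaks = purrr::map_int(peaks, nrow),
      bivalent = if (is.null(split)) 0L else nrow(split)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  results$manifest <- manifest

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    hdr <- function(path, txt) readr::write_lines(
      paste0("# ", txt, "; coordinates 0-based half-open; normalization target ",
             format(p$normalization_target, scientific = FALSE)), path)
    w <- function(df, name, txt) {
      path <- file.path(od, name)
      hdr(path, txt)
      readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    }
    w(occupancy, "promoter_occupancy.tsv", "normalized promoter occupancy")
    for (id in names(peaks)) {
      pk <- peaks[[id]]
      if (nrow(pk) > 0) {
        write_bed(pk |>
                    mutate(name = sprintf("peak%d", dplyr::row_number()),
                           score = pmin(.data$score, 1000),
                           strand = ".") |>
                    select("chrom", "start", "end", "name", "score",
                           "strand"),
                  file.path(od, paste0("peaks_", gsub("[/.]", "_", id),
                                       ".bed")))
      }
    }
    if (!is.null(overlap)) w(overlap, "overlap_gas41_h2az.tsv",
                             "consensus overlap, GAS41 vs H2A.Z")
    if (!is.null(states)) w(states, "promoter_states.tsv",
                            "promoter chromatin classes")
    if (!is.null(split)) w(split, "bivalent_split.tsv",
                           "bivalent Up/Other split")
    for (mk in names(matrices)) {
      write_occupancy_matrix(matrices[[mk]]$delta,
                             file.path(od, paste0("delta_", mk, ".tsv")))
      w(profiles[[mk]], paste0("profile_", mk, ".tsv"),
        paste0("average TSS profile, ", mk))
    }
    if (nrow(results$profile_tests %||% tibble()) > 0) {
      w(results$profile_tests, "profile_tests.tsv",
        "Wilcoxon tests, kd vs control promoter occupancy")
    }
    if (!is.null(enrichment)) {
      jsonlite::write_json(glance(enrichment),
                           file.path(od, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }
  results
}
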