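#' Default promoter archetypes for the chromatin-state simulator
#'
#' Four promoter archetypes emulate the mESC promoter landscape the
#' analysis assumes: `active` (H3K4me3, H2A.Z, acetylation; no H3K27me3),
#' `bivalent_up` and `bivalent_other` (both H3K4me3 and H3K27me3; the
#' `_up` subset is derepressed under knockdown), and `silent`
#' (H3K27me3 only). Densities are promoter signal **above background** in
#' tags/bp under the control condition; `kd_multiplier` scales the signal
#' under knockdown. The knockdown effect is confined to `bivalent_up`
#' promoters: H2A.Z x0.5, H3K27me3 x0.6, H3K4me3 x1.1.
#'
#' @return A list with two tibbles: `signal` (`archetype`, `mark`,
#'   `density`, `kd_multiplier`) and `expression` (`archetype`,
#'   `true_log2FC`, `baseline_mean`).
#' @export
default_archetypes <- function() {
  marks <- c("H3K4me3", "H3K27me3", "H2A.Z", "H3K27ac", "H3K14ac", "GAS41")
  dens <- rbind(
    active         = c(0.10, 0.00, 0.10, 0.10, 0.08, 0.08),
    bivalent_up    = c(0.07, 0.10, 0.07, 0.03, 0.03, 0.10),
    bivalent_other = c(0.08, 0.08, 0.08, 0.05, 0.05, 0.10),
    silent         = c(0.00, 0.05, 0.00, 0.00, 0.00, 0.00)
  )
  colnames(dens) <- marks
  signal <- as_tibble(as.data.frame(dens)) |>
    mutate(archetype = rownames(dens)) |>
    tidyr::pivot_longer(-"archetype", names_to = "mark",
                        values_to = "density") |>
    mutate(kd_multiplier = dplyr::case_when(
      .data$archetype == "bivalent_up" & .data$mark == "H2A.Z" ~ 0.5,
      .data$archetype == "bivalent_up" & .data$mark == "H3K27me3" ~ 0.6,
      .data$archetype == "bivalent_up" & .data$mark == "H3K4me3" ~ 1.1,
      TRUE ~ 1.0
    ))
  expression <- tibble(
    archetype = rownames(dens),
    true_log2FC = c(0, 3, 0, 0),
    baseline_mean = c(500, 200, 400, 20)
  )
  list(signal = signal, expression = expression)
}

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic generator. The
#' default gene mix scales the mESC census (8618 active, 2389 bivalent of
#' which 435 derepressed under knockdown) down by 1/20, plus 50 silent
#' promoters. All randomness derives from `seed`; each (mark, condition)
#' sample draws from its own sub-stream.
#'
#' @param n_genes Named integer vector of genes per archetype.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param background_density Genome-wide background tag density (tags/bp).
#' @param depth Optional per-sample total-tag target. `NULL` (default)
#'   leaves densities as configured, so the expected depth is
#'   `background + promoter signal`. When given, the background density is
#'   re-scaled per sample so the expected total equals `depth`; `0` yields
#'   empty tag collections. It is an error if promoter signal alone
#'   already exceeds `depth`.
#' @param signal_width Width of the promoter signal window in bp (uniform
#'   over `[tss - w/2, tss + w/2)`).
#' @param dispersion Negative-binomial dispersion of the simulated
#'   expression counts.
#' @param n_reps Replicates per condition in the expression simulation
#'   (must be >= 2).
#' @param seed Master seed (integer).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = c(active = 431, bivalent_up = 22,
                                          bivalent_other = 97, silent = 50),
                              n_chroms = 4,
                              chrom_length = 2e6,
                              background_density = 0.005,
                              depth = NULL,
                              signal_width = 2000,
                              dispersion = 0.005,
                              n_reps = 3,
                              seed = 1L) {
  if (is.null(names(n_genes)) || any(!nzchar(names(n_genes)))) {
    abort("`n_genes` must be a named vector (one entry per archetype).")
  }
  if (any(n_genes < 0)) abort("`n_genes` must be non-negative.")
  assert_scalar_number(n_chroms, "n_chroms", positive = TRUE)
  assert_scalar_number(chrom_length, "chrom_length", positive = TRUE)
  assert_scalar_number(background_density, "background_density")
  if (background_density < 0) abort("`background_density` must be >= 0.")
  if (!is.null(depth)) {
    assert_scalar_number(depth, "depth")
    if (depth < 0) abort("`depth` must be >= 0.")
  }
  assert_scalar_number(signal_width, "signal_width", positive = TRUE)
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  assert_scalar_number(n_reps, "n_reps", positive = TRUE)
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  assert_scalar_number(seed, "seed")
  structure(list(n_genes = n_genes, n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length,
                 background_density = background_density, depth = depth,
                 signal_width = signal_width, dispersion = dispersion,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "simulation_config")
}

# Lay genes on a regular grid across chromosomes and assign shuffled
# archetypes and alternating strands (seeded).
place_genes <- function(config, archetypes) {
  n_total <- sum(config$n_genes)
  margin <- 10000
  usable <- config$chrom_length - 2 * margin
  per_chrom <- ceiling(n_total / config$n_chroms)
  spacing <- floor(usable / max(per_chrom, 1))
  if (spacing < 2 * config$signal_width) {
    abort("genome too small for the requested number of genes.")
  }
  chroms <- paste0("chr", seq_len(config$n_chroms))
  slots <- tidyr::expand_grid(chrom = chroms, slot = seq_len(per_chrom)) |>
    mutate(tss = margin + (.data$slot - 1) * spacing) |>
    dplyr::slice(seq_len(n_total))
  labels <- rep(names(config$n_genes), times = config$n_genes)
  labels <- with_seed(derive_seed(config$seed, "gene-placement"),
                      sample(labels))
  half <- config$signal_width / 2
  slots |>
    mutate(gene_id = sprintf("gene%04d", dplyr::row_number()),
           archetype = labels,
           strand = rep_len(c("+", "-"), n_total),
           promoter_start = .data$tss - half,
           promoter_end = .data$tss + half) |>
    select("gene_id", "archetype", "chrom", "strand", "tss",
           "promoter_start", "promoter_end") |>
    left_join(archetypes$expression, by = "archetype")
}

#' Simulate multi-mark, two-condition ChIP tag data with ground truth
#'
#' Tags are single-bp points drawn per (mark, condition) sample from (a) a
#' uniform genome-wide background and (b) uniform promoter-centred signal
#' windows, with expected promoter tag count `density x width x multiplier`
#' (the multiplier applies under the `kd` condition only). Sample totals
#' are Poisson around their expectation. The same seed reproduces the
#' output exactly.
#'
#' @param config A [simulation_config()].
#' @param archetypes Archetype definition as returned by
#'   [default_archetypes()]; densities must be non-negative.
#' @return A `chip_simulation` list with elements:
#'   \describe{
#'     \item{tags}{tibble `mark`, `condition`, `chrom`, `pos` (one row per tag)}
#'     \item{truth}{list: `genes` (per-gene archetype, promoter, true
#'       log2FC), `occupancy` (per gene x mark x condition expected signal
#'       tag count), `peaks` (true signal intervals per mark/condition),
#'       `samples` (expected totals)}
#'     \item{genome}{tibble `chrom`, `size`}
#'     \item{config}{the config used}
#'   }
#' @export
simulate_tags <- function(config = simulation_config(),
                          archetypes = default_archetypes()) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(archetypes$signal$density < 0)) {
    abort("archetype densities must be >= 0.")
  }
  if (any(archetypes$signal$kd_multiplier < 0)) {
    abort("KD multipliers must be >= 0.")
  }
  if (anyDuplicated(unique(archetypes$signal[c("archetype", "mark")])) > 0) {
    abort("duplicate (archetype, mark) rows in archetype signal table.")
  }
  genes <- place_genes(config, archetypes)
  genome <- tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
                   size = config$chrom_length)
  genome_size <- sum(genome$size)
  w <- config$signal_width
  marks <- unique(archetypes$signal$mark)
  conditions <- c("control", "kd")

  # per-gene expected signal tag count for each mark x condition
  occupancy <- genes |>
    select("gene_id", "archetype", "chrom", "promoter_start",
           "promoter_end") |>
    left_join(archetypes$signal, by = "archetype",
              relationship = "many-to-many") |>
    tidyr::expand_grid(condition = conditions) |>
    mutate(multiplier = ifelse(.data$condition == "kd",
                               .data$kd_multiplier, 1),
           expected_tags = .data$density * w * .data$multiplier) |>
    select("gene_id", "mark", "condition", "density", "multiplier",
           "expected_tags")

  true_peaks <- genes |>
    left_join(archetypes$signal, by = "archetype",
              relationship = "many-to-many") |>
    filter(.data$density > 0) |>
    tidyr::expand_grid(condition = conditions) |>
    mutate(start = .data$promoter_start, end = .data$promoter_end) |>
    select("mark", "condition", "chrom", "start", "end", "gene_id")

  signal_totals <- occupancy |>
    group_by(.data$mark, .data$condition) |>
    summarise(signal = sum(.data$expected_tags), .groups = "drop")

  samples <- signal_totals |>
    mutate(background = if (is.null(config$depth)) {
      config$background_density * genome_size
    } else {
      pmax(0, config$depth - .data$signal)
    })
  if (!is.null(config$depth) && config$depth > 0 &&
      any(samples$signal > config$depth)) {
    abort("`depth` is smaller than the expected promoter signal alone.")
  }
  if (!is.null(config$depth) && config$depth == 0) {
    samples$background <- 0
    samples$signal_scale <- 0
  } else {
    samples$signal_scale <- 1
  }
  samples <- samples |>
    mutate(expected_total = .data$background +
             .data$signal * .data$signal_scale)

  sim_sample <- function(mk, cond) {
    srow <- samples[samples$mark == mk & samples$condition == cond, ]
    with_seed(derive_seed(config$seed, paste0("tags/", mk, "/", cond)), {
      n_bg <- if (srow$background > 0) rpois(1L, srow$background) else 0L
      bg <- if (n_bg > 0) {
        chrom_idx <- sample.int(nrow(genome), n_bg, replace = TRUE,
                                prob = genome$size)
        tibble(chrom = genome$chrom[chrom_idx],
               pos = floor(runif(n_bg, 0, genome$size[chrom_idx])))
      } else tibble(chrom = character(), pos = numeric())
      occ <- occupancy |>
        filter(.data$mark == mk, .data$condition == cond,
               .data$expected_tags > 0) |>
        left_join(genes[c("gene_id", "chrom", "promoter_start",
                          "promoter_end")], by = "gene_id")
      sig <- if (nrow(occ) > 0 && srow$signal_scale > 0) {
        counts <- rpois(nrow(occ), occ$expected_tags)
        idx <- rep(seq_len(nrow(occ)), counts)
        tibble(chrom = occ$chrom[idx],
               pos = floor(runif(length(idx), occ$promoter_start[idx],
                                 occ$promoter_end[idx])))
      } else tibble(chrom = character(), pos = numeric())
      bind_rows(bg, sig) |>
        mutate(mark = mk, condition = cond) |>
        arrange(.data$chrom, .data$pos)
    })
  }

  tags <- tidyr::expand_grid(mark = marks, condition = conditions) |>
    purrr::pmap(function(mark, condition) sim_sample(mark, condition)) |>
    bind_rows() |>
    select("mark", "condition", "chrom", "pos")

  structure(list(
    tags = tags,
    truth = list(genes = genes, occupancy = occupancy, peaks = true_peaks,
                 samples = samples |>
                   select("mark", "condition", "expected_total")),
    genome = genome,
    config = config
  ), class = "chip_simulation")
}

#' Simulate a matched differential-expression table
#'
#' For each simulated gene, counts are drawn for two conditions x
#' `n_reps` replicates from a negative binomial with mean
#' `baseline_mean` (control) or `baseline_mean x 2^true_log2FC`
#' (knockdown) and the configured dispersion. The per-gene two-sided test
#' is a Welch t on `log2(count + 1)` across replicates;
#' Benjamini-Hochberg adjustment gives the `FDR` column. The observed
#' `log2FC` is the difference of mean log2 counts.
#'
#' @param sim A `chip_simulation` (or its `truth$genes` tibble together
#'   with a `config`).
#' @param config A [simulation_config()]; defaults to the one stored in
#'   `sim`.
#' @return DE tibble: `gene_id`, `log2FC`, `FDR`, `baseline`, plus
#'   `pvalue` and the true values (`archetype`, `true_log2FC`) for
#'   benchmarking.
#' @export
simulate_expression <- function(sim, config = NULL) {
  if (inherits(sim, "chip_simulation")) {
    genes <- sim$truth$genes
    config <- config %||% sim$config
  } else {
    genes <- as_tibble(sim)
    if (is.null(config)) abort("`config` is required when `sim` is a gene table.")
  }
  if (nrow(genes) == 0L) abort("no genes to simulate expression for.")
  if (config$n_reps < 2) abort("`n_reps` must be >= 2.")
  size <- 1 / config$dispersion
  n <- nrow(genes)
  r <- config$n_reps
  with_seed(derive_seed(config$seed, "expression"), {
    ctrl <- matrix(rnbinom(n * r, mu = rep(genes$baseline_mean, each = r),
                           size = size), nrow = r)
    kd <- matrix(rnbinom(n * r,
                         mu = rep(genes$baseline_mean * 2^genes$true_log2FC,
                                  each = r), size = size), nrow = r)
  })
  lc <- log2(ctrl + 1)
  lk <- log2(kd + 1)
  pvals <- vapply(seq_len(n), function(i) {
    a <- lk[, i]; b <- lc[, i]
    if (stats::var(a) + stats::var(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  tibble(
    gene_id = genes$gene_id,
    log2FC = colMeans(lk) - colMeans(lc),
    pvalue = pvals,
    FDR = stats::p.adjust(pvals, method = "BH"),
    baseline = colMeans(ctrl),
    archetype = genes$archetype,
    true_log2FC = genes$true_log2FC
  )
}

#' Write a simulation to disk as plain-text files
#'
#' One BED3 file per (mark, condition) sample (`tags_<mark>_<condition>.bed`),
#' plus `tss.tsv`, `chrom_sizes.tsv`, `truth_genes.tsv`,
#' `truth_occupancy.tsv` and, when `de` is supplied, `de.tsv`.
#'
#' @param sim A `chip_simulation`.
#' @param dir Output directory (created if needed).
#' @param de Optional DE tibble from [simulate_expression()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, de = NULL) {
  stopifnot(inherits(sim, "chip_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- unique(sim$tags[c("mark", "condition")])
  for (i in seq_len(nrow(samples))) {
    mk <- samples$mark[i]; cond <- samples$condition[i]
    sub <- sim$tags |> filter(.data$mark == mk, .data$condition == cond)
    # mark names must not contain "_" (the filename field separator)
    write_tag_bed(sub, file.path(dir, sprintf("tags_%s_%s.bed", mk, cond)))
  }
  tss <- sim$truth$genes |> select("gene_id", "chrom", "strand", "tss")
  readr::write_lines("# coordinates: 0-based; tss is the TSS base position",
                     file.path(dir, "tss.tsv"))
  readr::write_tsv(tss, file.path(dir, "tss.tsv"), append = TRUE,
                   col_names = TRUE)
  readr::write_tsv(sim$genome, file.path(dir, "chrom_sizes.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$occupancy,
                   file.path(dir, "truth_occupancy.tsv"))
  if (!is.null(de)) {
    write_de_table(de[c("gene_id", "log2FC", "FDR", "baseline")],
                   file.path(dir, "de.tsv"))
  }
  invisible(dir)
}
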