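#' Comparative-CT (2^-ddCt) relative expression
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; the test sample's dCt is
#' referenced to the calibrator's (`ddCt = dCt_test - dCt_calibrator`) and
#' relative expression is `2^-ddCt`. When the calibrator has several
#' rows its mean dCt is used.
#'
#' @param test Tibble with columns `target_ct`, `reference_ct` and
#'   optionally `sample_id`; one row per test sample.
#' @param calibrator Tibble with `target_ct`, `reference_ct` (one or more
#'   rows; averaged).
#' @return Tibble `sample_id`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expression`.
#' @examples
#' cal <- tibble::tibble(target_ct = 24, reference_ct = 18)
#' test <- tibble::tibble(target_ct = 25, reference_ct = 18)
#' comparative_ct(test, cal)$rel_expression  # 0.5
#' @export
comparative_ct <- function(test, calibrator) {
  test <- as_tibble(test)
  calibrator <- as_tibble(calibrator)
  if (any(c(test$target_ct, test$reference_ct,
            calibrator$target_ct, calibrator$reference_ct) <= 0)) {
    abort("Ct values must be > 0.")
  }
  cal_dct <- mean(calibrator$target_ct - calibrator$reference_ct)
  dct <- test$target_ct - test$reference_ct
  ddct <- dct - cal_dct
  tibble(
    sample_id = if ("sample_id" %in% names(test)) test$sample_id
                else sprintf("sample%d", seq_len(nrow(test))),
    delta_ct = dct, delta_delta_ct = ddct,
    rel_expression = 2^(-ddct)
  )
}

#' Two-tailed unpaired t test
#'
#' Classical two-sample Student t with pooled variance by default (the
#' form usually labelled "Student's t-test" in figure legends); set
#' `var_equal = FALSE` for the Welch form. When both samples have zero
#' variance and equal means the p-value is defined as 1.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default TRUE).
#' @return One-row tibble: `statistic` (t), `df`, `p.value`, `method`.
#' @export
t_test_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each sample needs at least 2 values.")
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p.value = 1, method = "degenerate (zero variance)"))
    }
    abort("zero variance in both samples with unequal means; t undefined.")
  }
  fit <- stats::t.test(a, b, var.equal = var_equal)
  tibble(statistic = unname(fit$statistic), df = unname(fit$parameter),
         p.value = fit$p.value, method = fit$method)
}

#' Two-tailed unpaired Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The p-value is
#' exact (full enumeration of rank assignments) when the combined sample
#' size is at most `exact_max` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param a,b Numeric samples (each length >= 1).
#' @param exact_max Combined-n switch point for the exact test
#'   (default 12).
#' @return One-row tibble: `statistic` (the Mann-Whitney U for `a`),
#'   `p.value`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) < 1L || length(b) < 1L) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= exact_max && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble(statistic = unname(fit$statistic), p.value = fit$p.value,
         exact = exact)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Categorize colony staining intensities against a control sample
#'
#' Cutoffs are the 10th and 40th percentiles of the **control**
#' intensities (linear-interpolation quantiles), so that by construction
#' the control splits into bottom 10% "low", middle 30% "intermediate"
#' and top 60% "high". The same cutoffs are applied unchanged to every
#' sample; boundaries are assigned downward (intensity <= q10 is low,
#' <= q40 intermediate, else high).
#'
#' @param samples Tibble with columns `intensity` and `sample` (and
#'   optionally `colony_id`); may include the control itself.
#' @param control Numeric vector of control-colony intensities (or a
#'   tibble with an `intensity` column).
#' @return List with `colonies` (input plus `category`), `fractions`
#'   (per-sample category fractions) and `cutoffs` (named numeric,
#'   `q10`/`q40`).
#' @export
ap_categorize <- function(samples, control) {
  if (is.data.frame(control)) control <- control$intensity
  if (length(control) == 0L) abort("control sample is empty.")
  if (any(control < 0)) abort("intensities must be >= 0.")
  cuts <- stats::quantile(control, c(0.1, 0.4), type = 7, names = FALSE)
  samples <- as_tibble(samples)
  colonies <- samples |>
    mutate(category = dplyr::case_when(
      .data$intensity <= cuts[1] ~ "low",
      .data$intensity <= cuts[2] ~ "intermediate",
      TRUE ~ "high"))
  fractions <- colonies |>
    count(.data$sample,
          category = factor(.data$category,
                            levels = c("low", "intermediate", "high")),
          .drop = FALSE) |>
    group_by(.data$sample) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(category = as.character(.data$category))
  list(colonies = colonies, fractions = fractions,
       cutoffs = c(q10 = cuts[1], q40 = cuts[2]))
}
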