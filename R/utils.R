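#' @importFrom rlang abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n across rename count pull if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

# Derive a reproducible 32-bit sub-seed from a master seed and a string label.
# Each (mark, condition) pair gets its own stream so adding a mark never
# perturbs the draws of another.
derive_seed <- function(master_seed, label) {
  h <- digest::digest(list(as.integer(master_seed), as.character(label)),
                      algo = "crc32")
  (strtoi(substr(h, 1, 7), base = 16L) + as.integer(master_seed)) %% 2147483587L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}
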