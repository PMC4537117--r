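#' Per-sample capture statistics
#'
#' Summarises a per-base depth vector over the target together with the
#' on-target read count: total on-target bases (reads x read length), mean
#' depth, the fraction of target bases at >= 20-fold, and 1x coverage.
#' Mean depth is computed empirically from the depth vector, not as
#' bases / target size: the two differ whenever reads are deduplicated or
#' clipped before depth is tallied.
#'
#' @param depth_vector Non-negative per-base depths over the whole target.
#' @param on_target_reads Number of reads mapped to the target.
#' @param read_length Read length in bases.
#' @return A one-row tibble of class `"capture_stats"`: `on_target_reads`,
#'   `read_length`, `on_target_bases`, `mean_depth`, `fraction_ge_20x`,
#'   `coverage_ge_1x`.
#' @examples
#' capture_stats(rep(25, 100), on_target_reads = 6925841, read_length = 90)
#' @export
capture_stats <- function(depth_vector, on_target_reads, read_length) {
  if (length(depth_vector) == 0) {
    stop_paneldx("empty target: depth vector has length 0",
                 class = "paneldx_validation_error")
  }
  if (any(is.na(depth_vector)) || any(depth_vector < 0)) {
    stop_paneldx("depths must be non-negative and non-missing",
                 class = "paneldx_validation_error")
  }
  check_number(on_target_reads, "on_target_reads", lower = 0)
  check_number(read_length, "read_length", lower = 0)
  out <- tibble(
    on_target_reads = on_target_reads,
    read_length = read_length,
    on_target_bases = as.numeric(on_target_reads) * as.numeric(read_length),
    mean_depth = mean(depth_vector),
    fraction_ge_20x = coverage_at(depth_vector, 20),
    coverage_ge_1x = coverage_at(depth_vector, 1)
  )
  class(out) <- c("capture_stats", class(out))
  out
}

#' Fraction of target bases at or above a depth threshold
#'
#' Monotonically non-increasing in `threshold`.
#'
#' @param depth_vector Per-base depths.
#' @param threshold Depth cutoff (inclusive).
#' @return A proportion in \[0, 1\].
#' @export
coverage_at <- function(depth_vector, threshold) {
  check_number(threshold, "threshold", lower = 0)
  mean(depth_vector >= threshold)
}

#' Default coverage QC thresholds
#'
#' Defaults are anchored to the worst per-sample values a clinical panel run
#' is expected to clear: mean depth 77.43-fold, 90.34% of the target at
#' >= 20-fold, 99.4% of the target covered at all.
#'
#' @param mean_depth,fraction_ge_20x,coverage_ge_1x Minimum acceptable
#'   values (inclusive).
#' @return A named list.
#' @export
qc_thresholds <- function(mean_depth = 77.43, fraction_ge_20x = 0.9034,
                          coverage_ge_1x = 0.994) {
  list(mean_depth = mean_depth, fraction_ge_20x = fraction_ge_20x,
       coverage_ge_1x = coverage_ge_1x)
}

#' Gate capture statistics against QC thresholds
#'
#' Pure function: each thresholded metric gets a `"pass"` or `"warn"` flag,
#' with the offending value attached. Boundaries are inclusive — a value
#' exactly at its threshold passes.
#'
#' @param stats A [capture_stats()] row.
#' @param thresholds A list as from [qc_thresholds()].
#' @return A tibble: `metric`, `value`, `threshold`, `status`.
#' @export
qc_gate <- function(stats, thresholds = qc_thresholds()) {
  stopifnot(inherits(stats, "capture_stats"))
  metrics <- names(thresholds)
  tibble(
    metric = metrics,
    value = purrr::map_dbl(metrics, ~ stats[[.x]]),
    threshold = purrr::map_dbl(metrics, ~ thresholds[[.x]]),
  ) |>
    mutate(status = ifelse(.data$value >= .data$threshold, "pass", "warn"))
}

#' Read a per-base depth track
#'
#' Accepts samtools-depth-style TSV (`chrom`, `pos`, `depth`, no header) or
#' a single-column file of depths.
#'
#' @param path Path to the file.
#' @return A numeric vector of per-base depths.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) {
    stop_paneldx(sprintf("depth track not found: %s", path),
                 class = "paneldx_io_error")
  }
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  col <- if (ncol(df) >= 3) 3 else 1
  depths <- suppressWarnings(as.numeric(df[[col]]))
  if (any(is.na(depths))) {
    stop_paneldx("non-numeric depth values in depth track",
                 class = "paneldx_parse_error")
  }
  depths
}
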