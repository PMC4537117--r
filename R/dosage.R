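#' Per-exon dosage ratios against in-batch controls
#'
#' Normalizes a test sample's exon depths against normal control samples
#' from the same batch: each sample's exon depths are first divided by that
#' sample's median exon depth (removing library-size differences), then the
#' test sample's normalized depth at each exon is divided by the median
#' normalized depth of the controls at that exon. The resulting dosage
#' ratio has expectation copies/2: 1 for diploid exons, 1.5 for a
#' heterozygous duplication, 0.5 for a heterozygous (or hemizygous) loss.
#'
#' Medians, not means, are used at both normalization steps so that the
#' test sample's own event does not drag its reference level, and the
#' ratio vector is finally re-centered on its own median so that
#' copy-neutral exons sit exactly at 1 even though the event contributes
#' to the test sample's median depth. This assumes most exons are
#' copy-neutral, the usual regime for a germline diagnostic panel.
#'
#' @param dm A long depth matrix (e.g. from [simulate_depths()]): columns
#'   `gene`, `exon`, `sample`, `depth`, optionally `batch`, `chrom`,
#'   `start`, `end`.
#' @param test_sample The sample to interrogate.
#' @param controls Control sample names. Defaults to all other samples in
#'   the test sample's batch; supplying none (and none being available) is
#'   a configuration error naming the batch.
#' @return A tibble of class `"exon_ratios"`: one row per exon with
#'   `ratio` and `flag` (`"ok"`, or `"not_computed"` where the control
#'   median depth is zero). Attributes `test_sample` and `controls`.
#' @export
normalize_exon_ratios <- function(dm, test_sample, controls = NULL) {
  check_columns(dm, c("gene", "exon", "sample", "depth"), "depth matrix")
  dm <- as_tibble(dm)
  if (!test_sample %in% dm$sample) {
    stop_paneldx(sprintf("test sample '%s' not in depth matrix", test_sample),
                 class = "paneldx_config_error")
  }
  if (is.null(controls)) {
    if (!"batch" %in% names(dm)) {
      stop_paneldx("no controls given and no batch column to select them from",
                   class = "paneldx_config_error")
    }
    test_batch <- unique(dm$batch[dm$sample == test_sample])
    controls <- setdiff(unique(dm$sample[dm$batch %in% test_batch]),
                        test_sample)
    if (length(controls) == 0) {
      stop_paneldx(
        sprintf("no in-batch controls available for batch '%s'", test_batch),
        class = "paneldx_config_error")
    }
  }
  controls <- setdiff(controls, test_sample)
  if (length(controls) == 0 || !all(controls %in% dm$sample)) {
    stop_paneldx("need at least one control sample present in the matrix (excluding the test sample)",
                 class = "paneldx_config_error")
  }

  keep_cols <- intersect(c("gene", "exon", "chrom", "start", "end"), names(dm))
  wide <- dm |>
    filter(.data$sample %in% c(test_sample, controls)) |>
    select(dplyr::all_of(keep_cols), "sample", "depth") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "depth")

  test_depth <- wide[[test_sample]]
  if (all(test_depth == 0)) {
    stop_paneldx(sprintf("test sample '%s' has all-zero depths", test_sample),
                 class = "paneldx_validation_error")
  }
  norm_one <- function(d) d / median(d)
  test_norm <- norm_one(test_depth)
  ctrl_norm <- vapply(controls, function(s) norm_one(wide[[s]]),
                      numeric(nrow(wide)))
  ctrl_med <- apply(as.matrix(ctrl_norm), 1, median)

  ratio <- ifelse(ctrl_med > 0, test_norm / ctrl_med, NA_real_)
  # Final median re-centering: the test sample's own event shifts its
  # within-sample median a little, so the raw ratio of an unaffected exon is
  # not exactly 1. Dividing by the median ratio restores the diploid level
  # exactly as long as most exons are copy-neutral.
  ratio <- ratio / median(ratio, na.rm = TRUE)
  out <- wide |>
    select(dplyr::all_of(keep_cols)) |>
    mutate(
      ratio = ratio,
      flag = ifelse(ctrl_med > 0, "ok", "not_computed")
    )
  attr(out, "test_sample") <- test_sample
  attr(out, "controls") <- controls
  class(out) <- c("exon_ratios", class(out))
  out
}

# Maximal runs of indices whose value sits beyond `ext` on one side, with at
# least one index beyond `main`. NA breaks runs. Returns list of index
# vectors.
find_runs <- function(r, main, ext, direction) {
  beyond <- function(x, thr) {
    !is.na(x) & if (direction == "gain") x >= thr else x <= thr
  }
  in_run <- beyond(r, ext)
  if (!any(in_run)) return(list())
  rl <- rle(in_run)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  runs <- purrr::map2(starts[rl$values], ends[rl$values], seq)
  purrr::keep(runs, ~ any(beyond(r[.x], main)))
}

#' Call exon-level copy-number variants from dosage ratios
#'
#' Within each gene, maximal runs of consecutive exons beyond a threshold
#' become one call. A run is seeded by at least one exon at or beyond the
#' main threshold (`gain_threshold` / `loss_threshold`); contiguous exons
#' beyond the midway extension threshold (halfway between 1 and the main
#' threshold) join the run, so a multi-exon event is not fragmented by one
#' exon fluctuating across the main threshold. The call's `observed_ratio`
#' is the median ratio of the run and `expected_copies = round(2 * ratio)`.
#'
#' Default thresholds 1.35 / 0.65 sit midway between the diploid
#' expectation (1.0) and the heterozygous-event expectations (1.5 / 0.5).
#'
#' @param ratios An `"exon_ratios"` tibble from [normalize_exon_ratios()]
#'   (or any tibble with `gene`, `exon`, `ratio`). Exons must be in
#'   genomic order within each gene. `NA` ratios break runs.
#' @param gain_threshold,loss_threshold Main calling thresholds
#'   (`0 < loss < 1 < gain`).
#' @param min_run Minimum number of exons per call (default 1; single-exon
#'   calls are flagged `single_unit_call`).
#' @return A tibble of class `"dosage_calls"`: `gene`, `exon_first`,
#'   `exon_last`, `n_units`, `observed_ratio`, `expected_copies`,
#'   `classification`, `single_unit_call`, plus `chrom`/`start`/`end`
#'   spanning the run when coordinates are available. Empty ratio input
#'   yields an empty call list.
#' @export
call_exon_cnv <- function(ratios, gain_threshold = 1.35,
                          loss_threshold = 0.65, min_run = 1) {
  check_columns(ratios, c("gene", "exon", "ratio"), "ratio table")
  if (!(loss_threshold > 0 && loss_threshold < 1 && gain_threshold > 1)) {
    stop_paneldx("thresholds must satisfy 0 < loss < 1 < gain",
                 class = "paneldx_validation_error")
  }
  gain_ext <- (1 + gain_threshold) / 2
  loss_ext <- (1 + loss_threshold) / 2
  has_coord <- all(c("chrom", "start", "end") %in% names(ratios))

  empty <- tibble(
    gene = character(), exon_first = character(), exon_last = character(),
    n_units = integer(), observed_ratio = double(),
    expected_copies = double(), classification = character(),
    single_unit_call = logical()
  )
  if (nrow(ratios) == 0) {
    class(empty) <- c("dosage_calls", class(empty))
    return(empty)
  }

  calls <- ratios |>
    as_tibble() |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(gdf) {
      r <- gdf$ratio
      runs <- c(
        purrr::map(find_runs(r, gain_threshold, gain_ext, "gain"),
                   ~ list(idx = .x, cls = "gain")),
        purrr::map(find_runs(r, loss_threshold, loss_ext, "loss"),
                   ~ list(idx = .x, cls = "loss"))
      )
      bind_rows(purrr::map(runs, function(run) {
        idx <- run$idx
        med <- median(r[idx])
        out <- tibble(
          gene = gdf$gene[1],
          exon_first = gdf$exon[idx[1]],
          exon_last = gdf$exon[idx[length(idx)]],
          n_units = length(idx),
          observed_ratio = med,
          expected_copies = round_half_up(2 * med),
          classification = run$cls,
          single_unit_call = length(idx) == 1
        )
        if (has_coord) {
          out$chrom <- gdf$chrom[idx[1]]
          out$start <- min(gdf$start[idx])
          out$end <- max(gdf$end[idx])
        }
        out
      }))
    }) |>
    bind_rows()
  if (nrow(calls) == 0) calls <- empty
  calls <- filter(calls, .data$n_units >= min_run)
  class(calls) <- c("dosage_calls", class(calls))
  calls
}

#' Chromosome-level dosage analysis from on-target read counts
#'
#' Each chromosome's count is first turned into a share of the sample's
#' autosomal total, then divided by the median share of the reference
#' samples (whose autosomes are assumed diploid), and the resulting ratio
#' vector is re-centered on its autosomal median. The re-centering undoes
#' the damping an aneuploidy exerts on every share through the total, so a
#' trisomy sits exactly at 1.5, a monosomy at 0.5 and unaffected
#' chromosomes at 1.0 — provided most autosomes are euploid, the plausible
#' regime for a diagnostic sample.
#'
#' @param cc A `"chrom_counts"` tibble (`sample`, `chrom`, `count`).
#' @param test_sample Sample to interrogate.
#' @param reference_samples At least one reference sample.
#' @param gain_threshold,loss_threshold Call thresholds on the ratio.
#' @return A tibble of class `"chrom_dosage"`: `chrom`, `observed_ratio`,
#'   `expected_copies`, `classification` (`gain`/`loss`/`normal`, or
#'   `not_computed` where the reference statistic is zero, e.g. chrY
#'   against female references).
#' @export
chrom_dosage <- function(cc, test_sample, reference_samples,
                         gain_threshold = 1.35, loss_threshold = 0.65) {
  check_columns(cc, c("sample", "chrom", "count"), "chromosome counts")
  cc <- as_tibble(cc)
  reference_samples <- setdiff(reference_samples, test_sample)
  if (length(reference_samples) == 0 ||
      !all(c(test_sample, reference_samples) %in% cc$sample)) {
    stop_paneldx("need a test sample and >= 1 distinct reference sample, all present in the counts",
                 class = "paneldx_config_error")
  }
  if (any(cc$count < 0)) {
    stop_paneldx("negative read counts", class = "paneldx_validation_error")
  }

  wide <- cc |>
    filter(.data$sample %in% c(test_sample, reference_samples)) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0)
  chroms <- wide$chrom
  auto <- is_autosome(chroms)

  norm_stat <- function(counts) {
    auto_total <- sum(counts[auto])
    if (auto_total <= 0) {
      stop_paneldx("zero autosomal total in a sample's chromosome counts",
                   class = "paneldx_validation_error")
    }
    counts / auto_total
  }
  test_stat <- norm_stat(wide[[test_sample]])
  ref_stat <- vapply(reference_samples, function(s) norm_stat(wide[[s]]),
                     numeric(length(chroms)))
  ref_med <- apply(as.matrix(ref_stat), 1, median)

  ratio <- ifelse(ref_med > 0, test_stat / ref_med, NA_real_)
  # re-center on the autosomal median so an aneuploidy's effect on the
  # sample total does not bias every other chromosome's ratio
  ratio <- ratio / median(ratio[auto], na.rm = TRUE)
  out <- tibble(
    chrom = chroms,
    observed_ratio = ratio
  ) |>
    mutate(
      expected_copies = round_half_up(2 * .data$observed_ratio),
      classification = case_when(
        is.na(.data$observed_ratio) ~ "not_computed",
        .data$observed_ratio >= gain_threshold ~ "gain",
        .data$observed_ratio <= loss_threshold ~ "loss",
        TRUE ~ "normal"
      )
    )
  class(out) <- c("chrom_dosage", class(out))
  out
}

#' Segmental dosage analysis over binned counts of one chromosome
#'
#' Per-bin dosage ratios are computed exactly like exon ratios (within-
#' sample median normalization, then division by the median normalized
#' value of the references), and maximal runs of bins beyond a threshold
#' are reported as one call whose genomic interval is the union of the run
#' bins. Suitable for megabase-scale microdeletions/microduplications.
#'
#' @param binned Tibble of bin counts tiling one chromosome's on-target
#'   footprint: `chrom`, `start`, `end`, `sample`, `count`.
#' @param test_sample,reference_samples As in [chrom_dosage()].
#' @param gain_threshold,loss_threshold Call thresholds.
#' @param min_run Minimum bins per call.
#' @return A tibble of class `"dosage_calls"` with `chrom`, `start`, `end`
#'   of each called segment, `n_units` (bins), `observed_ratio`,
#'   `expected_copies`, `classification`.
#' @export
segment_dosage <- function(binned, test_sample, reference_samples,
                           gain_threshold = 1.35, loss_threshold = 0.65,
                           min_run = 1) {
  check_columns(binned, c("chrom", "start", "end", "sample", "count"),
                "binned counts")
  if (nrow(binned) == 0) {
    stop_paneldx("bins do not cover any target",
                 class = "paneldx_validation_error")
  }
  dm <- binned |>
    mutate(gene = .data$chrom,
           exon = paste0("bin", format(.data$start, scientific = FALSE,
                                       trim = TRUE)),
           depth = .data$count)
  ratios <- normalize_exon_ratios(dm, test_sample, reference_samples)
  calls <- call_exon_cnv(ratios, gain_threshold, loss_threshold, min_run)
  if (nrow(calls) == 0) {
    out <- tibble(chrom = character(), start = double(), end = double(),
                  n_units = integer(), observed_ratio = double(),
                  expected_copies = double(), classification = character(),
                  single_unit_call = logical())
    class(out) <- c("dosage_calls", class(out))
    return(out)
  }
  calls |>
    select(-"gene", -"exon_first", -"exon_last") |>
    select("chrom", "start", "end", dplyr::everything())
}

#' Infer sample sex from sex-chromosome dosage
#'
#' Compares each sample's X (and, when targeted, Y) read-count share
#' against the share expected from the panel footprint for an XX karyotype.
#' `x_dose` is ~1 for females and ~0.5 for males; `y_dose` is the Y share
#' relative to a single-copy expectation (~1 male, ~0 female). Samples
#' whose X dosage falls between the decision bands are `undetermined`.
#'
#' @param cc A `"chrom_counts"` tibble.
#' @param p The [panel()] the counts were produced against (must contain
#'   X-chromosome targets).
#' @param female_min Minimum `x_dose` to call female (default 0.8).
#' @param male_max Maximum `x_dose` to call male (default 0.65).
#' @return A tibble: `sample`, `x_dose`, `y_dose`, `sex` (`"female"`,
#'   `"male"` or `"undetermined"`).
#' @export
infer_sex <- function(cc, p, female_min = 0.8, male_max = 0.65) {
  check_columns(cc, c("sample", "chrom", "count"), "chromosome counts")
  fp <- panel_footprint(p)
  if (!"chrX" %in% fp$chrom) {
    stop_paneldx("panel contains no X-chromosome targets",
                 class = "paneldx_config_error")
  }
  fx <- fp$footprint[fp$chrom == "chrX"]
  fy <- if ("chrY" %in% fp$chrom) fp$footprint[fp$chrom == "chrY"] else NA
  fa <- sum(fp$footprint[is_autosome(fp$chrom)])

  cc |>
    as_tibble() |>
    group_by(.data$sample) |>
    summarise(
      auto_total = sum(.data$count[is_autosome(.data$chrom)]),
      x_count = sum(.data$count[.data$chrom == "chrX"]),
      y_count = sum(.data$count[.data$chrom == "chrY"]),
      .groups = "drop"
    ) |>
    mutate(
      x_dose = (.data$x_count / .data$auto_total) / (fx / fa),
      y_dose = if (is.na(fy)) NA_real_ else
        (.data$y_count / .data$auto_total) / (0.5 * fy / fa),
      sex = case_when(
        .data$x_dose >= female_min &
          (is.na(.data$y_dose) | .data$y_dose < 0.5) ~ "female",
        .data$x_dose <= male_max &
          (is.na(.data$y_dose) | .data$y_dose >= 0.5) ~ "male",
        TRUE ~ "undetermined"
      )
    ) |>
    select("sample", "x_dose", "y_dose", "sex")
}

#' Expected dosage ratio for a copy number
#'
#' The expectation a confirmatory quantitative PCR should observe: copy
#' number divided by the baseline ploidy (2 for autosomes, 1 for male sex
#' chromosomes). A heterozygous duplication (3 copies) gives 1.5, a
#' heterozygous deletion (1 copy) gives 0.5.
#'
#' @param copies Non-negative integer copy number.
#' @param baseline_ploidy Baseline copy number (default 2).
#' @return `copies / baseline_ploidy`.
#' @export
expected_copy_ratio <- function(copies, baseline_ploidy = 2) {
  if (any(copies < 0) || any(is.na(copies))) {
    stop_paneldx("copies must be non-negative",
                 class = "paneldx_validation_error")
  }
  check_number(baseline_ploidy, "baseline_ploidy", lower = 1e-9)
  copies / baseline_ploidy
}
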