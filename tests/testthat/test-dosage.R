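ratio_tbl <- function(r, gene = "G") {
  tibble::tibble(gene = gene, exon = paste0("E", seq_along(r)), ratio = r)
}

test_that("a test sample identical to its controls has ratio 1 everywhere", {
  p <- small_panel(10, 5)
  dm <- simulate_depths(p, simulation_spec(seed = 4, noise_free = TRUE))
  r <- normalize_exon_ratios(dm, "S1")
  expect_equal(r$ratio, rep(1, nrow(r)))
})

test_that("noise-free events produce exact ratios and exact call boundaries", {
  p <- small_panel(20, 6)
  ev <- rbind(
    dosage_event("exon_run", sample = "S1", copies = 3, gene = "GENE004",
                 exons = paste0("CDS", 1:4)),
    dosage_event("exon_run", sample = "S1", copies = 1, gene = "GENE010",
                 exons = "CDS3")
  )
  dm <- simulate_depths(p, simulation_spec(seed = 6, noise_free = TRUE,
                                           events = ev))
  r <- normalize_exon_ratios(dm, "S1")
  dup <- dplyr::filter(r, gene == "GENE004", exon %in% paste0("CDS", 1:4))
  expect_equal(dup$ratio, rep(1.5, 4))
  hemi <- dplyr::filter(r, gene == "GENE010", exon == "CDS3")
  expect_equal(hemi$ratio, 0.5)

  calls <- call_exon_cnv(r)
  expect_equal(nrow(calls), 2)
  gain <- dplyr::filter(calls, classification == "gain")
  expect_equal(gain$gene, "GENE004")
  expect_equal(c(gain$exon_first, gain$exon_last), c("CDS1", "CDS4"))
  expect_equal(gain$n_units, 4)
  expect_equal(gain$expected_copies, 3)
  loss <- dplyr::filter(calls, classification == "loss")
  expect_equal(loss$gene, "GENE010")
  expect_equal(loss$expected_copies, 1)
  expect_true(loss$single_unit_call)
})

test_that("ratios are invariant to global per-sample depth scaling", {
  p <- small_panel(10, 5)
  dm <- simulate_depths(p, simulation_spec(seed = 12))
  r1 <- normalize_exon_ratios(dm, "S1")
  dm2 <- dplyr::mutate(dm, depth = ifelse(sample == "C2", depth * 7, depth))
  r2 <- normalize_exon_ratios(dm2, "S1")
  expect_equal(r1$ratio, r2$ratio)
  dm3 <- dplyr::mutate(dm, depth = ifelse(sample == "S1", depth * 0.3, depth))
  r3 <- normalize_exon_ratios(dm3, "S1")
  expect_equal(r1$ratio, r3$ratio)
})

test_that("control selection honours batches and fails without controls", {
  p <- small_panel(5, 4)
  dm <- simulate_depths(p, simulation_spec(seed = 13),
                        samples = c("S1", "C1", "C2", "X1"),
                        batch = c("B1", "B1", "B1", "B2"))
  r <- normalize_exon_ratios(dm, "S1")
  expect_setequal(attr(r, "controls"), c("C1", "C2"))

  expect_error(normalize_exon_ratios(dm, "X1"), "B2",
               class = "paneldx_config_error")
  # zero-depth control exons are flagged, not silently divided
  dm0 <- dplyr::mutate(dm, depth = ifelse(sample %in% c("C1", "C2") &
                                            gene == "GENE001" & exon == "CDS1",
                                          0, depth))
  r0 <- normalize_exon_ratios(dm0, "S1")
  flagged <- dplyr::filter(r0, gene == "GENE001", exon == "CDS1")
  expect_equal(flagged$flag, "not_computed")
  expect_true(is.na(flagged$ratio))
})

test_that("run calling matches a brute-force oracle on discrete ratio vectors", {
  # independent oracle: on the alphabet {0.5, 1, 1.5}, calls are exactly the
  # maximal runs of 1.5 (gain, 3 copies) and 0.5 (loss, 1 copy)
  oracle <- function(r, gene) {
    rl <- rle(r)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    keep <- rl$values != 1
    tibble::tibble(
      gene = rep(gene, sum(keep)),
      exon_first = paste0("E", starts[keep]),
      exon_last = paste0("E", ends[keep]),
      classification = as.character(ifelse(rl$values[keep] > 1, "gain",
                                           "loss")),
      expected_copies = as.numeric(ifelse(rl$values[keep] > 1, 3, 1))
    )
  }
  alphabet <- c(0.5, 1, 1.5)
  for (len in 1:8) {
    grid <- as.matrix(expand.grid(rep(list(alphabet), len)))
    genes <- sprintf("V%05d", seq_len(nrow(grid)))
    # every vector is its own gene: one batched call over all 3^len vectors
    ratios <- tibble::tibble(
      gene = rep(genes, each = len),
      exon = rep(paste0("E", seq_len(len)), times = nrow(grid)),
      ratio = as.vector(t(grid))
    )
    got <- call_exon_cnv(ratios) |>
      dplyr::select(gene, exon_first, exon_last, classification,
                    expected_copies) |>
      dplyr::arrange(gene, exon_first, classification)
    want <- dplyr::bind_rows(
      purrr::map(seq_len(nrow(grid)),
                 ~ oracle(unname(grid[.x, ]), genes[.x]))) |>
      dplyr::arrange(gene, exon_first, classification)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("flat or empty ratio vectors yield no calls", {
  expect_equal(nrow(call_exon_cnv(ratio_tbl(rep(1, 6)))), 0)
  expect_equal(nrow(call_exon_cnv(ratio_tbl(numeric(0)))), 0)
  expect_error(call_exon_cnv(ratio_tbl(1), gain_threshold = 0.9),
               class = "paneldx_validation_error")
})

test_that("the published 4-exon ratio profile is called as a 3-copy gain", {
  r <- ratio_tbl(c(1.4965, 1.5674, 1.5513, 1.5306), gene = "PMP22")
  calls <- call_exon_cnv(r)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$classification, "gain")
  expect_equal(calls$n_units, 4)
  expect_equal(calls$expected_copies, 3)
})

test_that("chromosome dosage is exactly 1.5 for a noise-free trisomy", {
  p <- small_panel(48, 4)
  ev <- dosage_event("chromosome", sample = "T1", copies = 3, chrom = "chr9")
  spec <- simulation_spec(seed = 8, noise_free = TRUE, events = ev)
  cc <- simulate_chrom_counts(p, spec, sex = c(T1 = "female", R1 = "female",
                                               R2 = "female", R3 = "female"))
  cd <- chrom_dosage(cc, "T1", c("R1", "R2", "R3"))
  expect_equal(cd$observed_ratio[cd$chrom == "chr9"], 1.5)
  expect_equal(cd$classification[cd$chrom == "chr9"], "gain")
  auto_other <- dplyr::filter(cd, chrom != "chr9", chrom != "chrY")
  expect_equal(auto_other$observed_ratio, rep(1, nrow(auto_other)))

  # a reference against the remaining references is flat
  cd_ref <- chrom_dosage(cc, "R1", c("R2", "R3"))
  expect_equal(dplyr::filter(cd_ref, chrom != "chrY")$observed_ratio,
               rep(1, 23))
})

test_that("multinomial trisomy ratios concentrate near 1.5 at realistic depth", {
  p <- small_panel(48, 4)
  ratios <- purrr::map_dbl(1:20, function(s) {
    ev <- dosage_event("chromosome", sample = "T1", copies = 3,
                       chrom = "chr9")
    spec <- simulation_spec(seed = s, events = ev, total_reads = 7e6)
    cc <- simulate_chrom_counts(
      p, spec, sex = c(T1 = "female", R1 = "female", R2 = "female",
                       R3 = "female"))
    cd <- chrom_dosage(cc, "T1", c("R1", "R2", "R3"))
    cd$observed_ratio[cd$chrom == "chr9"]
  })
  expect_true(all(ratios >= 1.35 & ratios <= 1.65))
})

test_that("segment dosage recovers an injected microdeletion interval", {
  # binned counts over a chromosome-17-like footprint: 24 bins, a 3.4 Mb
  # heterozygous deletion spanning bins 9-16 inclusive
  bin_size <- 425e3
  n_bins <- 24
  starts <- 16773072 - 8 * bin_size + (seq_len(n_bins) - 1) * bin_size
  del_bins <- 9:16
  build <- function(sample, affected, mu = 5000, noise = FALSE, seed = 1) {
    mult <- rep(1, n_bins)
    if (affected) mult[del_bins] <- 0.5
    count <- if (noise) {
      set.seed(seed); rpois(n_bins, mu * mult)
    } else mu * mult
    tibble::tibble(chrom = "chr17", start = starts,
                   end = starts + bin_size, sample = sample, count = count)
  }
  binned <- rbind(build("T1", TRUE), build("R1", FALSE), build("R2", FALSE),
                  build("R3", FALSE))
  calls <- segment_dosage(binned, "T1", c("R1", "R2", "R3"))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$classification, "loss")
  expect_equal(calls$observed_ratio, 0.5)
  expect_equal(calls$n_units, 8)
  expect_equal(calls$start, starts[9])
  expect_equal(calls$end, starts[16] + bin_size)

  # no event -> empty list
  quiet <- rbind(build("T1", FALSE), build("R1", FALSE), build("R2", FALSE))
  expect_equal(nrow(segment_dosage(quiet, "T1", c("R1", "R2"))), 0)

  # with Poisson noise the called interval still overlaps the truth well
  noisy <- rbind(build("T1", TRUE, noise = TRUE, seed = 11),
                 build("R1", FALSE, noise = TRUE, seed = 12),
                 build("R2", FALSE, noise = TRUE, seed = 13),
                 build("R3", FALSE, noise = TRUE, seed = 14))
  ncalls <- segment_dosage(noisy, "T1", c("R1", "R2", "R3"))
  loss <- dplyr::filter(ncalls, classification == "loss")
  expect_equal(nrow(loss), 1)
  truth <- c(starts[9], starts[16] + bin_size)
  inter <- min(loss$end, truth[2]) - max(loss$start, truth[1])
  union <- max(loss$end, truth[2]) - min(loss$start, truth[1])
  expect_gte(inter / union, 0.9)
})

test_that("sex inference separates XX, XY and ambiguous dosage", {
  p <- small_panel(48, 4)
  cc <- simulate_chrom_counts(p, simulation_spec(seed = 9, noise_free = TRUE),
                              sex = c(F1 = "female", M1 = "male"))
  sx <- infer_sex(cc, p)
  expect_equal(sx$sex[sx$sample == "F1"], "female")
  expect_equal(sx$sex[sx$sample == "M1"], "male")

  # X dosage midway between the profiles, no Y signal -> undetermined
  mid <- dplyr::mutate(
    dplyr::filter(cc, sample == "F1"),
    count = ifelse(chrom == "chrX", 0.75 * count, count),
    sample = "A1")
  expect_equal(infer_sex(mid, p)$sex, "undetermined")

  p_nox <- panel(dplyr::filter(tibble::as_tibble(p), chrom != "chrX"))
  expect_error(infer_sex(cc, p_nox), class = "paneldx_config_error")
})

test_that("expected copy ratio is copies over baseline ploidy", {
  expect_equal(expected_copy_ratio(3), 1.5)
  expect_equal(expected_copy_ratio(2), 1)
  expect_equal(expected_copy_ratio(1), 0.5)
  expect_equal(expected_copy_ratio(0), 0)
  expect_equal(expected_copy_ratio(1, baseline_ploidy = 1), 1)
  expect_error(expected_copy_ratio(-1), class = "paneldx_validation_error")
})

test_that("stochastic 4-exon duplications are recovered at 80-fold depth", {
  p <- small_panel(30, 6)
  hits <- purrr::map_lgl(1:100, function(s) {
    ev <- dosage_event("exon_run", sample = "S1", copies = 3,
                       gene = "GENE005", exons = paste0("CDS", 1:4))
    dm <- simulate_depths(p, simulation_spec(seed = s, events = ev))
    calls <- call_exon_cnv(normalize_exon_ratios(dm, "S1"))
    any(calls$gene == "GENE005" & calls$classification == "gain" &
          calls$expected_copies == 3)
  })
  expect_gte(sum(hits), 95)
})
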