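# TSV readers/writers for the tabular interchange formats: depth matrices
# (rows = exons, columns = samples), chromosome counts and genotype tables.
# All text is UTF-8 with LF line endings.

#' Read a per-exon depth matrix
#'
#' Wide TSV: metadata columns `gene`, `exon` (optionally `chrom`, `start`,
#' `end`) followed by one numeric column per sample. An optional
#' `#batch:` header line of the form `#batch: SAMPLE=B1 SAMPLE2=B1 ...`
#' assigns batches; otherwise all samples share batch `"B1"`.
#'
#' @param path Path to the TSV.
#' @return A long tibble of class `"depth_matrix"` (`gene`, `exon`, ...,
#'   `sample`, `batch`, `depth`).
#' @export
read_depth_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_paneldx(sprintf("depth matrix not found: %s", path),
                 class = "paneldx_io_error")
  }
  first <- readLines(path, n = 1)
  batches <- NULL
  if (startsWith(first, "#batch:")) {
    kv <- strsplit(trimws(sub("^#batch:", "", first)), "\\s+")[[1]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    batches <- setNames(purrr::map_chr(parts, 2), purrr::map_chr(parts, 1))
  }
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  check_columns(df, c("gene", "exon"), "depth matrix")
  meta <- intersect(c("gene", "exon", "chrom", "start", "end"), names(df))
  out <- tidyr::pivot_longer(df, cols = -dplyr::all_of(meta),
                             names_to = "sample", values_to = "depth") |>
    mutate(batch = unname((batches %||% character())[.data$sample]) |>
             (\(b) ifelse(is.na(b), "B1", b))())
  if (any(is.na(out$depth)) || any(out$depth < 0)) {
    stop_paneldx("depth matrix contains missing or negative depths",
                 class = "paneldx_validation_error")
  }
  class(out) <- c("depth_matrix", class(out))
  out
}

#' Write a long depth matrix as wide TSV
#'
#' @param dm Long depth matrix (as from [simulate_depths()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_matrix <- function(dm, path) {
  check_columns(dm, c("gene", "exon", "sample", "depth"), "depth matrix")
  meta <- intersect(c("gene", "exon", "chrom", "start", "end"), names(dm))
  wide <- tidyr::pivot_wider(as_tibble(dm),
                             id_cols = dplyr::all_of(meta),
                             names_from = "sample", values_from = "depth")
  header <- NULL
  if ("batch" %in% names(dm)) {
    sb <- distinct(as_tibble(dm), .data$sample, .data$batch)
    header <- paste0("#batch: ",
                     paste(sprintf("%s=%s", sb$sample, sb$batch),
                           collapse = " "))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  readr::write_tsv(wide, con)
  invisible(path)
}

#' Read per-chromosome on-target read counts
#'
#' Wide TSV: column `chrom` plus one numeric column per sample.
#'
#' @param path Path to the TSV.
#' @return A long tibble of class `"chrom_counts"` (`sample`, `chrom`,
#'   `count`).
#' @export
read_chrom_counts <- function(path) {
  df <- readr::read_tsv(path, comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  check_columns(df, "chrom", "chromosome counts")
  out <- tidyr::pivot_longer(df, cols = -"chrom", names_to = "sample",
                             values_to = "count") |>
    select("sample", "chrom", "count")
  if (any(out$count < 0, na.rm = TRUE)) {
    stop_paneldx("negative read counts", class = "paneldx_validation_error")
  }
  class(out) <- c("chrom_counts", class(out))
  out
}

#' Write chromosome counts as wide TSV
#'
#' @param cc Long counts (as from [simulate_chrom_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_counts <- function(cc, path) {
  check_columns(cc, c("sample", "chrom", "count"), "chromosome counts")
  wide <- tidyr::pivot_wider(as_tibble(cc), id_cols = "chrom",
                             names_from = "sample", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a genotype table
#'
#' TSV with header columns `sample`, `chrom`, `pos`, `genotype`
#' (`rsid` optional); genotypes as `"A/B"` pairs or single alleles for
#' hemizygous loci.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_genotype_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, c("sample", "chrom", "pos", "genotype"),
                "genotype table")
  mutate(df, pos = as.numeric(.data$pos))
}
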