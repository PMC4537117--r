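#' Construct a capture-panel object
#'
#' A panel is the target-region universe of a diagnostic capture design: one
#' row per targeted exon (or other region), addressed by chromosome, 0-based
#' half-open coordinates, gene symbol and an exon label such as `"CDS1"`.
#' Depth matrices, chromosome read counts and variant calls are all
#' interpreted against a panel.
#'
#' @param regions A data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `exon`. Coordinates are 0-based half-open (BED convention).
#' @return A tibble of class `"panel"`, sorted by (chrom, start).
#' @examples
#' p <- panel(tibble::tibble(
#'   chrom = "chr1", start = c(0, 200), end = c(100, 350),
#'   gene = "GENE1", exon = c("CDS1", "CDS2")
#' ))
#' panel_total_size(p)
#' @export
panel <- function(regions) {
  regions <- as_tibble(regions)
  check_columns(regions, c("chrom", "start", "end", "gene", "exon"), "panel")
  if (nrow(regions) == 0) {
    stop_paneldx("a panel must contain at least one target region",
                 class = "paneldx_validation_error")
  }
  bad <- which(!(regions$start >= 0 & regions$start < regions$end))
  if (length(bad) > 0) {
    stop_paneldx(
      sprintf("target region(s) with start >= end or negative start at row(s): %s",
              paste(head(bad, 5), collapse = ", ")),
      class = "paneldx_validation_error"
    )
  }
  regions$chrom <- normalize_chrom(regions$chrom)
  dup <- regions |>
    dplyr::count(.data$gene, .data$exon) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_paneldx(
      sprintf("exon labels must be unique within a gene; duplicated: %s",
              paste(paste0(dup$gene, "/", dup$exon), collapse = ", ")),
      class = "paneldx_validation_error"
    )
  }
  out <- arrange(regions, .data$chrom, .data$start)
  class(out) <- c("panel", class(tibble()))
  out
}

panel_granges <- function(p) {
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end)
  )
}

#' Total target size of a panel
#'
#' The number of distinct targeted bases: region lengths are summed after
#' merging overlapping regions, so the result is invariant under permutation
#' or double-listing of input lines.
#'
#' @param p A [panel()].
#' @return Integer number of bases.
#' @export
panel_total_size <- function(p) {
  stopifnot(inherits(p, "panel"))
  sum(GenomicRanges::width(GenomicRanges::reduce(panel_granges(p))))
}

#' Per-chromosome on-target footprint
#'
#' @param p A [panel()].
#' @return A tibble with columns `chrom` and `footprint` (merged bases).
#' @export
panel_footprint <- function(p) {
  stopifnot(inherits(p, "panel"))
  gr <- GenomicRanges::reduce(panel_granges(p))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    width = GenomicRanges::width(gr)
  ) |>
    group_by(.data$chrom) |>
    summarise(footprint = sum(.data$width), .groups = "drop")
}

#' @export
glance.panel <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_genes = dplyr::n_distinct(x$gene),
    n_chromosomes = dplyr::n_distinct(x$chrom),
    total_size = panel_total_size(x)
  )
}

#' @export
print.panel <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<panel> %d regions, %d genes, %d chromosomes, %s targeted bases\n",
    g$n_regions, g$n_genes, g$n_chromosomes,
    format(g$total_size, big.mark = ",")
  ))
  NextMethod()
}

#' Read a capture panel from a BED file
#'
#' Expects at least four tab-separated columns: chromosome, 0-based start,
#' end, and a name field of the form `"GENE|EXONLABEL"`. Lines starting with
#' `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @return A [panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    stop_paneldx(sprintf("panel file not found: %s", path),
                 class = "paneldx_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- purrr::map2(fields, idx, function(f, i) {
    if (length(f) < 4) {
      stop_paneldx(sprintf("line %d: expected >= 4 tab-separated fields, got %d",
                           i, length(f)),
                   class = "paneldx_parse_error")
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_paneldx(sprintf("line %d: non-numeric coordinates '%s', '%s'",
                           i, f[2], f[3]),
                   class = "paneldx_parse_error")
    }
    if (start >= end) {
      stop_paneldx(sprintf("line %d: start (%d) must be < end (%d)",
                           i, start, end),
                   class = "paneldx_validation_error")
    }
    name <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    if (length(name) != 2 || !nzchar(name[1]) || !nzchar(name[2])) {
      stop_paneldx(sprintf("line %d: name field must be 'GENE|EXONLABEL', got '%s'",
                           i, f[4]),
                   class = "paneldx_parse_error")
    }
    tibble(chrom = f[1], start = start, end = end,
           gene = name[1], exon = name[2])
  })
  panel(bind_rows(rows))
}

#' Write a panel as a BED file
#'
#' Inverse of [read_panel()]: 4-column BED with the name field
#' `"GENE|EXONLABEL"`, UTF-8, LF line endings.
#'
#' @param p A [panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  stopifnot(inherits(p, "panel"))
  lines <- sprintf("%s\t%d\t%d\t%s|%s", p$chrom, p$start, p$end, p$gene, p$exon)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
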