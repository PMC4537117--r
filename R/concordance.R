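#' Genotype concordance between sequencing and array platforms
#'
#' Compares genotypes at shared loci per sample. Genotypes are normalized
#' as unordered allele pairs before comparison, so `"A/G"` and `"G/A"`
#' agree. Loci present on only one platform are excluded from the
#' denominator and reported separately — the comparison is over shared
#' selected loci. Percentages are computed exactly and rounded (half away
#' from zero) to 2 decimals at presentation; the mean is taken over the
#' unrounded per-sample values and rounded last.
#'
#' @param pairs A tibble with columns `sample`, `chrom`, `pos`, `ngs`,
#'   `array`; `NA` in either genotype marks a locus missing on that
#'   platform.
#' @return An object of class `"concordance_summary"`: `per_sample`
#'   (tibble: `sample`, `n_total`, `n_concordant`, `percent`),
#'   `mean_percent`, `discordant` (loci with both genotypes) and
#'   `unshared` (loci dropped from the denominator).
#' @export
genotype_concordance <- function(pairs) {
  check_columns(pairs, c("sample", "chrom", "pos", "ngs", "array"),
                "genotype pairs")
  pairs <- as_tibble(pairs)
  norm_gt <- function(g) {
    purrr::map_chr(g, function(x) {
      if (is.na(x)) return(NA_character_)
      paste(sort(strsplit(x, "/", fixed = TRUE)[[1]]), collapse = "/")
    })
  }
  pairs <- mutate(pairs, ngs = norm_gt(.data$ngs), array = norm_gt(.data$array))
  unshared <- filter(pairs, is.na(.data$ngs) != is.na(.data$array))
  shared <- filter(pairs, !is.na(.data$ngs) & !is.na(.data$array))
  per_sample <- shared |>
    group_by(.data$sample) |>
    summarise(
      n_total = n(),
      n_concordant = sum(.data$ngs == .data$array),
      .groups = "drop"
    ) |>
    mutate(
      percent_exact = 100 * .data$n_concordant / .data$n_total,
      percent = round_half_up(.data$percent_exact, 2)
    )
  discordant <- filter(shared, .data$ngs != .data$array)
  structure(
    list(
      per_sample = per_sample,
      mean_percent = round_half_up(mean(per_sample$percent_exact), 2),
      discordant = discordant,
      unshared = unshared
    ),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>\n")
  for (i in seq_len(nrow(x$per_sample))) {
    r <- x$per_sample[i, ]
    cat(sprintf("  %s: %.2f%% (%d/%d)\n", r$sample, r$percent,
                r$n_concordant, r$n_total))
  }
  cat(sprintf("  mean: %.2f%%; %d discordant, %d unshared loci\n",
              x$mean_percent, nrow(x$discordant), nrow(x$unshared)))
  invisible(x)
}

#' @export
tidy.concordance_summary <- function(x, ...) {
  select(x$per_sample, "sample", "n_total", "n_concordant", "percent")
}

#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(n_samples = nrow(x$per_sample),
         mean_percent = x$mean_percent,
         n_discordant = nrow(x$discordant),
         n_unshared = nrow(x$unshared))
}

#' Replicate SNV stability (k-way Venn overlap)
#'
#' Intersects k replicate sets of coding-SNV keys and reports, per
#' replicate, the proportion of its SNVs present in all replicates. The
#' mean is taken over the unrounded proportions and rounded (half away
#' from zero) to 2 decimals last.
#'
#' @param snv_sets A list (k >= 2) of character vectors of SNV keys
#'   (conventionally `"chrom:pos:ref:alt"`).
#' @return An object of class `"stability_summary"`: `per_replicate`
#'   (tibble: `replicate`, `n_total`, `percent`), `n_intersection`,
#'   `mean_percent`.
#' @export
replicate_overlap <- function(snv_sets) {
  if (!is.list(snv_sets) || length(snv_sets) < 2) {
    stop_paneldx("need at least two replicate SNV sets",
                 class = "paneldx_validation_error")
  }
  sets <- purrr::map(snv_sets, unique)
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    stop_paneldx("stability proportion undefined for an empty SNV set",
                 class = "paneldx_validation_error")
  }
  common <- Reduce(intersect, sets)
  nm <- names(sets) %||% paste0("rep", seq_along(sets))
  per <- tibble(
    replicate = nm,
    n_total = as.integer(unname(sizes)),
    percent_exact = 100 * length(common) / as.numeric(unname(sizes))
  ) |>
    mutate(percent = round_half_up(.data$percent_exact, 2))
  structure(
    list(per_replicate = select(per, "replicate", "n_total", "percent",
                                "percent_exact"),
         n_intersection = length(common),
         mean_percent = round_half_up(mean(per$percent_exact), 2)),
    class = "stability_summary"
  )
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("<stability_summary> %d replicates, %d shared SNVs\n",
              nrow(x$per_replicate), x$n_intersection))
  for (i in seq_len(nrow(x$per_replicate))) {
    r <- x$per_replicate[i, ]
    cat(sprintf("  %s: %.2f%% (%d/%d)\n", r$replicate, r$percent,
                x$n_intersection, r$n_total))
  }
  cat(sprintf("  mean: %.2f%%\n", x$mean_percent))
  invisible(x)
}

#' @export
tidy.stability_summary <- function(x, ...) {
  select(x$per_replicate, "replicate", "n_total", "percent")
}

#' @export
glance.stability_summary <- function(x, ...) {
  tibble(n_replicates = nrow(x$per_replicate),
         n_intersection = x$n_intersection,
         mean_percent = x$mean_percent)
}

# hg19 pseudoautosomal regions (1-based), where X/Y heterozygosity in males
# is legitimate
PAR_REGIONS <- tibble::tibble(
  chrom = c("chrX", "chrX", "chrY", "chrY"),
  start = c(60001, 154931044, 10001, 59034050),
  end = c(2699520, 155260560, 2649520, 59363566)
)

#' Screen genotype tables for sex-impossible records
#'
#' A normal female cannot carry any Y-chromosome genotype, and a male
#' cannot be heterozygous on the X chromosome outside the pseudoautosomal
#' regions (he has only one X there). Records violating these rules are
#' returned with the reason.
#'
#' @param genotypes Tibble: `chrom`, `pos`, `genotype` (optionally
#'   `sample`).
#' @param declared_sex `"female"` or `"male"`.
#' @param par Pseudoautosomal regions (1-based, inclusive); defaults to
#'   the hg19 PAR1/PAR2 coordinates.
#' @return The impossible records with a `reason` column (0 rows when the
#'   table is clean).
#' @export
sex_sanity <- function(genotypes, declared_sex, par = PAR_REGIONS) {
  check_columns(genotypes, c("chrom", "pos", "genotype"), "genotype table")
  declared_sex <- match.arg(declared_sex, c("female", "male"))
  genotypes <- as_tibble(genotypes)
  if (nrow(genotypes) == 0) return(mutate(genotypes, reason = character()))
  genotypes$chrom <- normalize_chrom(genotypes$chrom)
  in_par <- function(chrom, pos) {
    purrr::map2_lgl(chrom, pos, function(ch, p) {
      any(par$chrom == ch & par$start <= p & par$end >= p)
    })
  }
  is_het <- purrr::map_lgl(genotypes$genotype, function(g) {
    if (is.na(g)) return(FALSE)
    a <- strsplit(g, "/", fixed = TRUE)[[1]]
    length(unique(a)) > 1
  })
  has_call <- !is.na(genotypes$genotype) & nzchar(genotypes$genotype) &
    genotypes$genotype != "-"
  flag_y <- declared_sex == "female" & genotypes$chrom == "chrY" & has_call
  flag_x <- declared_sex == "male" & genotypes$chrom == "chrX" & is_het &
    !in_par(genotypes$chrom, genotypes$pos)
  out <- genotypes[flag_y | flag_x, , drop = FALSE]
  out$reason <- ifelse(flag_y[flag_y | flag_x],
                       "Y-chromosome genotype in a female",
                       "heterozygous X genotype in a male outside PAR")
  out
}
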