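#' Parse and classify an HGVS-style coding variant description
#'
#' Classifies a `c.` description into one of the categories `SNV`,
#' `insertion`, `deletion`, `delins` or `duplication`, and into a region
#' class (`coding` vs `splice/intronic`). Positions with an intronic offset
#' (e.g. `c.1116+1G>A`, `c.7210-2A>G`, `c.851-33T>A`) are splice/intronic;
#' offsets of magnitude 1 or 2 touch the canonical splice dinucleotides.
#'
#' The full HGVS grammar is out of scope: inversions, mosaic alleles and
#' RNA-level descriptions are rejected with a classification error that
#' carries the raw string. The nonstandard deletion-insertion shorthand
#' `c.<pos>ins><bases>` is classified `delins`.
#'
#' @param desc Character vector of coding-level descriptions, each beginning
#'   with `"c."`.
#' @return A tibble with one row per description: `cdna` (canonicalized,
#'   whitespace stripped), `category`, `region_class`, `position`, `offset`,
#'   `end_position`, `affected_length` (positive when positions or explicit
#'   bases allow it, otherwise `NA`).
#' @examples
#' parse_hgvs_c(c("c.236G>A", "c.9914_9915delCT", "c.1116+1G>A"))
#' @export
parse_hgvs_c <- function(desc) {
  if (length(desc) == 0) {
    stop_paneldx("no description supplied", class = "paneldx_hgvs_error")
  }
  bind_rows(lapply(desc, parse_hgvs_c_one))
}

parse_hgvs_c_one <- function(desc) {
  raw <- desc
  if (!is.character(desc) || length(desc) != 1L || is.na(desc) ||
      !nzchar(trimws(desc))) {
    stop_paneldx("empty or non-character variant description",
                 class = "paneldx_hgvs_error", raw = raw)
  }
  s <- gsub("\\s+", "", desc)
  if (!startsWith(s, "c.")) {
    stop_paneldx(sprintf("not a coding-level (c.) description: '%s'", raw),
                 class = "paneldx_hgvs_error", raw = raw)
  }
  body <- substr(s, 3, nchar(s))

  # Leading position(s): <num>[(+|-)<num>] optionally _<num>[(+|-)<num>]
  pos_re <- "^(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?"
  m <- regmatches(body, regexec(pos_re, body, perl = TRUE))[[1]]
  if (length(m) == 0 || !nzchar(m[1])) {
    stop_paneldx(sprintf("cannot locate a coding position in '%s'", raw),
                 class = "paneldx_hgvs_error", raw = raw)
  }
  position <- as.integer(m[2])
  offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  end_position <- if (length(m) >= 4 && nzchar(m[4])) as.integer(m[4]) else NA_integer_
  end_offset <- if (length(m) >= 5 && nzchar(m[5])) as.integer(m[5]) else 0L
  rest <- substr(body, nchar(m[1]) + 1, nchar(body))

  has_del <- grepl("del", rest, fixed = TRUE)
  has_ins <- grepl("ins", rest, fixed = TRUE)
  has_dup <- grepl("dup", rest, fixed = TRUE)

  category <- NULL
  affected <- NA_integer_
  if (has_del && has_ins) {
    category <- "delins"
  } else if (grepl("^ins>", rest)) {
    # nonstandard shorthand for a deletion-insertion at one position
    category <- "delins"
  } else if (has_del) {
    category <- "deletion"
  } else if (has_ins) {
    category <- "insertion"
  } else if (has_dup) {
    category <- "duplication"
  } else if (grepl("^[ACGTacgt]>[ACGTacgt]$", rest)) {
    category <- "SNV"
  } else {
    stop_paneldx(sprintf("unrecognized coding description: '%s'", raw),
                 class = "paneldx_hgvs_error", raw = raw)
  }

  if (category %in% c("deletion", "duplication", "delins")) {
    if (!is.na(end_position)) {
      affected <- end_position - position + 1L
    } else {
      bases <- sub("^(del|dup|ins>)", "", rest)
      bases <- sub("^ins", "", bases)
      affected <- if (grepl("^[ACGTacgt]+$", bases)) nchar(bases) else 1L
    }
  } else if (category == "insertion") {
    bases <- sub("^ins", "", rest)
    affected <- if (grepl("^[ACGTacgt]+$", bases)) nchar(bases) else NA_integer_
  } else if (category == "SNV") {
    affected <- 1L
  }
  if (!is.na(affected) && affected <= 0) {
    stop_paneldx(
      sprintf("non-positive affected length in '%s' (end before start?)", raw),
      class = "paneldx_hgvs_error", raw = raw
    )
  }

  region_class <- if (offset != 0L || end_offset != 0L) "splice/intronic" else "coding"

  tibble(
    cdna = s,
    category = category,
    region_class = region_class,
    position = position,
    offset = offset,
    end_position = end_position,
    affected_length = as.integer(affected)
  )
}

#' Classify any mutation description from a diagnostic report table
#'
#' Extends [parse_hgvs_c()] to the chromosome-scale entries that appear in
#' diagnostic summaries: karyotype-style gains (`"47,XX,+10"`) map to
#' `chromosomal_gain`, cytogenetic deletions (`"del(17)(p11.2)"` or
#' `"46,XN,del(17)(p11.2)"`) to `chromosomal_loss`, and exon-run
#' duplications (`"CDS1-4 dup"`) to `duplication`. These categories are
#' excluded from SNV/indel accounting.
#'
#' @param desc Character vector of descriptions.
#' @return A tibble as in [parse_hgvs_c()]; chromosome-scale entries have
#'   `NA` positions and region class `NA`.
#' @export
classify_mutation <- function(desc) {
  bind_rows(lapply(desc, function(d) {
    s <- trimws(d)
    if (startsWith(gsub("\\s+", "", s), "c.")) {
      return(parse_hgvs_c_one(s))
    }
    flat <- gsub("\\s+", "", s)
    if (grepl("del\\(", flat)) {
      cat_ <- "chromosomal_loss"
    } else if (grepl("^4[5-9][.,]X", flat) && grepl("\\+", flat)) {
      cat_ <- "chromosomal_gain"
    } else if (grepl("dup", flat, ignore.case = TRUE)) {
      cat_ <- "duplication"
    } else {
      stop_paneldx(sprintf("unrecognized mutation description: '%s'", d),
                   class = "paneldx_hgvs_error", raw = d)
    }
    tibble(
      cdna = s,
      category = cat_,
      region_class = NA_character_,
      position = NA_integer_,
      offset = NA_integer_,
      end_position = NA_integer_,
      affected_length = NA_integer_
    )
  }))
}

#' Read a tab-separated mutation summary table
#'
#' Reads a diagnostic mutation summary in which each row is a case and the
#' `mutations` column holds zero or more `";"`-separated entries of the form
#' `"GENE c.<desc> (p.<desc>) (Hom|Hem), novel"`. A cell equal to
#' `"negative result"` (or empty) yields no records for that case, so a case
#' with compound heterozygous mutations yields two records. Zygosity marks
#' `(Hom)` / `(Hem)` map to homozygous / hemizygous; unmarked entries are
#' heterozygous. `", novel"` sets the novel flag on that record only.
#'
#' Alternatively the file may already be one-record-per-row with columns
#' `case_id, gene, cdna, protein, zygosity, novel`.
#'
#' @param path Path to a TSV file with a header. Mandatory columns:
#'   `case_id` plus either `mutations` or `cdna`.
#' @return A tibble with one row per mutation record: `case_id`, `gene`,
#'   `cdna`, `protein`, `zygosity`, `novel`, `category`, `region_class`,
#'   plus any `clinical_diagnosis` / `consistency` columns present in the
#'   input.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) {
    stop_paneldx(sprintf("mutation table not found: %s", path),
                 class = "paneldx_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, "case_id", "mutation table")
  if (!("mutations" %in% names(df)) && !("cdna" %in% names(df))) {
    stop_paneldx("mutation table needs a 'mutations' or a 'cdna' column",
                 class = "paneldx_schema_error")
  }

  extras <- intersect(c("clinical_diagnosis", "consistency"), names(df))

  if ("cdna" %in% names(df)) {
    check_columns(df, c("gene", "cdna", "zygosity", "novel"), "mutation table")
    recs <- df |>
      mutate(novel = tolower(.data$novel) %in% c("true", "yes", "1"),
             protein = if ("protein" %in% names(df)) .data$protein else NA_character_)
  } else {
    recs <- bind_rows(purrr::map(seq_len(nrow(df)), function(i) {
      cell <- df$mutations[i]
      if (is.na(cell) || !nzchar(trimws(cell)) ||
          grepl("negative result", cell, fixed = TRUE)) {
        return(NULL)
      }
      entries <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
      bind_rows(purrr::map(entries, parse_mutation_entry)) |>
        mutate(case_id = df$case_id[i], .before = 1)
    }))
    for (col in extras) {
      recs <- left_join(recs, select(df, "case_id", dplyr::all_of(col)),
                        by = "case_id")
    }
  }

  cls <- classify_mutation(recs$cdna)
  recs |>
    mutate(category = cls$category, region_class = cls$region_class,
           cdna = cls$cdna)
}

# One "GENE c.desc (p.desc) (Hom), novel" entry -> one record row.
parse_mutation_entry <- function(entry) {
  s <- entry
  novel <- grepl("\\bnovel\\b", s)
  s <- trimws(gsub(",?\\s*novel", "", s))
  zyg <- "heterozygous"
  if (grepl("\\(Hom\\)", s)) zyg <- "homozygous"
  if (grepl("\\(Hem\\)", s)) zyg <- "hemizygous"
  s <- trimws(gsub("\\((Hom|Hem)\\)", "", s))
  protein <- NA_character_
  pm <- regmatches(s, regexec("\\((p\\.[^)]+)\\)", s))[[1]]
  if (length(pm) == 2) {
    protein <- pm[2]
    s <- trimws(gsub("\\(p\\.[^)]+\\)", "", s))
  }
  gene <- NA_character_
  gm <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9-]*)\\s+(.+)$", s))[[1]]
  if (length(gm) == 3 && !startsWith(gm[2], "c.")) {
    gene <- gm[2]
    s <- trimws(gm[3])
  }
  if (identical(gene, "-")) gene <- NA_character_
  tibble(gene = gene, cdna = trimws(s), protein = protein,
         zygosity = zyg, novel = novel)
}

#' Summary counts over a mutation record table
#'
#' @param records Output of [read_mutation_table()].
#' @return A one-row tibble: per-category counts, `n_records`, `n_indels`
#'   (deletion + insertion + delins), `n_snv_records`,
#'   `n_snv_unique_alleles` (deduplicated on gene + cdna, since the same
#'   allele can recur in related cases), and `n_novel` (per record
#'   occurrence).
#' @export
mutation_summary <- function(records) {
  check_columns(records, c("cdna", "category", "novel"), "mutation records")
  cats <- c("SNV", "insertion", "deletion", "delins", "duplication",
            "chromosomal_gain", "chromosomal_loss")
  counts <- setNames(
    purrr::map_int(cats, ~ sum(records$category == .x)),
    paste0("n_", gsub("/", "_", tolower(cats)))
  )
  snv <- filter(records, .data$category == "SNV")
  out <- as_tibble(as.list(counts))
  out$n_records <- nrow(records)
  out$n_indels <- sum(records$category %in% c("deletion", "insertion", "delins"))
  out$n_snv_records <- nrow(snv)
  out$n_snv_unique_alleles <- nrow(distinct(snv, .data$gene, .data$cdna))
  out$n_novel <- sum(records$novel)
  out
}
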