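#' Annotate variant calls against pluggable annotation tables
#'
#' Left-joins calls with an annotation table keyed by
#' (chrom, pos, ref, alt) carrying local cohort frequency, population
#' frequency, a known-pathogenic flag and a count of in-silico tools voting
#' the variant deleterious. Calls absent from the table get missing
#' frequencies, are treated as rare, and are flagged novel.
#'
#' @param calls Tibble of variant calls: `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `zygosity` (plus optional `cdna`, `protein`).
#' @param annotations Annotation tibble: `chrom`, `pos`, `ref`, `alt` and
#'   any of `local_cohort_freq`, `population_freq`, `known_pathogenic`,
#'   `deleterious_votes`. `NULL` means no annotation source (everything
#'   novel).
#' @return The calls with annotation columns and a logical `novel` column.
#' @export
annotate_calls <- function(calls, annotations = NULL) {
  check_columns(calls, c("chrom", "pos", "ref", "alt", "gene", "zygosity"),
                "variant calls")
  calls <- as_tibble(calls)
  for (col in c("cdna", "protein")) {
    if (!col %in% names(calls)) calls[[col]] <- NA_character_
  }
  if (nrow(calls) == 0) {
    return(mutate(calls, local_cohort_freq = double(),
                  population_freq = double(), known_pathogenic = logical(),
                  deleterious_votes = integer(), novel = logical()))
  }
  ann_cols <- c("local_cohort_freq", "population_freq", "known_pathogenic",
                "deleterious_votes")
  if (is.null(annotations) || nrow(as_tibble(annotations)) == 0) {
    annotations <- tibble(chrom = character(), pos = double(),
                          ref = character(), alt = character(),
                          local_cohort_freq = double(),
                          population_freq = double(),
                          known_pathogenic = logical(),
                          deleterious_votes = integer())
  }
  annotations <- as_tibble(annotations)
  check_columns(annotations, c("chrom", "pos", "ref", "alt"),
                "annotation table")
  for (col in ann_cols) {
    if (!col %in% names(annotations)) {
      annotations[[col]] <- if (col == "known_pathogenic") NA else NA_real_
    }
  }
  for (col in c("local_cohort_freq", "population_freq")) {
    v <- annotations[[col]]
    if (!is.numeric(v) || any(v < 0 | v > 1, na.rm = TRUE)) {
      stop_paneldx(sprintf("annotation column '%s' must be numeric in [0, 1]",
                           col),
                   class = "paneldx_schema_error")
    }
  }
  ann <- annotations |>
    select("chrom", "pos", "ref", "alt", dplyr::all_of(ann_cols)) |>
    mutate(.matched = TRUE)
  out <- calls |>
    left_join(ann, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(
      novel = is.na(.data$.matched),
      known_pathogenic = !is.na(.data$known_pathogenic) & .data$known_pathogenic,
      deleterious_votes = tidyr::replace_na(.data$deleterious_votes, 0)
    ) |>
    select(-".matched")
  out
}

#' Filter annotated variants on population and cohort frequency
#'
#' Retains records whose every *available* frequency is at or below
#' `max_freq`, or that are known pathogenic (pathogenicity overrides
#' frequency). Records with no frequency data at all are retained (treated
#' as rare). The function is monotone in `max_freq`: raising it can only
#' enlarge the output. Removed records, with the reason, are attached as
#' `attr(out, "removed")`.
#'
#' @param records Annotated calls from [annotate_calls()].
#' @param max_freq Maximum tolerated frequency (default 0.005).
#' @return The retained records.
#' @export
frequency_filter <- function(records, max_freq = 0.005) {
  check_columns(records, c("local_cohort_freq", "population_freq",
                           "known_pathogenic"), "annotated records")
  check_number(max_freq, "max_freq", lower = 0, upper = 1)
  rare <- function(f) is.na(f) | f <= max_freq
  keep <- records$known_pathogenic |
    (rare(records$local_cohort_freq) & rare(records$population_freq))
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed) > 0) {
    removed$removal_reason <- sprintf(
      "frequency above %g (local %s, population %s)", max_freq,
      format(removed$local_cohort_freq), format(removed$population_freq))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Check a gene's variant records against an inheritance model
#'
#' * `AR`: consistent with disease iff one homozygous record or at least
#'   two heterozygous records (a putative compound heterozygote — phase is
#'   unknown from calls alone); a single heterozygote is `carrier_only`.
#' * `AD`: any record is consistent.
#' * `XL`: consistent iff hemizygous (males) or homozygous (females); a
#'   heterozygous record is `carrier_only`.
#'
#' @param records Variant records sharing one gene, with a `zygosity`
#'   column.
#' @param model `"AD"`, `"AR"` or `"XL"`.
#' @param sex Sample sex (`"female"`/`"male"`/`NA`), used for XL.
#' @return `"consistent"`, `"inconsistent"` or `"carrier_only"`.
#' @export
model_consistency <- function(records, model, sex = NA_character_) {
  if (!is.character(model) || length(model) != 1 ||
      !model %in% c("AD", "AR", "XL")) {
    stop_paneldx(sprintf("unknown inheritance model: %s",
                         paste(model, collapse = ",")),
                 class = "paneldx_config_error")
  }
  if (nrow(records) == 0) return("inconsistent")
  if (dplyr::n_distinct(records$gene) > 1) {
    stop_paneldx("records must all share one gene",
                 class = "paneldx_validation_error")
  }
  zyg <- records$zygosity
  switch(model,
    AD = "consistent",
    AR = if (any(zyg == "homozygous")) {
      "consistent"
    } else if (sum(zyg == "heterozygous") >= 2) {
      "consistent"  # putative compound het, phase unknown
    } else {
      "carrier_only"
    },
    XL = if (any(zyg == "hemizygous") || any(zyg == "homozygous")) {
      "consistent"
    } else {
      "carrier_only"
    }
  )
}

#' Label proband variants by trio segregation
#'
#' Each proband variant is looked up in both parents' call sets:
#' present in one parent only gives `inherited_paternal` /
#' `inherited_maternal`; in both, `inherited_biparental`; in neither,
#' `de_novo`. A homozygous proband variant requires both parents to carry
#' it (otherwise `mendelian_error`), and a hemizygous X variant in a male
#' proband is expected from the mother — paternal-only presence is a
#' `mendelian_error`.
#'
#' @param proband,father,mother Call tibbles (`chrom`, `pos`, `ref`,
#'   `alt`, `zygosity`).
#' @return The proband calls with `in_father`, `in_mother` and `status`.
#' @export
segregation_check <- function(proband, father, mother) {
  for (nm in c("proband", "father", "mother")) {
    df <- get(nm)
    check_columns(df, c("chrom", "pos", "ref", "alt"), paste(nm, "calls"))
    if (nrow(distinct(df, .data$chrom, .data$pos, .data$ref, .data$alt)) <
        nrow(df)) {
      stop_paneldx(sprintf("duplicated locus within %s call set", nm),
                   class = "paneldx_data_error")
    }
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  proband |>
    as_tibble() |>
    mutate(
      in_father = key(proband) %in% key(father),
      in_mother = key(proband) %in% key(mother),
      status = case_when(
        .data$zygosity == "hemizygous" & .data$chrom == "chrX" &
          .data$in_mother ~ "inherited_maternal",
        .data$zygosity == "hemizygous" & .data$chrom == "chrX" &
          .data$in_father & !.data$in_mother ~ "mendelian_error",
        .data$zygosity == "homozygous" & .data$in_father & .data$in_mother ~
          "inherited_biparental",
        # a homozygote needs one allele from each parent; anything else is
        # a transmission anomaly (or an overlapping deletion)
        .data$zygosity == "homozygous" ~ "mendelian_error",
        .data$in_father & .data$in_mother ~ "inherited_biparental",
        .data$in_father ~ "inherited_paternal",
        .data$in_mother ~ "inherited_maternal",
        TRUE ~ "de_novo"
      )
    )
}

# A record is truncating when its descriptions imply loss of function:
# nonsense or frameshift protein change, or a substitution at the canonical
# +/-1/2 splice positions.
is_truncating <- function(records) {
  prot <- records$protein %||% rep(NA_character_, nrow(records))
  cdna <- records$cdna %||% rep(NA_character_, nrow(records))
  prot_trunc <- !is.na(prot) & grepl("(fs|\\*)", prot)
  splice <- rep(FALSE, nrow(records))
  ok <- !is.na(cdna) & startsWith(cdna, "c.")
  if (any(ok)) {
    parsed <- purrr::map(cdna[ok], function(d) {
      tryCatch(parse_hgvs_c_one(d), error = function(e) NULL)
    })
    off <- purrr::map_int(parsed, ~ if (is.null(.x)) NA_integer_ else .x$offset)
    splice[ok] <- !is.na(off) & abs(off) %in% c(1L, 2L)
  }
  prot_trunc | splice
}

#' Two-pass candidate-gene variant prioritization
#'
#' Implements the diagnostic decision logic: annotate, filter on frequency
#' (pathogenicity overriding), then look for inheritance-consistent hits in
#' the clinical diagnosis's candidate genes first (tier 1: known
#' pathogenic; tier 2: novel/rare and deleterious or truncating). Only when
#' the candidate genes yield nothing is the whole panel scanned (tier 3,
#' "backward inference"), and the report's consistency field is reassigned
#' to the disease of the hit gene. A single heterozygote in a recessive
#' gene is reported as `carrier_only` (possible missed second allele) and
#' yields a `suspected` verdict, as does a dominant variant inherited from
#' an unaffected parent (incomplete penetrance or non-causal).
#'
#' @param calls Proband variant calls (`chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `zygosity`, optional `cdna`, `protein`).
#' @param clinical_diagnosis Disease code; must exist in `map` unless it is
#'   the explicit string `"unknown"`.
#' @param map Disease-gene map tibble: `disease`, `gene`, `model`.
#' @param annotations Annotation table for [annotate_calls()].
#' @param sex Proband sex, used for X-linked logic.
#' @param father_calls,mother_calls Optional parental call sets enabling
#'   trio segregation labels.
#' @param father_affected,mother_affected Whether each parent shows the
#'   phenotype. A dominant variant inherited from an *unaffected* parent is
#'   downgraded; inheriting it from an affected parent is ordinary dominant
#'   transmission.
#' @param max_freq Frequency cutoff for [frequency_filter()].
#' @param case_id Identifier placed in the report.
#' @return A [diagnostic_report()].
#' @export
prioritize <- function(calls, clinical_diagnosis, map, annotations = NULL,
                       sex = NA_character_, father_calls = NULL,
                       mother_calls = NULL, father_affected = FALSE,
                       mother_affected = FALSE, max_freq = 0.005,
                       case_id = "case") {
  check_columns(map, c("disease", "gene", "model"), "disease-gene map")
  known_dx <- clinical_diagnosis %in% map$disease
  if (!known_dx && !identical(clinical_diagnosis, "unknown")) {
    stop_paneldx(
      sprintf("diagnosis code '%s' not in the disease-gene map (use \"unknown\" to force a panel-wide scan)",
              clinical_diagnosis),
      class = "paneldx_config_error")
  }
  ann <- annotate_calls(calls, annotations)
  kept <- frequency_filter(ann, max_freq)

  seg <- NULL
  if (!is.null(father_calls) && !is.null(mother_calls) && nrow(kept) > 0) {
    seg <- segregation_check(kept, father_calls, mother_calls) |>
      select("chrom", "pos", "ref", "alt", "status")
  }

  gene_model <- function(g) {
    m <- map$model[map$gene == g]
    if (length(m) == 0) NA_character_ else m[1]
  }

  evaluate_genes <- function(records, tier_known, tier_novel) {
    if (nrow(records) == 0) return(records[0, ])
    records |>
      dplyr::group_split(.data$gene) |>
      purrr::map(function(gdf) {
        g <- gdf$gene[1]
        model <- gene_model(g)
        trunc <- is_truncating(gdf)
        qualifies <- gdf$known_pathogenic | gdf$deleterious_votes >= 1 | trunc
        q <- gdf[qualifies, , drop = FALSE]
        if (nrow(q) == 0) return(NULL)
        # genes without a mapped model are assessed leniently as dominant
        mc <- model_consistency(q, if (is.na(model)) "AD" else model, sex)
        if (mc == "inconsistent") return(NULL)
        q |>
          mutate(
            tier = ifelse(.data$known_pathogenic, tier_known, tier_novel),
            model_call = mc,
            truncating = trunc[qualifies],
            model_used = model
          )
      }) |>
      bind_rows()
  }

  candidate_genes <- map$gene[map$disease == clinical_diagnosis]
  pass1 <- evaluate_genes(filter(kept, .data$gene %in% candidate_genes), 1L, 2L)
  hits <- pass1
  consistency <- "yes"
  if (is.null(hits) || nrow(hits) == 0) {
    pass2 <- evaluate_genes(filter(kept, !.data$gene %in% candidate_genes),
                            3L, 3L)
    hits <- pass2
    if (!is.null(hits) && nrow(hits) > 0) {
      top_gene <- hits$gene[order(hits$tier)][1]
      dx <- map$disease[map$gene == top_gene]
      consistency <- paste0("reassigned:",
                            if (length(dx) > 0) dx[1] else "unknown")
    }
  }

  if (is.null(hits) || nrow(hits) == 0) {
    return(diagnostic_report(
      case_id, clinical_diagnosis,
      tibble(tier = integer(), gene = character(), cdna = character(),
             zygosity = character(), novel = logical(),
             model_call = character(), evidence = character()),
      verdict = "negative", consistency = "no"
    ))
  }

  if (!is.null(seg)) {
    hits <- left_join(hits, seg, by = c("chrom", "pos", "ref", "alt"))
    # dominant variants inherited from an unaffected parent: downgrade
    from_unaffected <- (hits$status %in% "inherited_paternal" &
                          !father_affected) |
      (hits$status %in% "inherited_maternal" & !mother_affected) |
      (hits$status %in% "inherited_biparental" &
         !father_affected & !mother_affected)
    ad_inherited <- !is.na(hits$model_used) & hits$model_used == "AD" &
      from_unaffected
    hits$model_call[ad_inherited] <- "downgraded"
  } else {
    hits$status <- NA_character_
  }

  n_het_in_gene <- hits |>
    group_by(.data$gene) |>
    mutate(.n_het = sum(.data$zygosity == "heterozygous")) |>
    pull(.data$.n_het)
  hits <- hits |>
    mutate(
      evidence = paste0(
        ifelse(.data$known_pathogenic, "known_pathogenic", "rare"),
        ifelse(.data$novel, ";novel", ""),
        ifelse(.data$truncating, ";truncating", ""),
        ifelse(.data$deleterious_votes >= 1, ";deleterious", ""),
        ifelse(.data$zygosity == "heterozygous" & n_het_in_gene >= 2 &
                 .data$model_used %in% "AR", ";phase_unknown", ""),
        ifelse(.data$model_call == "carrier_only",
               ";possible_missed_second_allele", ""),
        ifelse(.data$model_call == "downgraded",
               ";incomplete_penetrance_or_non_causal", ""),
        ifelse(!is.na(.data$status), paste0(";", .data$status), "")
      )
    )

  verdict <- if (any(hits$model_call == "consistent")) {
    "causal_found"
  } else {
    "suspected"
  }
  diagnostic_report(
    case_id, clinical_diagnosis,
    select(hits, "tier", "gene", "cdna", "zygosity", "novel", "model_call",
           "evidence", dplyr::any_of(c("chrom", "pos", "ref", "alt",
                                       "protein", "status"))),
    verdict = verdict, consistency = consistency
  )
}

#' Read a disease-to-candidate-gene map
#'
#' @param path TSV with header columns `disease`, `gene`, `model`
#'   (`AD`/`AR`/`XL`); one row per (disease, gene) pair, candidate genes in
#'   priority order.
#' @return A tibble.
#' @export
read_disease_gene_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  check_columns(df, c("disease", "gene", "model"), "disease-gene map")
  bad <- setdiff(unique(df$model), c("AD", "AR", "XL"))
  if (length(bad) > 0) {
    stop_paneldx(sprintf("unknown inheritance model(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "paneldx_schema_error")
  }
  df
}
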