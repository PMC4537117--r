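#' Construct a diagnostic report
#'
#' The tiered output of variant prioritization for one case. Tier 1 holds
#' known-pathogenic, inheritance-consistent hits in candidate genes; tier 2
#' novel deleterious/truncating hits in candidate genes; tier 3 hits found
#' by scanning the rest of the panel when the candidate genes are empty
#' ("backward inference", with the consistency field reassigned to the
#' disease of the hit gene).
#'
#' @param case_id Case identifier.
#' @param clinical_diagnosis Diagnosis code the case came in with (may be
#'   `"unknown"`).
#' @param hits A tibble of prioritized variants (possibly 0-row) with at
#'   least columns `tier`, `gene`, `cdna`, `zygosity`, `novel`,
#'   `model_call`, `evidence`.
#' @param verdict One of `"causal_found"`, `"suspected"`, `"negative"`.
#'   Must be `"negative"` exactly when `hits` is empty.
#' @param consistency `"yes"`, `"no"`, or `"reassigned:<disease>"`.
#' @return An object of class `"diagnostic_report"`.
#' @export
diagnostic_report <- function(case_id, clinical_diagnosis, hits, verdict,
                              consistency) {
  hits <- as_tibble(hits)
  if (nrow(hits) > 0) {
    check_columns(hits, c("tier", "gene", "cdna", "zygosity", "novel",
                          "model_call", "evidence"), "report hits")
  }
  verdict <- match.arg(verdict, c("causal_found", "suspected", "negative"))
  if ((verdict == "negative") != (nrow(hits) == 0)) {
    stop_paneldx("verdict must be 'negative' exactly when there are no hits",
                 class = "paneldx_validation_error")
  }
  structure(
    list(case_id = case_id,
         clinical_diagnosis = clinical_diagnosis,
         hits = arrange(hits, .data$tier, .data$gene, .data$cdna),
         verdict = verdict,
         consistency = consistency),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> case %s (%s)\n", x$case_id,
              x$clinical_diagnosis))
  cat(sprintf("  verdict: %s, consistency: %s\n", x$verdict, x$consistency))
  if (nrow(x$hits) == 0) {
    cat("  negative result\n")
  } else {
    for (i in seq_len(nrow(x$hits))) {
      h <- x$hits[i, ]
      cat(sprintf("  [tier %d] %s %s (%s%s)\n", h$tier, h$gene, h$cdna,
                  h$zygosity, if (isTRUE(h$novel)) ", novel" else ""))
    }
  }
  invisible(x)
}

#' @describeIn diagnostic_report Hits as a tibble (one row per prioritized
#'   variant).
#' @param x A `diagnostic_report`.
#' @param ... Unused.
#' @export
tidy.diagnostic_report <- function(x, ...) x$hits

#' @describeIn diagnostic_report One-row summary (case, verdict,
#'   consistency, hit counts by tier).
#' @export
glance.diagnostic_report <- function(x, ...) {
  tibble(
    case_id = x$case_id,
    clinical_diagnosis = x$clinical_diagnosis,
    verdict = x$verdict,
    consistency = x$consistency,
    n_hits = nrow(x$hits),
    n_tier1 = sum(x$hits$tier == 1),
    n_tier2 = sum(x$hits$tier == 2),
    n_tier3 = sum(x$hits$tier == 3)
  )
}

#' Write a diagnostic report to a deterministic JSON file
#'
#' Output is diff-stable: hits are sorted, keys appear in a fixed order and
#' the serialize -> parse -> serialize round trip is byte-identical. A report
#' with no hits serializes with the human-readable summary
#' `"negative result"`.
#'
#' @param report A [diagnostic_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "diagnostic_report"))
  hits <- report$hits
  # zygosity marks as they appear in printed summaries
  mark <- function(z) c(homozygous = " (Hom)", hemizygous = " (Hem)",
                        heterozygous = "")[z]
  summary_txt <- if (nrow(hits) == 0) {
    "negative result"
  } else {
    paste(sprintf("%s %s%s%s", hits$gene, hits$cdna, mark(hits$zygosity),
                  ifelse(hits$novel, ", novel", "")),
          collapse = "; ")
  }
  obj <- list(
    case_id = report$case_id,
    clinical_diagnosis = report$clinical_diagnosis,
    verdict = report$verdict,
    consistency = report$consistency,
    summary = summary_txt,
    hits = hits
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = 2,
                           na = "null")
  ok <- tryCatch({
    writeLines(json, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_paneldx(sprintf("cannot write report to '%s': %s",
                         path, conditionMessage(ok)),
                 class = "paneldx_io_error")
  }
  invisible(path)
}

#' Read back a JSON diagnostic report
#'
#' @param path Path written by [write_report()].
#' @return A [diagnostic_report()].
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  hits <- as_tibble(obj$hits)
  if (nrow(hits) == 0) {
    hits <- tibble(tier = integer(), gene = character(), cdna = character(),
                   zygosity = character(), novel = logical(),
                   model_call = character(), evidence = character())
  }
  diagnostic_report(obj$case_id, obj$clinical_diagnosis, hits,
                    obj$verdict, obj$consistency)
}
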