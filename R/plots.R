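# ggplot2 views of the result objects. Each autoplot returns a ggplot the
# caller can restyle.

#' Plot exon dosage ratios
#'
#' Dots per exon along each gene, with the diploid level and the gain/loss
#' thresholds as reference lines — the view used to eyeball an exon-run
#' duplication such as a 4-exon ~1.5x profile.
#'
#' @param object An `"exon_ratios"` tibble from [normalize_exon_ratios()].
#' @param genes Optional gene subset to display.
#' @param gain_threshold,loss_threshold Reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exon_ratios <- function(object, genes = NULL, gain_threshold = 1.35,
                                 loss_threshold = 0.65, ...) {
  df <- as_tibble(object)
  if (!is.null(genes)) df <- filter(df, .data$gene %in% genes)
  df <- df |>
    group_by(.data$gene) |>
    mutate(exon_index = row_number()) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exon_index, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 1, colour = "grey60") +
    ggplot2::geom_hline(yintercept = c(gain_threshold, loss_threshold),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::labs(x = "exon (panel order)", y = "dosage ratio",
                  title = paste0("Exon dosage ratios: ",
                                 attr(object, "test_sample") %||% "test"))
}

#' Plot chromosome dosage ratios
#'
#' One bar per chromosome; aneuploidies and large segmental events stand
#' out against the diploid line.
#'
#' @param object A `"chrom_dosage"` tibble from [chrom_dosage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chrom_dosage <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(chrom = factor(.data$chrom, levels = KNOWN_CHROMS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$observed_ratio,
                                   fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "dosage ratio", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-sample platform concordance
#'
#' @param object A `"concordance_summary"` from [genotype_concordance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$sample, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_percent, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(min(object$per_sample$percent) - 0.5,
                                      100)) +
    ggplot2::labs(x = NULL, y = "genotype concordance (%)")
}

#' Plot replicate SNV stability
#'
#' @param object A `"stability_summary"` from [replicate_overlap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_replicate,
                  ggplot2::aes(x = .data$replicate, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_percent, linetype = 2) +
    ggplot2::labs(x = NULL, y = "SNVs shared by all replicates (%)")
}
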