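# Shared fixture builders; everything is generated in code.

small_panel <- function(n_genes = 30, exons_per_gene = 6) {
  synthetic_panel(n_genes = n_genes, exons_per_gene = exons_per_gene)
}

small_map <- function() {
  tibble::tibble(
    disease = c("D_AR", "D_AD", "D_XL", "D_OTHER"),
    gene = c("GENE001", "GENE002", "GENE023", "GENE010"),
    model = c("AR", "AD", "XL", "AR")
  )
}

# minimal variant-call row builder
vcall <- function(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                  gene = "GENE001", zygosity = "heterozygous",
                  cdna = NA_character_, protein = NA_character_,
                  sample = "proband") {
  tibble::tibble(sample = sample, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, gene = gene, zygosity = zygosity, cdna = cdna,
                 protein = protein)
}

mutation_table_path <- function() {
  system.file("extdata", "diagnostic_mutations.tsv", package = "paneldx")
}

# SNV key sets with prescribed totals and a prescribed k-way intersection
snv_sets_with <- function(totals, n_common) {
  common <- sprintf("chr1:%d:A:G", seq_len(n_common))
  purrr::imap(setNames(totals, paste0("rep", seq_along(totals))),
              function(n, nm) {
                extra <- sprintf("%s:%d:C:T", nm, seq_len(n - n_common))
                c(common, extra)
              })
}
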