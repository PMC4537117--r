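#' Simulation settings for the synthetic-data generators
#'
#' Bundles every tunable of the generators so that all of them are pure
#' functions of (inputs, spec). Defaults emulate the study conditions the
#' pipeline was evaluated under: ~80-fold mean on-target depth, 90 bp reads,
#' and about 7 million on-target reads per sample.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param n_controls Number of in-batch normal control samples (default 5, a
#'   typical clinical capture batch).
#' @param mean_depth Mean fold-coverage per sample (default 80).
#' @param nb_dispersion Negative-binomial dispersion of per-exon read counts
#'   beyond Poisson (variance = mu + dispersion * mu^2). Default 0.002,
#'   giving an exon dosage-ratio coefficient of variation of roughly 10% at
#'   80-fold depth, in the range observed for hybrid-capture panels.
#' @param capture_effect_sd Standard deviation (log scale) of the per-exon
#'   log-normal capture-efficiency multipliers (default 0.25, reflecting
#'   uneven capture across exons).
#' @param read_length Read length in bases (default 90).
#' @param total_reads On-target reads per sample for chromosome-count
#'   simulation (default 7e6).
#' @param noise_free If `TRUE`, all generators return exact expectations
#'   (negative binomial and multinomial replaced by their means). This mode
#'   is the closed-form oracle for the dosage caller.
#' @param background_rate Expected number of background (non-causal)
#'   variants per gene per individual in case simulation (default 0.02).
#' @param replicate_jitter Length-2 numeric `c(add, drop)`: per-replicate
#'   probability of gaining a spurious SNV / dropping a true SNV.
#' @param events Dosage events as created by [dosage_event()], or `NULL`.
#' @return An object of class `"simulation_spec"` (a named list).
#' @export
simulation_spec <- function(seed = 1L,
                            n_controls = 5L,
                            mean_depth = 80,
                            nb_dispersion = 0.002,
                            capture_effect_sd = 0.25,
                            read_length = 90L,
                            total_reads = 7e6,
                            noise_free = FALSE,
                            background_rate = 0.02,
                            replicate_jitter = c(add = 0.01, drop = 0.01),
                            events = NULL) {
  check_number(seed, "seed")
  check_number(n_controls, "n_controls", lower = 1)
  check_number(mean_depth, "mean_depth", lower = 1e-9)
  check_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_number(capture_effect_sd, "capture_effect_sd", lower = 0)
  check_number(read_length, "read_length", lower = 1)
  check_number(total_reads, "total_reads", lower = 1)
  check_number(background_rate, "background_rate", lower = 0)
  stopifnot(length(replicate_jitter) == 2)
  if (any(replicate_jitter < 0 | replicate_jitter > 1)) {
    stop_paneldx("replicate_jitter probabilities must lie in [0, 1]",
                 class = "paneldx_validation_error")
  }
  if (!is.null(events)) events <- as_tibble(events)
  structure(
    list(seed = as.integer(seed), n_controls = as.integer(n_controls),
         mean_depth = mean_depth, nb_dispersion = nb_dispersion,
         capture_effect_sd = capture_effect_sd,
         read_length = as.integer(read_length), total_reads = total_reads,
         noise_free = isTRUE(noise_free), background_rate = background_rate,
         replicate_jitter = replicate_jitter, events = events),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> seed %d, %d controls, %g-fold depth, dispersion %g%s\n",
    x$seed, x$n_controls, x$mean_depth, x$nb_dispersion,
    if (x$noise_free) " (noise-free)" else ""
  ))
  if (!is.null(x$events) && nrow(x$events) > 0) {
    cat(sprintf("  %d dosage event(s)\n", nrow(x$events)))
  }
  invisible(x)
}

#' Describe a dosage event to inject into simulated data
#'
#' @param scope `"exon_run"` (a run of exons in one gene), `"chromosome"`
#'   (whole-chromosome copy change, e.g. trisomy), or `"segment"` (a genomic
#'   interval, e.g. a megabase-scale microdeletion).
#' @param sample Sample the event belongs to.
#' @param copies Total copy number of the event region (diploid baseline 2;
#'   0 = homozygous loss, 1 = heterozygous loss, 3 = heterozygous gain).
#' @param gene,exons For `exon_run`: gene symbol and character vector of
#'   exon labels.
#' @param chrom,start,end For `chromosome` (chrom only) or `segment`.
#' @return A one-row tibble; rows from several calls can be `rbind`-ed into
#'   the `events` field of [simulation_spec()].
#' @export
dosage_event <- function(scope = c("exon_run", "chromosome", "segment"),
                         sample, copies, gene = NA_character_, exons = NULL,
                         chrom = NA_character_, start = NA_real_,
                         end = NA_real_) {
  scope <- match.arg(scope)
  check_number(copies, "copies", lower = 0)
  tibble(scope = scope, sample = sample, copies = copies, gene = gene,
         exons = list(exons), chrom = chrom, start = start, end = end)
}

#' Build a deterministic synthetic capture panel
#'
#' Lays out `n_genes` genes round-robin across the requested chromosomes,
#' each with `exons_per_gene` exons of `exon_size` bases labelled
#' `CDS1..CDSn`, separated by fixed gaps. The layout is deterministic, so
#' the panel is a pure function of its arguments; total target size is
#' `n_genes * exons_per_gene * exon_size`.
#'
#' @param n_genes,exons_per_gene,exon_size Layout parameters.
#' @param chromosomes Chromosomes to spread genes over.
#' @param intron_gap,gene_gap Spacing between exons / genes, in bases.
#' @return A [panel()].
#' @examples
#' # a 6.19 Mb design: 619 genes x 5 exons x 2 kb
#' p <- synthetic_panel(n_genes = 619, exons_per_gene = 5, exon_size = 2000)
#' panel_total_size(p)
#' @export
synthetic_panel <- function(n_genes = 48, exons_per_gene = 5, exon_size = 150,
                            chromosomes = paste0("chr", c(1:22, "X", "Y")),
                            intron_gap = 2000, gene_gap = 50000) {
  stopifnot(n_genes >= 1, exons_per_gene >= 1, exon_size >= 1)
  chrom_of <- rep(chromosomes, length.out = n_genes)
  gene_rank <- stats::ave(seq_len(n_genes), chrom_of, FUN = seq_along)
  gene_span <- exons_per_gene * (exon_size + intron_gap)
  rows <- purrr::map(seq_len(n_genes), function(g) {
    gstart <- (gene_rank[g] - 1) * (gene_span + gene_gap) + 10000
    estart <- gstart + (seq_len(exons_per_gene) - 1) * (exon_size + intron_gap)
    tibble(
      chrom = chrom_of[g],
      start = estart,
      end = estart + exon_size,
      gene = sprintf("GENE%03d", g),
      exon = paste0("CDS", seq_len(exons_per_gene))
    )
  })
  panel(bind_rows(rows))
}

# Resolve spec$events for one scope against a panel: per (sample, exon row)
# copy numbers. Exons not covered by any event sit at `baseline`.
resolve_exon_copies <- function(p, events, samples, baseline = 2) {
  cp <- matrix(baseline, nrow = nrow(p), ncol = length(samples),
               dimnames = list(NULL, samples))
  if (is.null(events) || nrow(events) == 0) return(cp)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$sample %in% samples) next
    hit <- switch(ev$scope,
      exon_run = {
        labs <- ev$exons[[1]]
        sel <- p$gene == ev$gene & p$exon %in% labs
        if (!any(sel) || sum(sel) != length(labs)) {
          stop_paneldx(
            sprintf("event names unknown exon(s) %s in gene %s",
                    paste(setdiff(labs, p$exon[p$gene == ev$gene]),
                          collapse = ", "), ev$gene),
            class = "paneldx_validation_error")
        }
        sel
      },
      chromosome = p$chrom == ev$chrom,
      segment = p$chrom == ev$chrom & p$start < ev$end & p$end > ev$start
    )
    cp[hit, ev$sample] <- ev$copies
  }
  cp
}

#' Simulate a per-exon depth matrix
#'
#' Per-exon mean depth for each sample is realized through exon read counts:
#' the count for exon e in sample s is negative binomial with mean
#' `mean_depth * capture_effect(e) * copies(e, s) / 2 * width(e) / read_length`
#' and dispersion `nb_dispersion`, and depth = count * read_length /
#' width(e). This keeps the stated mean-depth formula while letting the
#' counting granularity scale with exon size. In noise-free mode the exact
#' expectation is returned.
#'
#' @param p A [panel()].
#' @param spec A [simulation_spec()]; `spec$events` with scope `exon_run`
#'   (or `segment`/`chromosome`) inject copy-number changes.
#' @param samples Character vector of sample names. Defaults to one test
#'   sample `"S1"` plus `spec$n_controls` controls `"C1"..`, all in batch
#'   `"B1"`.
#' @param batch Batch label per sample (recycled).
#' @return A long tibble of class `"depth_matrix"`: `gene`, `exon`, `chrom`,
#'   `start`, `end`, `sample`, `batch`, `depth`.
#' @export
simulate_depths <- function(p, spec, samples = NULL, batch = "B1") {
  stopifnot(inherits(p, "panel"), inherits(spec, "simulation_spec"))
  if (is.null(samples)) {
    samples <- c("S1", paste0("C", seq_len(spec$n_controls)))
  }
  batch <- rep(batch, length.out = length(samples))
  cp <- resolve_exon_copies(p, spec$events, samples)
  width <- p$end - p$start
  n_exon <- nrow(p)

  with_seed(spec$seed, offset = 101L, {
    ce <- exp(stats::rnorm(n_exon, 0, spec$capture_effect_sd))
    depth <- matrix(0, nrow = n_exon, ncol = length(samples))
    for (j in seq_along(samples)) {
      mu_reads <- spec$mean_depth * ce * (cp[, j] / 2) * width / spec$read_length
      counts <- if (spec$noise_free || spec$nb_dispersion == 0) {
        if (spec$noise_free) mu_reads else stats::rpois(n_exon, mu_reads)
      } else {
        rnbinom(n_exon, mu = mu_reads, size = 1 / spec$nb_dispersion)
      }
      depth[, j] <- counts * spec$read_length / width
    }
    out <- tidyr::expand_grid(
      i = seq_len(n_exon), j = seq_along(samples)
    ) |>
      mutate(
        gene = p$gene[.data$i], exon = p$exon[.data$i],
        chrom = p$chrom[.data$i], start = p$start[.data$i],
        end = p$end[.data$i],
        sample = samples[.data$j], batch = batch[.data$j],
        depth = depth[cbind(.data$i, .data$j)]
      ) |>
      select(-"i", -"j")
    class(out) <- c("depth_matrix", class(out))
    out
  })
}

# Per-chromosome expected-count weights for one sample: footprint-weighted
# copies/2, with segment events replacing the overlapped share of the
# footprint. `sex` sets the sex-chromosome baseline (XX or XY).
chrom_weights <- function(fp, sex, events, sample) {
  base <- ifelse(fp$chrom == "chrX", if (sex == "female") 2 else 1,
          ifelse(fp$chrom == "chrY", if (sex == "female") 0 else 1, 2))
  w <- fp$footprint * base / 2
  wbase <- w
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!identical(ev$sample, sample)) next
      k <- match(ev$chrom, fp$chrom)
      if (is.na(k)) next
      if (ev$scope == "chromosome") {
        w[k] <- fp$footprint[k] * ev$copies / 2
      } else if (ev$scope == "segment") {
        # footprint share of the segment approximated by its genomic span
        # clipped to the chromosome's targeted extent
        frac <- min(1, (ev$end - ev$start) / fp$span[k])
        affected <- fp$footprint[k] * frac
        w[k] <- (affected * ev$copies + (fp$footprint[k] - affected) * base[k]) / 2
      }
    }
  }
  list(w = w, w_base = wbase)
}

#' Simulate per-chromosome on-target read counts
#'
#' Expected counts are proportional to each chromosome's merged on-target
#' footprint times copies/2 (sex chromosomes at the karyotype's baseline:
#' XX females carry two X weights, XY males one X and one Y). In stochastic
#' mode, `total_reads` reads are multinomially distributed over chromosomes;
#' in noise-free mode the exact expectation `total_reads * w /
#' sum(w_baseline)` is returned, so a trisomic chromosome's count is exactly
#' 1.5 times its diploid expectation (read yield scales with genome dosage
#' rather than being renormalized).
#'
#' @param p A [panel()].
#' @param spec A [simulation_spec()]; events with scope `chromosome` or
#'   `segment` change dosage.
#' @param sex Named character vector, one of `"female"`/`"male"` per sample;
#'   names are the sample names.
#' @return A tibble of class `"chrom_counts"`: `sample`, `chrom`, `count`.
#' @export
simulate_chrom_counts <- function(p, spec, sex) {
  stopifnot(inherits(p, "panel"), inherits(spec, "simulation_spec"))
  if (is.null(names(sex)) || any(!nzchar(names(sex)))) {
    stop_paneldx("`sex` must be a named vector (names = sample names)",
                 class = "paneldx_validation_error")
  }
  if (!all(sex %in% c("female", "male"))) {
    stop_paneldx("sex values must be 'female' or 'male'",
                 class = "paneldx_validation_error")
  }
  ev <- spec$events
  if (!is.null(ev) && nrow(ev) > 0) {
    ev <- filter(ev, .data$scope %in% c("chromosome", "segment"))
    if (any(ev$copies < 0)) {
      stop_paneldx("negative copy number in dosage event",
                   class = "paneldx_validation_error")
    }
  }
  fp <- panel_footprint(p)
  span <- p |>
    group_by(.data$chrom) |>
    summarise(span = max(.data$end) - min(.data$start), .groups = "drop")
  fp <- left_join(fp, span, by = "chrom")

  with_seed(spec$seed, offset = 202L, {
    out <- purrr::imap(sex, function(sx, sm) {
      ws <- chrom_weights(fp, sx, ev, sm)
      count <- if (spec$noise_free) {
        spec$total_reads * ws$w / sum(ws$w_base)
      } else {
        as.numeric(rmultinom(1, size = spec$total_reads,
                             prob = ws$w / sum(ws$w)))
      }
      tibble(sample = sm, chrom = fp$chrom, count = count)
    })
    out <- bind_rows(out)
    class(out) <- c("chrom_counts", class(out))
    out
  })
}

#' Simulate a diagnostic case (optionally a trio) with known truth
#'
#' Generates a variant call set for a proband (and parents, in trio mode)
#' containing a causal configuration consistent with the candidate gene's
#' inheritance model, plus background variants drawn at stated population
#' frequencies, with trio genotypes obeying Mendelian transmission except
#' for explicitly injected de novo events.
#'
#' * AR, `ar_config = "hom"`: proband homozygous, both parents heterozygous
#'   carriers.
#' * AR, `ar_config = "compound_het"`: two heterozygous variants in the
#'   gene, one inherited from each parent.
#' * AD, `mode = "inherited"`: proband heterozygous, one parent carries the
#'   variant; `mode = "de_novo"`: both parents negative.
#' * XL: male proband hemizygous; mother a heterozygous carrier
#'   (`inherited`) or negative (`de_novo`).
#'
#' @param spec A [simulation_spec()].
#' @param disease_code Disease to simulate; must exist in `map`.
#' @param map Disease-gene map: tibble with columns `disease`, `gene`,
#'   `model` (`AD`/`AR`/`XL`).
#' @param p A [panel()]; causal and background variants are placed inside
#'   its target regions.
#' @param pedigree `"singleton"` or `"trio"`.
#' @param mode `"inherited"` or `"de_novo"` (AD/XL only).
#' @param ar_config For AR genes, `"hom"` or `"compound_het"`.
#' @return A list with elements `calls` (tibble: `sample`, `role`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `zygosity`, `cdna`, `protein`), `truth`
#'   (the causal variant rows for the proband), `annotations` (an
#'   annotation table covering the background variants; causal variants are
#'   deliberately absent, i.e. novel), and `samples` (sample metadata).
#' @export
simulate_case <- function(spec, disease_code, map, p,
                          pedigree = c("singleton", "trio"),
                          mode = c("inherited", "de_novo"),
                          ar_config = c("hom", "compound_het")) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(p, "panel"))
  pedigree <- match.arg(pedigree)
  mode <- match.arg(mode)
  ar_config <- match.arg(ar_config)
  check_columns(map, c("disease", "gene", "model"), "disease-gene map")
  cand <- filter(map, .data$disease == disease_code)
  if (nrow(cand) == 0) {
    stop_paneldx(sprintf("disease code '%s' not present in map", disease_code),
                 class = "paneldx_config_error")
  }

  with_seed(spec$seed, offset = 303L, {
    # prefer a gene whose panel regions exist; XL genes must be on chrX
    cand <- filter(cand, .data$gene %in% p$gene)
    if (nrow(cand) == 0) {
      stop_paneldx("no candidate gene of the requested disease is on the panel",
                   class = "paneldx_config_error")
    }
    gene_row <- cand[1, ]
    model <- gene_row$model
    gene_regions <- filter(as_tibble(p), .data$gene == gene_row$gene)
    if (model == "XL" && !all(gene_regions$chrom == "chrX")) {
      stop_paneldx(sprintf("gene %s is mapped XL but not on chrX",
                           gene_row$gene),
                   class = "paneldx_config_error")
    }

    proband_sex <- if (model == "XL") "male" else sample(c("female", "male"), 1)
    samples <- tibble(
      sample = "proband", role = "proband", sex = proband_sex, affected = TRUE
    )
    if (pedigree == "trio") {
      # in an inherited dominant configuration the transmitting parent
      # (father, by convention here) shows the phenotype too
      samples <- bind_rows(samples, tibble(
        sample = c("father", "mother"), role = c("father", "mother"),
        sex = c("male", "female"),
        affected = c(model == "AD" && mode == "inherited", FALSE)
      ))
    }

    rand_variant <- function(regions, tag) {
      r <- regions[sample(nrow(regions), 1), ]
      pos <- r$start + sample(r$end - r$start, 1)  # 1-based within region
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      cpos <- sample(3000, 1)
      tibble(chrom = r$chrom, pos = pos, ref = ref, alt = alt,
             gene = r$gene,
             cdna = sprintf("c.%d%s>%s", cpos, ref, alt),
             protein = if (tag == "truncating") {
               sprintf("p.Q%d*", ceiling(cpos / 3))
             } else {
               sprintf("p.A%dV", ceiling(cpos / 3))
             })
    }

    # causal configuration: genotype per family member, 0/1/2 alt copies
    causal <- switch(model,
      AR = if (ar_config == "hom") {
        v <- rand_variant(gene_regions, "truncating")
        mutate(v, g_proband = 2, g_father = 1, g_mother = 1)
      } else {
        v1 <- mutate(rand_variant(gene_regions, "truncating"),
                     g_proband = 1, g_father = 1, g_mother = 0)
        v2 <- mutate(rand_variant(gene_regions, "truncating"),
                     g_proband = 1, g_father = 0, g_mother = 1)
        v2$pos <- v1$pos + 10  # distinct loci in the same gene
        bind_rows(v1, v2)
      },
      AD = {
        v <- rand_variant(gene_regions, "truncating")
        if (mode == "de_novo") {
          mutate(v, g_proband = 1, g_father = 0, g_mother = 0)
        } else {
          mutate(v, g_proband = 1, g_father = 1, g_mother = 0)
        }
      },
      XL = {
        v <- rand_variant(gene_regions, "truncating")
        if (mode == "de_novo") {
          mutate(v, g_proband = 1, g_father = 0, g_mother = 0)
        } else {
          mutate(v, g_proband = 1, g_father = 0, g_mother = 1)
        }
      },
      stop_paneldx(sprintf("no gene with a known inheritance model for '%s'",
                           disease_code),
                   class = "paneldx_config_error")
    )

    # background variants across the panel, transmitted Mendelian-ly
    other <- filter(as_tibble(p), is_autosome(.data$chrom))
    n_bg <- if (spec$background_rate > 0) {
      stats::rpois(1, spec$background_rate * dplyr::n_distinct(other$gene))
    } else 0L
    bg <- NULL
    ann_rows <- NULL
    if (n_bg > 0) {
      bg <- bind_rows(purrr::map(seq_len(n_bg), function(i) {
        v <- rand_variant(other, "missense")
        freq <- if (runif(1) < 0.7) runif(1, 0.05, 0.5) else runif(1, 1e-4, 4e-3)
        gf <- rbinom(2, 2, freq)           # parent genotypes under HWE
        gp <- rbinom(1, 1, gf[1] / 2) + rbinom(1, 1, gf[2] / 2)
        mutate(v, g_proband = gp, g_father = gf[1], g_mother = gf[2],
               freq = freq)
      }))
      bg <- distinct(bg, .data$chrom, .data$pos, .keep_all = TRUE)
      ann_rows <- bg |>
        select("chrom", "pos", "ref", "alt", "freq") |>
        mutate(local_cohort_freq = .data$freq, population_freq = .data$freq,
               known_pathogenic = FALSE, deleterious_votes = 0L) |>
        select(-"freq")
      bg <- select(bg, -"freq")
    }
    allv <- bind_rows(mutate(causal, causal = TRUE),
                      if (!is.null(bg)) mutate(bg, causal = FALSE))

    geno_to_zyg <- function(g, chrom, sx) {
      dplyr::case_when(
        g == 0 ~ NA_character_,
        chrom == "chrX" & sx == "male" ~ "hemizygous",
        g >= 2 ~ "homozygous",
        TRUE ~ "heterozygous"
      )
    }
    calls <- bind_rows(purrr::map(seq_len(nrow(samples)), function(i) {
      sm <- samples$sample[i]
      g <- allv[[paste0("g_", samples$role[i])]]
      zyg <- geno_to_zyg(g, allv$chrom, samples$sex[i])
      allv |>
        mutate(sample = sm, role = samples$role[i], zygosity = zyg) |>
        filter(!is.na(.data$zygosity)) |>
        select("sample", "role", "chrom", "pos", "ref", "alt", "gene",
               "zygosity", "cdna", "protein", "causal")
    }))
    truth <- calls |>
      filter(.data$role == "proband", .data$causal) |>
      select(-"causal", -"role")
    annotations <- ann_rows %||%
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), local_cohort_freq = double(),
             population_freq = double(), known_pathogenic = logical(),
             deleterious_votes = integer())

    list(calls = select(calls, -"causal"), truth = truth,
         annotations = annotations, samples = samples,
         gene = gene_row$gene, model = model)
  })
}

#' Simulate a paired NGS-vs-array genotype table
#'
#' Builds `n_loci` autosomal loci with a shared genotype per locus, then
#' injects discordances: either exactly `n_discordant` of them
#' (deterministic mode) or each locus independently with probability
#' `discordance_rate`.
#'
#' @param n_loci Number of shared loci (> 0).
#' @param discordance_rate Probability a locus is discordant.
#' @param seed Integer seed.
#' @param n_discordant If not `NULL`, exactly this many loci (chosen by the
#'   seed) are made discordant and `discordance_rate` is ignored.
#' @param sample Sample name attached to the table.
#' @return A tibble: `sample`, `chrom`, `pos`, `ngs`, `array` (genotypes as
#'   `"A/B"` unordered allele pairs).
#' @export
simulate_concordance_pair <- function(n_loci, discordance_rate = 0, seed = 1L,
                                      n_discordant = NULL, sample = "S1") {
  check_number(n_loci, "n_loci", lower = 1)
  check_number(discordance_rate, "discordance_rate", lower = 0, upper = 1)
  with_seed(seed, offset = 404L, {
    chrom <- base::sample(AUTOSOMES, n_loci, replace = TRUE)
    pos <- base::sample(1e6, n_loci, replace = TRUE) +
      1e6 * as.integer(factor(chrom, levels = AUTOSOMES))
    alleles <- purrr::map_chr(seq_len(n_loci), function(i) {
      a <- base::sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      paste(sort(a), collapse = "/")
    })
    flip <- if (!is.null(n_discordant)) {
      check_number(n_discordant, "n_discordant", lower = 0, upper = n_loci)
      seq_len(n_loci) %in% base::sample(n_loci, n_discordant)
    } else {
      runif(n_loci) < discordance_rate
    }
    arr <- alleles
    # a discordant array genotype: swap to a genotype guaranteed different
    arr[flip] <- purrr::map_chr(alleles[flip], function(g) {
      a <- strsplit(g, "/", fixed = TRUE)[[1]]
      b <- setdiff(c("A", "C", "G", "T"), a)[1]
      paste(sort(c(a[1], b)), collapse = "/")
    })
    out <- tibble(sample = sample, chrom = chrom, pos = pos,
                  ngs = alleles, array = arr)
    arrange(out, .data$chrom, .data$pos)
  })
}

#' Simulate replicate coding-SNV call sets
#'
#' One "true" set of SNV keys plus `k` replicate observations of it, each
#' dropping true SNVs and adding spurious ones at the configured jitter
#' probabilities. Used to exercise replicate-stability statistics.
#'
#' @param spec A [simulation_spec()] (`replicate_jitter`, `seed`).
#' @param n_snvs Size of the true SNV set.
#' @param k Number of replicates.
#' @return A named list of `k` character vectors of SNV keys.
#' @export
simulate_replicate_snvs <- function(spec, n_snvs = 3000, k = 3) {
  stopifnot(inherits(spec, "simulation_spec"))
  check_number(n_snvs, "n_snvs", lower = 1)
  check_number(k, "k", lower = 2)
  with_seed(spec$seed, offset = 505L, {
    truth <- sprintf("chr%d:%d:A:G", base::sample(22, n_snvs, replace = TRUE),
                     base::sample(5e7, n_snvs))
    truth <- unique(truth)
    add_p <- spec$replicate_jitter[["add"]]
    drop_p <- spec$replicate_jitter[["drop"]]
    out <- purrr::map(seq_len(k), function(i) {
      kept <- truth[runif(length(truth)) >= drop_p]
      n_add <- rbinom(1, length(truth), add_p)
      extra <- sprintf("chr%d:%d:C:T", base::sample(22, n_add, replace = TRUE),
                       base::sample(5e7, n_add))
      unique(c(kept, extra))
    })
    setNames(out, paste0("rep", seq_len(k)))
  })
}
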