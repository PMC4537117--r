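ann_tbl <- function(...) {
  tibble::tribble(...)
}

test_that("annotation joins tables and flags unseen variants as novel", {
  calls <- rbind(
    vcall(pos = 100, gene = "GENE001"),
    vcall(pos = 200, gene = "GENE001"),
    vcall(pos = 300, gene = "GENE002")
  )
  ann <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200), ref = "A", alt = "T",
    local_cohort_freq = c(0.2, 0.001), population_freq = c(0.25, NA),
    known_pathogenic = c(FALSE, TRUE), deleterious_votes = c(0L, 2L)
  )
  out <- annotate_calls(calls, ann)
  expect_equal(out$novel, c(FALSE, FALSE, TRUE))
  expect_equal(out$known_pathogenic, c(FALSE, TRUE, FALSE))
  expect_true(is.na(out$population_freq[3]))

  expect_equal(nrow(annotate_calls(calls[0, ], ann)), 0)
  bad <- dplyr::mutate(ann, population_freq = c(2, 3))
  expect_error(annotate_calls(calls, bad), class = "paneldx_schema_error")
})

test_that("frequency filter keeps rare/pathogenic and is monotone in the cutoff", {
  calls <- rbind(vcall(pos = 1), vcall(pos = 2), vcall(pos = 3),
                 vcall(pos = 4))
  ann <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    local_cohort_freq = c(0.30, 0.004, 0.008, NA),
    population_freq = c(0.30, 0.002, 0.008, NA),
    known_pathogenic = c(FALSE, FALSE, FALSE, FALSE),
    deleterious_votes = 0L
  )
  rec <- annotate_calls(calls, ann)
  kept <- frequency_filter(rec, max_freq = 0.005)
  expect_setequal(kept$pos, c(2, 4))
  expect_equal(nrow(attr(kept, "removed")), 2)

  # pathogenicity overrides frequency
  rec2 <- dplyr::mutate(rec, known_pathogenic = pos == 1)
  expect_true(1 %in% frequency_filter(rec2, 0.005)$pos)

  # superset property
  kept_wide <- frequency_filter(rec, max_freq = 0.01)
  expect_true(all(kept$pos %in% kept_wide$pos))
  expect_true(all(c(2, 3, 4) %in% kept_wide$pos))
})

test_that("inheritance-model consistency follows the zygosity rules", {
  hom <- vcall(zygosity = "homozygous")
  het <- vcall(zygosity = "heterozygous")
  hem <- vcall(chrom = "chrX", gene = "GENE023", zygosity = "hemizygous")
  xhet <- vcall(chrom = "chrX", gene = "GENE023", zygosity = "heterozygous")

  expect_equal(model_consistency(hom, "AR"), "consistent")
  expect_equal(model_consistency(rbind(het, het), "AR"), "consistent")
  expect_equal(model_consistency(het, "AR"), "carrier_only")
  expect_equal(model_consistency(het, "AD"), "consistent")
  expect_equal(model_consistency(hem, "XL", sex = "male"), "consistent")
  expect_equal(model_consistency(xhet, "XL", sex = "female"), "carrier_only")
  expect_error(model_consistency(het, "mitochondrial"),
               class = "paneldx_config_error")
  expect_error(model_consistency(rbind(het, vcall(gene = "GENE002")), "AR"),
               class = "paneldx_validation_error")
})

test_that("trio segregation labels maternal, paternal, de novo and errors", {
  pro <- rbind(
    vcall(chrom = "chrX", pos = 10, gene = "GENE023",
          zygosity = "hemizygous"),
    vcall(pos = 20, zygosity = "heterozygous"),
    vcall(pos = 30, zygosity = "homozygous"),
    vcall(pos = 40, zygosity = "heterozygous"),
    vcall(pos = 50, zygosity = "homozygous")
  )
  fa <- rbind(vcall(pos = 20), vcall(pos = 30))
  mo <- rbind(vcall(chrom = "chrX", pos = 10, gene = "GENE023"),
              vcall(pos = 30))
  seg <- segregation_check(pro, fa, mo)
  expect_equal(seg$status[seg$pos == 10], "inherited_maternal")
  expect_equal(seg$status[seg$pos == 20], "inherited_paternal")
  expect_equal(seg$status[seg$pos == 30], "inherited_biparental")
  expect_equal(seg$status[seg$pos == 40], "de_novo")
  # homozygous child with only one carrying parent is a Mendelian error
  expect_equal(seg$status[seg$pos == 50], "mendelian_error")

  expect_error(segregation_check(rbind(pro, pro[1, ]), fa, mo),
               class = "paneldx_data_error")
})

test_that("candidate-gene pass yields tiered causal hits with consistency yes", {
  map <- small_map()
  # homozygous known-pathogenic variant in the AR candidate gene
  calls <- vcall(zygosity = "homozygous", cdna = "c.98C>T",
                 protein = "p.A33V")
  ann <- tibble::tibble(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                        local_cohort_freq = 0.001, population_freq = 0.001,
                        known_pathogenic = TRUE, deleterious_votes = 2L)
  rep <- prioritize(calls, "D_AR", map, ann, case_id = "caseA")
  expect_equal(rep$verdict, "causal_found")
  expect_equal(rep$consistency, "yes")
  expect_equal(tidy(rep)$tier, 1L)

  # novel truncating compound het in the same gene lands in tier 2
  ch <- rbind(
    vcall(pos = 100, cdna = "c.100C>T", protein = "p.Q34*"),
    vcall(pos = 150, cdna = "c.150G>A", protein = "p.W50*")
  )
  rep2 <- prioritize(ch, "D_AR", map, NULL)
  expect_equal(rep2$verdict, "causal_found")
  expect_equal(sort(tidy(rep2)$tier), c(2L, 2L))
  expect_true(all(grepl("phase_unknown", tidy(rep2)$evidence)))
})

test_that("single recessive heterozygote is reported as suspected carrier", {
  map <- small_map()
  calls <- vcall(zygosity = "heterozygous", cdna = "c.1620A>G",
                 protein = "p.Q540Q")
  ann <- tibble::tibble(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                        local_cohort_freq = 0.0001, population_freq = 0.0001,
                        known_pathogenic = TRUE, deleterious_votes = 0L)
  rep <- prioritize(calls, "D_AR", map, ann)
  expect_equal(rep$verdict, "suspected")
  h <- tidy(rep)
  expect_equal(h$model_call, "carrier_only")
  expect_match(h$evidence, "possible_missed_second_allele")
})

test_that("panel-wide scan reassigns the diagnosis when candidates are empty", {
  map <- small_map()
  calls <- vcall(gene = "GENE010", zygosity = "homozygous",
                 cdna = "c.300C>T", protein = "p.Q100*")
  rep <- prioritize(calls, "D_AR", map, NULL)
  expect_equal(rep$verdict, "causal_found")
  expect_equal(rep$consistency, "reassigned:D_OTHER")
  expect_equal(tidy(rep)$tier, 3L)

  # nothing anywhere -> negative with consistency no
  benign <- vcall(gene = "GENE010", zygosity = "heterozygous")
  rep2 <- prioritize(benign, "D_AR", map, NULL)
  expect_equal(rep2$verdict, "negative")
  expect_equal(rep2$consistency, "no")
  expect_equal(nrow(tidy(rep2)), 0)

  expect_error(prioritize(benign, "NOT_A_CODE", map, NULL),
               class = "paneldx_config_error")
})

test_that("dominant variants inherited from an unaffected parent are downgraded", {
  map <- small_map()
  calls <- vcall(gene = "GENE002", cdna = "c.10G>T", protein = "p.G4*")
  rep <- prioritize(calls, "D_AD", map, NULL,
                    father_calls = vcall(gene = "GENE002", sample = "father"),
                    mother_calls = vcall(pos = 999, sample = "mother"))
  expect_equal(rep$verdict, "suspected")
  expect_match(tidy(rep)$evidence, "incomplete_penetrance_or_non_causal")

  # the same variant arising de novo stays causal
  rep2 <- prioritize(calls, "D_AD", map, NULL,
                     father_calls = vcall(pos = 998, sample = "father"),
                     mother_calls = vcall(pos = 999, sample = "mother"))
  expect_equal(rep2$verdict, "causal_found")
  expect_match(tidy(rep2)$evidence, "de_novo")
})

test_that("prioritization recovers injected causal variants in all noise-free cases", {
  p <- small_panel()
  map <- small_map()
  configs <- tidyr::expand_grid(
    dx = c("D_AR", "D_AD", "D_XL"),
    seed = 1:5
  )
  ok <- purrr::pmap_lgl(configs, function(dx, seed) {
    ar_cfg <- if (dx == "D_AR" && seed %% 2 == 0) "compound_het" else "hom"
    mode <- if (dx != "D_AR" && seed %% 2 == 0) "de_novo" else "inherited"
    cs <- simulate_case(simulation_spec(seed = seed), dx, map, p,
                        pedigree = "trio", mode = mode, ar_config = ar_cfg)
    rep <- prioritize(
      dplyr::filter(cs$calls, role == "proband"), dx, map,
      annotations = cs$annotations, sex = cs$samples$sex[1],
      father_calls = dplyr::filter(cs$calls, role == "father"),
      mother_calls = dplyr::filter(cs$calls, role == "mother"),
      father_affected = cs$samples$affected[cs$samples$role == "father"],
      mother_affected = cs$samples$affected[cs$samples$role == "mother"]
    )
    hits <- tidy(rep)
    found <- dplyr::inner_join(hits, cs$truth, by = c("chrom", "pos"))
    nrow(found) == nrow(cs$truth) && all(found$tier <= 2) &&
      rep$verdict == "causal_found"
  })
  expect_true(all(ok))
})

test_that("carrier parents yield carrier_only reports while the proband is causal", {
  p <- small_panel()
  map <- small_map()
  cs <- simulate_case(simulation_spec(seed = 77, background_rate = 0),
                      "D_AR", map, p, pedigree = "trio", ar_config = "hom")
  pro_rep <- prioritize(dplyr::filter(cs$calls, role == "proband"),
                        "D_AR", map, cs$annotations)
  expect_equal(pro_rep$verdict, "causal_found")
  for (parent in c("father", "mother")) {
    prep <- prioritize(dplyr::filter(cs$calls, role == parent),
                       "D_AR", map, cs$annotations)
    expect_equal(prep$verdict, "suspected")
    expect_true(all(tidy(prep)$model_call == "carrier_only"))
  }
})

test_that("every case yields exactly one verdict", {
  map <- small_map()
  set.seed(123)
  for (i in 1:10) {
    calls <- vcall(pos = sample(1000, 1),
                   gene = sample(c("GENE001", "GENE999"), 1),
                   zygosity = sample(c("heterozygous", "homozygous"), 1),
                   protein = sample(c("p.Q10*", "p.A10V", NA), 1))
    rep <- prioritize(calls, "D_AR", map, NULL)
    expect_true(rep$verdict %in% c("causal_found", "suspected", "negative"))
    expect_equal((rep$verdict == "negative"), nrow(tidy(rep)) == 0)
  }
})
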