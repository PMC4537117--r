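---
title: "Dosage calling and variant prioritization for targeted diagnostic panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage calling and variant prioritization for targeted diagnostic panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message = FALSE}
library(paneldx)
library(dplyr)
```

paneldx implements the post-alignment half of a targeted-capture
diagnostic pipeline for Mendelian disease: the reads have already been
aligned, deduplicated and genotyped by standard tooling, and what remains
is the part that turns per-exon depths, per-chromosome read counts and
variant call sets into diagnostic findings. The package covers five
analysis surfaces — capture QC, exon-level CNV calling against in-batch
controls, chromosome-level dosage (aneuploidy, segmental
microdeletion/microduplication, sex inference), candidate-gene variant
prioritization under Mendelian inheritance models, and the platform
concordance / replicate-stability statistics used to validate such an
assay — plus a synthetic-data generator so that all of it is testable
without patient data.

## The panel and its coordinate conventions

A `panel()` is the target-region universe: one row per targeted exon with
chromosome, 0-based half-open BED coordinates, gene symbol and exon label
(`CDS1`, `CDS2`, ...). Variant loci, in contrast, are 1-based in the VCF
convention; the conversion happens once, at the I/O boundary, and nowhere
else. `panel_total_size()` merges overlapping regions (via
GenomicRanges) before summing, so double-listed or overlapping BED lines
cannot inflate the target size.

## Exon-level CNV calling

### The dosage ratio

For a test sample $t$ and in-batch controls $c_1,\dots,c_k$, the depth
$d(e,s)$ of exon $e$ in sample $s$ is first scaled within each sample,
$u(e,s) = d(e,s)/\mathrm{median}_e\, d(e,s)$, removing library-size
differences. The raw dosage ratio is then

$$r(e) = \frac{u(e,t)}{\mathrm{median}_{c}\, u(e,c)},$$

and finally the whole vector is re-centered on its own median,
$r(e) \leftarrow r(e)/\mathrm{median}_e\, r(e)$. Both normalization steps
use medians rather than means so that the test sample's own event does
not drag its reference level, and the final re-centering removes the
small shift the event itself exerts on the test sample's median depth.
Under these conventions a copy-neutral exon sits exactly at 1 and an exon
with $n$ copies at $n/2$: 1.5 for a heterozygous duplication, 0.5 for a
heterozygous (or hemizygous) loss, 0 for a homozygous deletion. The
re-centering assumes most exons are copy-neutral — the normal regime for
a germline panel; a sample in which more than half the target is dosage-
altered would defeat it (and every other within-sample normalization).

Exons at which the control median is zero are flagged `not_computed`
rather than silently divided.

### Run calling

`call_exon_cnv()` turns a ratio vector into calls per gene: maximal runs
of consecutive exons beyond a threshold become one call, with
`observed_ratio` the median ratio of the run and
`expected_copies = round(2 * observed_ratio)`. The default thresholds
1.35 / 0.65 sit midway between the diploid level and the heterozygous
event expectations, and match the decision made on a real confirmed
4-exon duplication whose ratio profile was 1.4965–1.5674 (≈150% of the
control level, subsequently confirmed by qPCR at the same relative
quantification).

A run is *seeded* by at least one exon at or beyond the main threshold;
contiguous exons beyond the midway extension threshold
($(1+\text{main})/2$, i.e. 1.175 / 0.825) join the run. The seed-and-
extend rule matters only under noise: gating every exon of a multi-exon
event at the main threshold would fragment real events whenever one exon
fluctuates across the line, whereas the run median — which determines the
copy number — is much more stable than any single exon. On noise-free
input taking only the values {0.5, 1, 1.5} the rule reduces exactly to
plain per-exon threshold runs (1.0 is below the extension threshold), and
the test suite checks this equivalence against a brute-force run finder
on every such vector up to length 8. Single-exon calls are permitted
(`min_run = 1`) but carry a `single_unit_call` flag, since nothing
distinguishes them from a depth fluctuation except their magnitude.

```{r exon-demo}
p <- synthetic_panel(n_genes = 30, exons_per_gene = 6)
ev <- dosage_event("exon_run", sample = "S1", copies = 3,
                   gene = "GENE005", exons = paste0("CDS", 1:4))
dm <- simulate_depths(p, simulation_spec(seed = 1, noise_free = TRUE,
                                         events = ev))
calls <- call_exon_cnv(normalize_exon_ratios(dm, "S1"))
calls
```

## Chromosome-level dosage

`chrom_dosage()` applies the same idea to per-chromosome on-target read
counts: each chromosome's count becomes a share of the sample's autosomal
total, the share is divided by the median share of reference samples, and
the ratio vector is re-centered on its autosomal median. The re-centering
is what makes the arithmetic exact: a trisomy inflates the sample total
and therefore deflates every share by the same factor, so without it the
trisomic chromosome would sit at $1.5/k$ and every other chromosome at
$1/k$ with $k = 1 + 0.5\,f_c/A$. After re-centering (valid while most
autosomes are euploid) the trisomy sits exactly at 1.5 and everything
else at 1.0. Expected ratios: 1.5 trisomy, 0.5 monosomy, and
intermediate values for segmental events in proportion to the affected
share of the chromosome's footprint.

`segment_dosage()` runs the exon machinery over bins tiling one
chromosome to localize megabase-scale microdeletions and
microduplications; the reported interval is the union of the run's bins,
so breakpoint resolution is the bin size. `infer_sex()` compares X and Y
count shares against the panel-footprint expectation for an XX karyotype
(`x_dose` ≈ 1 female, ≈ 0.5 male) and returns `undetermined` between the
decision bands (0.65–0.8) rather than guessing. `expected_copy_ratio()`
is the expectation a confirmatory qPCR should see: copies / baseline
ploidy, with baseline 1 rather than 2 appropriate for male sex
chromosomes.

## Variant prioritization

`prioritize()` codifies a two-pass diagnostic logic. Calls are annotated
against pluggable tables (local cohort frequency, population frequency,
known-pathogenic flag, in-silico deleteriousness votes); variants absent
from every table are treated as rare and flagged novel. The frequency
filter keeps records whose every available frequency is ≤ `max_freq`
(default 0.005 — the sources this models say only "extremely low", so the
cutoff is configurable) or that are known pathogenic, pathogenicity
overriding frequency.

Pass 1 looks only at the candidate genes mapped to the clinical
diagnosis. A hit must qualify on evidence — known pathogenic (tier 1), or
novel/rare and either voted deleterious or truncating (tier 2), where
truncating is inferred from the descriptions (nonsense `*`, frameshift
`fs`, canonical ±1/2 splice offsets) — and the gene's record set must be
consistent with its inheritance model: AR needs a homozygote or ≥ 2
heterozygotes (a putative compound heterozygote, always flagged
`phase_unknown` because calls alone cannot phase), AD any variant, XL a
hemizygous male or homozygous female. A single AR heterozygote is
`carrier_only` and produces a `suspected` verdict with the reason
`possible_missed_second_allele` — deep-intronic second alleles escape a
CDS-focused panel, so discarding such a record would be wrong.

Only when pass 1 yields nothing is the rest of the panel scanned
(pass 2, tier 3), and the report's consistency field is reassigned to the
disease of the hit gene — the "backward inference" that catches clinical
misdiagnoses. With trio calls supplied, `segregation_check()` labels each
variant `inherited_paternal` / `inherited_maternal` /
`inherited_biparental` / `de_novo` / `mendelian_error` (a homozygote
must receive one allele from each parent; a hemizygous X variant in a
male is expected from the mother). A dominant variant inherited from an
*unaffected* parent is downgraded to `suspected`
(`incomplete_penetrance_or_non_causal`) rather than dropped: either
interpretation — reduced penetrance or a benign variant — remains open.

Verdicts are total: `causal_found` when any fully consistent hit exists,
`suspected` when only downgraded or carrier hits exist, `negative` iff
there are no hits at all.

## Concordance and stability statistics

`genotype_concordance()` compares NGS and array genotypes at shared loci
per sample (unordered allele pairs; loci typed on one platform only are
excluded from the denominator and reported separately).
`replicate_overlap()` intersects k replicate coding-SNV sets and reports
each replicate's share of the common intersection. Percentages are
computed exactly, means are taken over the *unrounded* per-sample values,
and rounding — half away from zero, 2 decimals — happens last; this
ordering is required for the printed per-sample values and their means to
be mutually consistent. `sex_sanity()` flags genotypes that are
impossible for the declared sex (any chrY genotype in a female; a
heterozygous chrX genotype outside the pseudoautosomal regions in a
male), which is how one of the two recurrent platform discordances in
such comparisons is adjudicated in the assay's favour.

## The synthetic-data generator

Every generator is a pure function of its inputs and a seed, and
`noise_free = TRUE` replaces every sampling step by its expectation —
this mode is the closed-form oracle the dosage tests are written against.

* `simulate_depths()` draws per-exon *read counts* from a negative
  binomial with mean `mean_depth × capture_effect(e) × copies/2 ×
  width(e)/read_length` and converts them to depth. Realizing depth
  through read counts makes the counting granularity scale with exon
  size, as it does on a sequencer. Defaults: 80-fold mean depth and 90 bp
  reads (the conditions the assay this models was evaluated under),
  log-normal(0, 0.25²) per-exon capture effects reflecting uneven
  capture, and `nb_dispersion = 0.002` of extra-Poisson variance. The
  dispersion default is a modelling choice — no distributional statement
  exists for this assay class to copy — and was set by a power
  consideration: it yields an exon dosage-ratio CV of ≈ 10% at 80-fold,
  in the range reported for hybrid-capture panels, consistent with the
  near-flat ratio profile observed on the confirmed 4-exon duplication,
  and large enough that run calling (not per-exon gating) is what makes
  multi-exon events recoverable.
* `simulate_chrom_counts()` distributes `total_reads` over chromosomes in
  proportion to on-target footprint × copies/2 (sex chromosomes at the
  karyotype's baseline). In noise-free mode the expectation is taken
  against the *diploid* weight total — read yield scales with genome
  dosage rather than being renormalized — so a trisomic chromosome's
  count is exactly 1.5× its diploid expectation; stochastic mode is a
  multinomial over the renormalized shares, which is what the dosage
  caller's re-centering is designed for. Segmental events scale the
  affected fraction of the chromosome's footprint, approximated by the
  event's share of the chromosome's targeted span.
* `simulate_case()` builds proband (and trio) call sets whose causal
  configuration matches the gene's inheritance model — AR homozygote with
  two carrier parents, AR compound heterozygote with one allele per
  parent, inherited or de novo AD, maternally inherited or de novo XL
  hemizygote — plus background variants drawn at stated population
  frequencies with parents at Hardy–Weinberg genotypes and Mendelian
  transmission to the child. Causal variants are deliberately absent from
  the generated annotation table (novel) and truncating, so they must
  survive the filters on their own evidence.
* `simulate_concordance_pair()` and `simulate_replicate_snvs()` generate
  the platform-comparison and replicate-stability inputs, with either an
  exact injected discordance count or a per-locus rate.

What the generator does *not* emulate: GC and mappability bias, batch
effects beyond a scalar library size, read-level artifacts (it never
produces FASTQ), allele-specific depth, and phasing. Passing tests
therefore demonstrate the correctness of the arithmetic and the decision
logic under the stated noise model, not robustness to every artifact of
real capture data; on real data the normalization inherits whatever
structure the controls share with the test sample, which is exactly why
controls are required to come from the same batch.

## Numerical choices and degenerate inputs

* Rounding of percentages is half away from zero, applied only at
  presentation; all means are over unrounded values.
* `round(2 × ratio)` for copy number is also half away from zero, so a
  ratio of exactly 1.25 reports 3 copies rather than flapping on binary
  representation.
* Ties in run finding cannot occur (thresholds are compared with ≥/≤ and
  runs are maximal by construction); `NA` ratios break runs and never
  seed or extend them.
* Degenerate inputs error loudly with typed conditions
  (`paneldx_validation_error`, `paneldx_config_error`,
  `paneldx_schema_error`, `paneldx_hgvs_error`): empty targets, all-zero
  test samples, absent in-batch controls (named by batch), karyotypes
  with negative copies, unknown inheritance models, unknown chromosome
  names.
* The HGVS-style classifier is deliberately partial: it covers the
  substitution / deletion / insertion / deletion-insertion / duplication
  grammar plus intronic offsets, treats the nonstandard `c.<pos>ins><bases>`
  shorthand as a deletion-insertion (its protein-level description is a
  delins), and rejects everything else with the raw string attached
  rather than guessing.

## Problem sizes in the test suite

The suite runs on panels of 30–48 genes (150–200 exons) with 5 in-batch
controls, 100-replicate recovery experiments for the stochastic
duplication check, 30 trio cases for prioritizer recovery, 10⁵ loci for
the binomial convergence checks, and the full 3^1..3^8 discrete ratio
grid for the run-calling oracle — sizes chosen so the whole suite
exercises every code path in a few minutes on one core while keeping
every statistical check at ≥ 3σ separation.

## Known limitations

* CNV ratios carry no GC/mappability correction; on real data the
  in-batch controls absorb shared capture structure but nothing else.
* Breakpoints are resolved to exon/bin granularity only.
* Compound heterozygotes are never phased; the flag is the honest output.
* The chromosome-dosage re-centering assumes a majority-euploid genome;
  a hypertriploid sample would need external normalization.
* The prioritizer implements codified rules, not clinical judgment: it
  does not score ACMG criteria, model splice impact beyond ±2, or weigh
  conflicting database assertions — those stay with the reviewing
  geneticist.
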