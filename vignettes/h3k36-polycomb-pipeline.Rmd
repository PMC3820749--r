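---
title: "Methods: classifying RA responses, chromatin signatures and DRB-resistant H3K36 methylation"
author: "ash36"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying RA responses, chromatin signatures and DRB-resistant H3K36 methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question and the analysis it requires

During retinoic-acid (RA) induced differentiation of embryonic stem (ES)
cells, developmentally poised genes (Hox and Wnt clusters among them) must
escape Polycomb silencing. The trithorax-group methyltransferase Ash1l
deposits H3K36 methylation over gene bodies, and the central claim this
pipeline operationalizes is that this methylation — and the exclusion of
Polycomb repressive complexes that follows — can be established
independently of productive transcriptional elongation (probed with the
P-TEFb inhibitor DRB), with retinoic-acid receptor (RAR) binding marking
the gene subset where K36me3 resists DRB.

Testing that claim genome-wide takes five coupled analyses, each a module
of this package:

1. **Expression response classification** (`classify_ra_responsive()`,
   `classify_impaired()`, `classify_dysregulated()`): which genes are
   induced by RA, and which of those fail to induce in a
   catalytically dead (ΔSET) mutant.
2. **Peak-to-gene association** (`associate_peaks()`): which genes are
   Ash1l targets (peak within ±4 kb of the TSS) or RAR-associated (peak
   between −20 kb and the TES), and how often RAR peaks are co-occupied
   by Ash1l (`co_occupancy()`).
3. **Chromatin-signature enrichment** (`classify_signature()`,
   `enrichment_vs_background()`): whether impaired genes are enriched for
   the bivalent/K27me3 states characteristic of Polycomb regulation,
   by chi-square against the total gene set.
4. **Coverage analysis** (`gene_rpkm_table()`,
   `percentile75_normalize()`, `drb_dlog2()`, `group_by_response()`,
   `underrepresentation_test()`, `metagene_profile()`,
   `anchor_profile()`): how K36me2/3 respond to DRB per gene, and whether
   RAR-associated genes avoid the "decreased K36me3" group.
5. **Small statistics** (`percent_input()`, `two_sample_t()`,
   `penetrance_table()`): ChIP-qPCR quantification and phenotype
   penetrance.

## Transforms and thresholds

All expression fold changes use the *modified log2* scale
$\log_2(\mathrm{FPKM} + 0.1)$. The 0.1 pseudocount (in FPKM units) damps
the dispersion of near-zero FPKM values; `dlog2()` is the difference of
two modified values, so $\Delta\log_2 = 1$ is a 2-fold change.

Classification thresholds (`response_thresholds()`), all strict
inequalities:

| call | rule | default |
|---|---|---|
| RA-responsive | $\Delta\log_2(\text{+RA} / \text{undiff}) > 2.5$ | > 2.5 (≈ >5-fold) |
| impaired | responsive and $\Delta\log_2(\text{mut} / \text{wt}) < -1$ | < −1 (>2-fold down) |
| dysregulated | $|\Delta\log_2(\text{mut}/\text{wt})| > 1$ | > 1 |
| eligible | FPKM ≥ 0.1 in ≥ 1 compared condition | 0.1 FPKM |

Strictness matters at the boundaries: a gene at exactly
$\Delta\log_2 = 2.5$ is *not* responsive, and a gene at exactly −0.6 in
the DRB grouping below is *not* "decreased". The eligibility floor is a
deliberate design choice: published gene universes of this kind (14,255
"eligible" out of 18,724 annotated) do not come with a stated filter, so
the package uses the simplest rule that removes never-expressed
annotations — detectable FPKM (≥ 0.1) in at least one of the conditions
being compared — and exposes it as a parameter rather than pretending to
reconstruct the original rule.

## Coordinate conventions and window rules

Internally everything is 0-based, half-open `[start, end)` (the BED
convention); GTF input is converted at the boundary, and conversion is an
involution (tested). The TSS is strand-aware (`start` on +, `end − 1` on
−). The two association windows are:

* **TSS window**: `[tss − flank, tss + flank]` inclusive of the TSS base,
  flank 4 kb by default.
* **Upstream + body**: from 20 kb 5′ of the TSS through the TES. "Coding
  region" here means the full transcription unit, not exons: the same
  gene-body span is used by the metagene profiles and the RPKM tables, so
  one consistent reading is applied throughout (this was genuinely open;
  exon-level association would need transcript structure the rest of the
  analysis never uses).

Association is *any overlap* of the peak interval with the window — no
summit rule is imposed, because the weaker reading is the only one all
peak formats support (summits are carried when narrowPeak input provides
them, and anchor profiles do use them). Genes with several transcripts
are reduced to the longest span at ingest so each gene has a single TSS.

Co-occupancy is defined at the *peak* level: the fraction of RAR peaks
with at least one overlapping Ash1l peak (`max_gap = 0` by default, with
a gap parameter exposed). A gene-level reading can be had by
cross-tabulating the two association flags with `cross_tabulate()`.

## Coverage quantification

`coverage_track` stores fixed-width binned counts (sparse runs per
chromosome) plus the library size. Reads are assumed uniform within a
bin, so partial overlaps pro-rate linearly; `region_rpkm()` is then reads
per kb per million mapped. Per-track tables are normalized to their **75th
percentile** (type-7 linear interpolation — the most widespread quantile
convention; the normalizer is stored in the table's attributes and the
operation is idempotent). The DRB response per gene is
$\log_2\frac{q_{75}\text{-norm RPKM}_{DRB+} + 0.1}{q_{75}\text{-norm RPKM}_{DRB-} + 0.1}$,
with the 0.1 pseudocount on the normalized scale chosen by analogy with
the FPKM transform (normalized RPKM can be exactly 0).

Genes are grouped as decreased ($\Delta\log_2 < -0.6$), unchanged, or
increased ($> 0.6$). Only the −0.6 boundary is externally fixed; the
symmetric three-group scheme is the package default and `bin_edges` is
fully configurable for finer schemes.

Metagene profiles rescale each gene body TSS→TES into 100 bins (default)
plus 2 kb flanks in 20 bins, strand-flipped for minus-strand genes; the
reported curve is the column-mean read *density* and its log2 ratio to a
**base density**. "Base" is not externally defined, so the default is the
track's own mean density over covered bases (a flat random track then
gives a flat log2-ratio of 0, which is the property the tests pin down);
any other baseline can be passed explicitly.

## The statistics layer

* `chi_square_2x2()` is the plain Pearson statistic (df = 1, upper tail,
  no continuity correction by default — the counts in these designs are
  large; a `continuity` flag exists). Enrichment reports test each
  category as (in group vs rest) × (in category vs not) against the whole
  universe; the alternative k-category goodness-of-fit reading
  (`test = "goodness_of_fit"`) is provided because "chi-square against
  the total gene set" admits both. P-values are reported raw (the
  `*P < 0.001` convention); a Bonferroni option exists and is off by
  default.
* `two_sample_t()` is the pooled-variance Student's t (the classical
  reading of "Student's t-test"), with Welch available via
  `var_equal = FALSE`. Zero-variance groups are handled explicitly
  (t = 0, p = 1 when means agree).
* `percent_input()` divides IP by dilution-corrected input;
  `subtract_background()` clips at zero (percent input is non-negative
  by construction) and reports how many values were clipped.
* `penetrance_table()` rounds half-up at integer precision, the
  convention under which printed penetrance tables reproduce exactly from
  their counts. `summarize_fraction()` does the same at one decimal.

## What the synthetic generator emulates

`synth_config()`/`synth_generate()` draw, from one seed, a complete
coherent data set: gene models, the four-condition FPKM table, Ash1l/RAR
peak sets, K36me2/3 ± DRB coverage, signature labels, and a truth table
for every planted attribute. Sub-seeds are derived per component, so
generating a subset of components does not change the rest.

The defaults are the study conditions the pipeline targets:

* `frac_ra_responsive = 0.038` (≈ 543 / 14,255) and
  `frac_impaired_given_responsive = 0.28`;
* `ra_effect_log2 = 3.0`, `impair_effect_log2 = −1.5`: placed so that at
  the strict thresholds (2.5, −1) the expected called fractions match the
  configured fractions given the measurement noise;
* `frac_ash1l_target = 0.30`; `co_occupancy = 0.60`;
* `drb_me3_loss_log2 = −1.0` vs `drb_me3_loss_rar_log2 = −0.1` (K36me3
  loss under DRB, attenuated at RAR-associated genes) and
  `drb_me2_gain_log2 = +0.3`;
* `noise_sd_log2 = 0.15` lognormal measurement noise and
  `coverage_density_log_sd = 0.10` per-gene baseline spread — moderate
  values under which a 1-unit effect is a ~5σ separation per gene;
* `frac_rar_associated = 0.40`. This matters beyond realism (upstream-20kb-to-TES
  windows do cover a large minority of genes): 75th-percentile
  normalization absorbs any *global* coverage shift, so a DRB-induced
  loss can only remain visible on the normalized scale if the upper
  quartile of the DRB+ distribution is anchored by unaffected genes.
  With ≥ 25% of genes RAR-associated and nearly unaffected, the
  normalizer tracks them and the −1.0 vs −0.1 contrast survives
  normalization; with a much smaller unaffected fraction the same
  physical effect would be partially normalized away. This is a real
  property of percentile normalization, not an artifact of the
  generator, and is worth remembering when interpreting "unchanged"
  groups in real data.

Placement keeps truth unambiguous: genes sit ≥ 50 kb apart (so no
window of one gene can touch another gene's peaks), Ash1l target peaks
are centred on the TSS, RAR peaks sit in the gene body at least 4.5 kb
from the TSS (so a co-occupying Ash1l partner peak never converts a
non-target into a target), and each RAR peak receives a partner with
probability `co_occupancy`, independently. Consequently the association
rules recover the planted labels *exactly*, and measured co-occupancy is
a binomial estimate of the parameter — both are tested.

Coverage realization is Poisson per bin around a per-gene density with
lognormal gene effects; FPKM noise is multiplicative lognormal. What the
generator does **not** emulate: read-level artifacts (mappability, GC,
duplication), overlapping/nested genes, replicate structure beyond
triplicate qPCR, peak-calling uncertainty, or any mechanistic model of
the ΔSET mutation. Passing tests therefore demonstrate that the
*computational* layer is correct and well-calibrated under the assumed
statistical structure — not that the biological conclusions would
reproduce from raw reads.

## Numerical choices and degenerate inputs

* NaN/negative FPKM, unknown chromosomes, intervals beyond chromosome
  ends, zero-length regions, and unnormalized inputs to `drb_dlog2()`
  are validation errors, never silent drops.
* Normalization requires ≥ 4 genes with positive RPKM; an all-zero table
  is a degenerate-normalizer error.
* Genes shorter than the body-bin count are skipped (with a count) by
  `metagene_profile()`.
* Ties at bin edges: outer edges are strict, internal edges belong to
  the lower bin.
* Rounding of reported percentages is half-up at printed precision
  (`round_half_up()`), not banker's rounding.
* All randomness flows from explicit seeds; `with_seed()` restores the
  caller's RNG state.

## Problem sizes used by the test suite

The suite exercises parameter recovery at 400–5,000 genes and 10–100
seeds per property: association/RPKM oracle equivalence on 100 randomized
≤ 100 kb genomes; co-occupancy recovery at ~2,000 RAR peaks; DRB power
(100 runs at 5,000 genes for the configured effects, 100 for the null);
signature-enrichment power at 5,000 genes with a 2× planted enrichment.
These sizes give the binomial bounds quoted in the tests while keeping a
full run of the suite in the minutes range on a single CPU.

## Known limitations

* The eligibility filter is a placeholder for an unstated published
  rule; absolute gene counts depend on it even though classifications of
  well-expressed genes do not.
* Percentile normalization makes "unchanged" a *relative* statement
  (see above); interpreting absolute DRB responses needs a spike-in or
  input-anchored design, which is out of scope.
* The 2×2 and goodness-of-fit readings of "chi-square against the total
  gene set" can differ for small groups; both are available and the
  default is the 2×2 per category.
* BAM parsing, peak calling, transcript quantification and GO analysis
  are intentionally outside the package; it consumes their standard
  outputs (BED/narrowPeak, GTF, FPKM TSV, bedGraph).
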