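# ash36

Integrative ChIP-Seq/RNA-Seq analysis of how Ash1l-dependent H3K36
methylation counteracts Polycomb silencing during retinoic-acid (RA)
induced differentiation of embryonic stem cells.

## Who this is for, and what it computes

During RA-induced differentiation, poised developmental genes (Hox, Wnt)
must escape Polycomb repression. Ash1l methylates H3K36 over gene bodies,
and the question this analysis pattern addresses is whether that
methylation — and the Polycomb exclusion it brings — requires productive
transcriptional elongation (blocked experimentally with DRB), and how it
relates to retinoic-acid receptor (RAR) binding. The package provides the
full computational layer of such a study, for epigenomics researchers who
have peak calls, FPKM tables and binned coverage in hand:

* **Expression responses** on the modified log2 scale
  $m(x)=\log_2(x+0.1)$: a gene is *RA-responsive* when
  $\Delta\log_2 = m(\mathrm{FPKM}_{+RA}) - m(\mathrm{FPKM}_{undiff}) > 2.5$
  (strict; ≈ more than 5-fold), *impaired* when it is responsive and the
  mutant/wild-type contrast under RA falls strictly below −1, and
  *dysregulated* at |Δlog2| > 1.
* **Peak-to-gene association**: *Ash1l targets* have a peak overlapping
  TSS ± 4 kb; *RAR-associated* genes have a peak between −20 kb of the
  TSS and the TES (strand-aware, 0-based half-open coordinates
  throughout); `co_occupancy()` measures the fraction of one factor's
  peaks overlapped by another's.
* **Chromatin-signature enrichment**: genes carry one of four promoter
  states (Lys4me alone / Bivalent / Lys27me alone / None from K4me3 ×
  K27me3); gene groups are tested against the total gene set with the
  Pearson chi-square (2×2 per category, df = 1, no continuity
  correction), reporting relative ratios as used in bar/radar charts.
* **Coverage analysis**: per-gene-body RPKM from binned coverage,
  normalized to the 75th percentile; the per-gene DRB response
  $\Delta\log_2 = \log_2\frac{\text{norm RPKM}_{DRB+}+0.1}{\text{norm RPKM}_{DRB-}+0.1}$
  groups genes as decreased (< −0.6, strict) / unchanged / increased
  (> 0.6), with chi-square under-representation testing of RAR-associated
  genes per group; metagene (TSS→TES rescaled) and peak-anchored
  profiles.
* **Small statistics**: ChIP-qPCR percent input with background
  subtraction, pooled-variance Student's t, phenotype penetrance tables
  (half-up rounding reproduces printed percentages exactly).
* **A seeded synthetic-data generator** (`synth_generate()`) that
  produces gene models, FPKM tables, peak sets, coverage tracks and
  signature labels with known ground truth, so every stage is testable
  without downloads.

## Worked example

```r
library(ash36)
cfg <- synth_config(seed = 42, n_genes = 2000, frac_ra_responsive = 0.038)
syn <- synth_generate(cfg)

resp <- classify_ra_responsive(syn$expression, "WT_RA", "WT")
imp  <- classify_impaired(syn$expression, "dSET_RA", "WT_RA", resp)
cat(sum(resp$responsive), "RA-responsive genes;",
    sum(imp$impaired), "impaired (",
    summarize_fraction(sum(imp$impaired), sum(resp$responsive)), "%)\n")
#> 76 RA-responsive genes; 22 impaired ( 28.9 %)

targets <- associate_peaks(syn$genes, syn$peaks$ash1l,
                           association_rule("tss_window"), syn$genome)
cat("Ash1l-target genes:", sum(targets$associated), "\n")
#> Ash1l-target genes: 571
cat("RAR/Ash1l co-occupancy:",
    round_half_up(100 * co_occupancy(syn$peaks$rar, syn$peaks$ash1l), 1), "%\n")
#> RAR/Ash1l co-occupancy: 64.1 %

norm <- lapply(syn$coverage$K36me3, function(tr)
  percentile75_normalize(gene_rpkm_table(tr, syn$genes)))
grp <- group_by_response(drb_dlog2(norm[["DRB+"]], norm[["DRB-"]]))
table(grp$group)
#> decreased unchanged increased
#>       682      1308        10

rar_flags <- data.frame(gene_id = syn$truth$gene_id,
                        flag = syn$truth$rar_associated)
underrepresentation_test(grp, rar_flags)
#>    category n_group n_universe relative_ratio statistic df       p_value direction
#> 1 decreased     682       2000       0.000000 717.68350  1 4.269507e-158  depleted
#> 2 unchanged    1308       2000       1.510382 682.89945  1 1.564575e-150  enriched
#> 3 increased      10       2000       2.442002  14.49249  1  1.407197e-04  enriched
```

Reading the output: 3.8% of genes were planted as RA-responsive and 76 are
recovered at the strict Δlog2 > 2.5 threshold; 28.9% of those fail to
induce in the ΔSET mutant, matching the planted impairment rate. K36me3
coverage drops under DRB for most genes (the "decreased" group), but the
genes that keep their K36me3 are almost exactly the RAR-associated ones —
the relative ratio of RAR-associated genes in the decreased group is 0
(chi-square p ≈ 1e-158), the in-silico version of the claim that
RAR-associated genes resist DRB-induced K36me3 loss.

The impaired genes are also enriched for the Bivalent signature
(`enrichment_vs_background(imp$gene_id[imp$impaired], syn$signatures)`
gives relative ratio 2.85, p = 1.4e-4 in this run), the Polycomb
connection on the expression side.

An end-to-end run with file outputs and a digest manifest:

```r
run_pipeline(pipeline_config(list(output_dir = "demo_out", seed = 5,
                                  synth = list(n_genes = 500))))
```

A thin CLI wrapper ships in `inst/cli/ash36.R` (after installation:
`Rscript "$(Rscript -e 'cat(system.file("cli/ash36.R", package="ash36"))')" run-all --config config.yaml`).

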