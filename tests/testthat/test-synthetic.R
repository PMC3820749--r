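test_that("identical seed and config give byte-identical files", {
  cfg <- small_synth_config(seed = 7, n_genes = 120)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- synth_generate(cfg, out_dir = d1)$files
  f2 <- synth_generate(cfg, out_dir = d2)$files
  expect_identical(names(f1), names(f2))
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  # a different seed changes the data
  f3 <- synth_generate(small_synth_config(seed = 8, n_genes = 120),
                       out_dir = withr::local_tempdir())$files
  expect_false(identical(readLines(f1[["fpkm"]]),
                         readLines(f3[["fpkm"]])))
})

test_that("degenerate fractions propagate to downstream classifiers", {
  syn <- synth_generate(small_synth_config(seed = 2, n_genes = 150,
                                           frac_ra_responsive = 0),
                        what = "expression")
  resp <- classify_ra_responsive(syn$expression, "WT_RA", "WT")
  expect_equal(sum(resp$responsive), 0)
  syn2 <- synth_generate(small_synth_config(seed = 2, n_genes = 150,
                                            frac_rar_associated = 0,
                                            frac_ash1l_target = 1),
                         what = "peaks")
  expect_equal(nrow(syn2$peaks$rar), 0)
  expect_equal(nrow(syn2$peaks$ash1l), 150)
})

test_that("planted labels are exactly recovered by the association rules", {
  for (seed in c(3, 4)) {
    syn <- synth_generate(small_synth_config(seed = seed, n_genes = 300),
                          what = "peaks")
    tgt <- associate_peaks(syn$genes, syn$peaks$ash1l,
                           association_rule("tss_window"),
                           genome = syn$genome)
    expect_identical(tgt$associated, syn$truth$ash1l_target)
    rar <- associate_peaks(syn$genes, syn$peaks$rar,
                           association_rule("upstream_and_body"),
                           genome = syn$genome)
    expect_identical(rar$associated, syn$truth$rar_associated)
  }
})

test_that("realized coverage effects recover the configured DRB deltas", {
  cfg <- small_synth_config(seed = 6, n_genes = 600)
  syn <- synth_generate(cfg, what = "coverage")
  raw <- lapply(syn$coverage$K36me3, function(tr)
    gene_rpkm_table(tr, syn$genes))
  # raw (pre-normalization) log ratio estimates the planted per-gene delta
  lr <- log2(raw[["DRB+"]]$rpkm / raw[["DRB-"]]$rpkm)
  rar <- syn$truth$rar_associated
  se <- cfg$noise_sd_log2 * sqrt(2)
  expect_lt(abs(mean(lr[!rar]) - cfg$drb_me3_loss_log2),
            3 * se / sqrt(sum(!rar)) + 0.05)
  expect_lt(abs(mean(lr[rar]) - cfg$drb_me3_loss_rar_log2),
            3 * se / sqrt(sum(rar)) + 0.05)
})

test_that("signature labels correlate with responsiveness as configured", {
  syn <- synth_generate(small_synth_config(seed = 10, n_genes = 4000,
                                           frac_ra_responsive = 0.3),
                        what = "signatures")
  biv_resp <- mean(syn$signatures$signature[syn$truth$responsive] ==
                     "Bivalent")
  biv_base <- mean(syn$signatures$signature[!syn$truth$responsive] ==
                     "Bivalent")
  expect_gt(biv_resp, biv_base)
  # booleans are consistent with the four-state label
  expect_identical(
    as.character(classify_signature(syn$signatures$k4me3,
                                    syn$signatures$k27me3)),
    as.character(syn$signatures$signature))
})

test_that("qPCR generator: zero noise reproduces the configured means", {
  means <- expand.grid(region = c("Hoxd4_pp", "Gapdh_cd"),
                       antibody = c("K36me2", "Mel18"),
                       genotype = c("WT", "dSET"),
                       condition = c("DRB-", "DRB+"),
                       stringsAsFactors = FALSE)
  means$mean_percent_input <- runif(nrow(means), 0.05, 2)
  tab <- synth_qpcr_table(means, noise_sd = 0, n_reps = 3, seed = 4)
  expect_equal(nrow(tab), 3 * nrow(means))
  merged <- merge(tab, means)
  expect_equal(merged$percent_input, merged$mean_percent_input)
  # with noise, triplicates differ
  tab2 <- synth_qpcr_table(means, noise_sd = 0.05, seed = 4)
  expect_gt(stats::sd(tab2$percent_input[1:3]), 0)
})

test_that("phenotype generator respects penetrance 0 and binomial
           expectation", {
  z <- synth_phenotype_counts(c(wt = 0, het = 0.5), c(wt = 12, het = 36),
                              seed = 1)
  expect_equal(unname(z$n_affected["wt"]), 0)

  tot <- 0
  for (seed in 1:200)
    tot <- tot + synth_phenotype_counts(c(g = 0.42), c(g = 36),
                                        seed = seed)$n_affected[["g"]]
  expect_equal(tot / 200, 15.1, tolerance = 0.08)

  ph <- synth_phenotype_counts(c(g = 0.8), c(g = 50),
                               phenotype_probs = c(a = 0.5, b = 0.5),
                               seed = 2)
  expect_equal(sum(ph$phenotype_counts), unname(ph$n_affected))
})

test_that("restricting generated components leaves shared draws unchanged", {
  cfg <- small_synth_config(seed = 12, n_genes = 100)
  full <- synth_generate(cfg)
  only_expr <- synth_generate(cfg, what = "expression")
  expect_identical(full$expression, only_expr$expression)
  only_peaks <- synth_generate(cfg, what = "peaks")
  expect_identical(as.data.frame(full$peaks$rar),
                   as.data.frame(only_peaks$peaks$rar))
})
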