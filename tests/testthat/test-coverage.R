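test_that("region RPKM is reads / kb / million mapped", {
  tr <- coverage_track("chr1", c(0, 1000), c(500, 500), 1000, 1e7)
  expect_equal(region_rpkm(tr, "chr1", 0, 2000), 50)
  # region with no coverage
  expect_equal(region_rpkm(tr, "chr1", 5000, 6000), 0)
  expect_error(region_rpkm(tr, "chr1", 100, 100), "zero-length")
})

test_that("pro-rated bin overlap matches the per-base oracle", {
  set.seed(55)
  for (rep in 1:20) {
    chrom_size <- 10000L
    bw <- 100L
    starts <- seq(0L, chrom_size - bw, bw)
    keep <- runif(length(starts)) < 0.7  # sparse track with gaps
    bins <- data.frame(start = starts[keep],
                       count = rpois(sum(keep), 20))
    tr <- coverage_track(rep("chrT", nrow(bins)), bins$start, bins$count,
                         bw, 1e6, genome = genome_info(c(chrT = chrom_size)))
    dens <- oracle_track_density(bins, bw, chrom_size)
    for (i in 1:30) {
      s <- sample.int(chrom_size - 1L, 1)
      e <- min(s + sample.int(2000L, 1), chrom_size)
      expect_equal(track_region_reads(tr, "chrT", s, e),
                   oracle_region_reads(dens, s, e), tolerance = 1e-9)
    }
  }
})

test_that("75th-percentile normalization: linear interpolation, unit
           percentile, idempotence", {
  t1 <- data.frame(gene_id = letters[1:4], rpkm = c(1, 2, 3, 4))
  n1 <- percentile75_normalize(t1)
  expect_equal(attr(n1, "normalizer"), 3.25)
  expect_equal(n1$rpkm, c(1, 2, 3, 4) / 3.25)
  expect_equal(unname(quantile(n1$rpkm, 0.75)), 1, tolerance = 1e-9)

  # constant vector -> all ones
  tc <- data.frame(gene_id = letters[1:5], rpkm = rep(7, 5))
  expect_equal(percentile75_normalize(tc)$rpkm, rep(1, 5))

  # idempotence: normalizing twice equals normalizing once
  n2 <- percentile75_normalize(n1)
  expect_equal(n2$rpkm, n1$rpkm)
  expect_equal(attr(n2, "normalizer"), 3.25)

  expect_error(percentile75_normalize(
    data.frame(gene_id = letters[1:4], rpkm = c(0, 0, 0, 1))), "at least 4")
})

test_that("random RPKM tables have unit 75th percentile after
           normalization", {
  set.seed(66)
  for (i in 1:20) {
    x <- rlnorm(sample(10:200, 1), 0, 1.5)
    tab <- data.frame(gene_id = seq_along(x), rpkm = x)
    out <- percentile75_normalize(tab)
    expect_equal(unname(quantile(out$rpkm, 0.75, type = 7)), 1,
                 tolerance = 1e-9)
  }
})

test_that("DRB dlog2 is a pseudocounted log-ratio of normalized tables", {
  t_plus <- structure(data.frame(gene_id = c("a", "b"), rpkm = c(1, 2)),
                      normalized = TRUE)
  t_minus <- structure(data.frame(gene_id = c("b", "a"), rpkm = c(1, 1)),
                       normalized = TRUE)
  d <- drb_dlog2(t_plus, t_minus)
  expect_equal(d$dlog2[d$gene_id == "a"], 0)
  expect_equal(d$dlog2[d$gene_id == "b"], log2(2.1 / 1.1))
  # antisymmetry
  d2 <- drb_dlog2(t_minus, t_plus)
  expect_equal(d$dlog2, -d2$dlog2[match(d$gene_id, d2$gene_id)])
  # limit check: plus = 2 x minus with vanishing pseudocount -> 1
  expect_equal(drb_dlog2(t_plus, t_minus, 1e-12)$dlog2[2], 1,
               tolerance = 1e-9)
  # unnormalized input refused
  expect_error(drb_dlog2(data.frame(gene_id = "a", rpkm = 1), t_minus),
               "normalized")
})

test_that("DRB response grouping is strict at -0.6 and partitions", {
  d <- data.frame(gene_id = letters[1:6],
                  dlog2 = c(-0.7, -0.6, 0, 0.6, 0.61, -0.601))
  g <- group_by_response(d)
  expect_equal(as.character(g$group),
               c("decreased", "unchanged", "unchanged", "unchanged",
                 "increased", "decreased"))
  set.seed(8)
  r <- data.frame(gene_id = 1:500, dlog2 = rnorm(500, 0, 1))
  gr <- group_by_response(r)
  expect_false(anyNA(gr$group))          # exhaustive
  expect_equal(nrow(gr), 500)            # disjoint by construction
  expect_error(group_by_response(r, edges = c(1, -1)), "increasing")
  expect_error(group_by_response(
    data.frame(gene_id = "a", dlog2 = NaN)), "finite")
})

test_that("under-representation test matches a hand-computed 2x2", {
  groups <- data.frame(
    gene_id = letters[1:4], dlog2 = c(-1, -0.8, 0.1, 0.2),
    group = factor(c("decreased", "decreased", "unchanged", "unchanged"),
                   levels = c("decreased", "unchanged", "increased")))
  flags <- c(FALSE, FALSE, TRUE, TRUE)
  expect_warning(rep <- underrepresentation_test(groups, flags),
                 "empty group")
  dec <- rep[rep$category == "decreased", ]
  # 2x2 is [[0,2],[2,0]]: E = 1 everywhere, X^2 = 4
  expect_equal(dec$statistic, 4)
  expect_equal(dec$relative_ratio, 0)
  expect_equal(dec$direction, "depleted")
})

test_that("metagene profile is flat at log2 zero under uniform coverage", {
  gen <- genome_info(c(chrU = 2e5))
  bw <- 100
  tr <- coverage_track(rep("chrU", 2000), seq(0, 2e5 - bw, bw),
                       rep(10, 2000), bw, 1e6, genome = gen)
  genes <- gene_models(c("g1", "g2"), "chrU", c(50000, 120000),
                       c(60000, 135000), c("+", "-"), gen)
  pm <- metagene_profile(tr, genes, n_body_bins = 50, flank_bp = 2000,
                         flank_bins = 10, genome = gen)
  expect_equal(pm$log2_ratio, rep(0, 70), tolerance = 1e-9)
})

test_that("minus-strand metagene profiles mirror the plus strand", {
  gen <- genome_info(c(chrU = 1e5))
  bw <- 100
  starts <- seq(0, 1e5 - bw, bw)
  counts <- pmax(0, round(seq_along(starts) / 10))  # coverage ramp
  trp <- coverage_track(rep("chrU", length(starts)), starts, counts, bw,
                        1e6, genome = gen)
  gplus <- gene_models("gp", "chrU", 40000, 50000, "+", gen)
  gminus <- gene_models("gm", "chrU", 40000, 50000, "-", gen)
  pp <- metagene_profile(trp, gplus, n_body_bins = 20, flank_bp = 1000,
                         flank_bins = 5, genome = gen)
  pmn <- metagene_profile(trp, gminus, n_body_bins = 20, flank_bp = 1000,
                          flank_bins = 5, genome = gen)
  expect_equal(pmn$counts[1, ], rev(pp$counts[1, ]), tolerance = 1e-9)
})

test_that("metagene body bins conserve total region reads", {
  set.seed(91)
  gen <- genome_info(c(chrT = 5e4))
  bw <- 100
  starts <- seq(0, 5e4 - bw, bw)
  tr <- coverage_track(rep("chrT", length(starts)), starts,
                       rpois(length(starts), 15), bw, 1e6, genome = gen)
  g <- gene_models("g", "chrT", 12345, 23456, "+", gen)
  pm <- metagene_profile(tr, g, n_body_bins = 37, flank_bp = 500,
                         flank_bins = 5, genome = gen)
  body_cols <- 6:42
  expect_equal(sum(pm$counts[1, body_cols]),
               track_region_reads(tr, "chrT", 12345, 23456),
               tolerance = 1e-9)
  # column count fixed, short genes skipped with a warning
  tiny <- gene_models("t", "chrT", 100, 120, "+", gen)
  expect_warning(expect_error(
    metagene_profile(tr, tiny, n_body_bins = 50), "no genes"),
    "skipped")
})

test_that("gene order does not change the mean metagene profile", {
  syn <- synth_generate(small_synth_config(seed = 3, n_genes = 60),
                        what = "coverage")
  tr <- syn$coverage$K36me3[["DRB-"]]
  p1 <- metagene_profile(tr, syn$genes, n_body_bins = 25, flank_bp = 1000,
                         flank_bins = 5, genome = syn$genome)
  shuf <- syn$genes[sample(nrow(syn$genes)), ]
  p2 <- metagene_profile(tr, shuf, n_body_bins = 25, flank_bp = 1000,
                         flank_bins = 5, genome = syn$genome)
  expect_equal(p1$mean_density, p2$mean_density, tolerance = 1e-12)
  expect_equal(p1$log2_ratio, p2$log2_ratio, tolerance = 1e-12)
})

test_that("anchor profiles center on summits when available", {
  gen <- genome_info(c(chrU = 1e5))
  bw <- 100
  starts <- seq(0, 1e5 - bw, bw)
  counts <- ifelse(starts >= 50000 & starts < 50100, 100, 10)
  tr <- coverage_track(rep("chrU", length(starts)), starts, counts, bw,
                       1e6, genome = gen)
  anchors <- peak_set("chrU", 49000, 52000, summit = 50050)
  pm <- anchor_profile(tr, anchors, half_width_bp = 2000, n_bins = 40,
                       genome = gen)
  expect_equal(which.max(pm$mean_density), 20, tolerance = 1)
  expect_equal(ncol(pm$counts), 40)
})
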