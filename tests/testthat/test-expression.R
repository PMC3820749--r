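test_that("modified log2 transform has the stated closed forms", {
  expect_equal(modified_log2(0), log2(0.1))
  expect_equal(modified_log2(0.9), 0)
  expect_equal(modified_log2(7.9), 3)
  expect_error(modified_log2(-0.1), ">= 0")
  expect_error(modified_log2(NaN), "NA")
})

test_that("dlog2 is a difference of modified log2 values and antisymmetric", {
  expect_equal(dlog2(5, 5), 0)
  expect_equal(dlog2(3.9, 0.9), 2)
  set.seed(1)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(dlog2(a, b), -dlog2(b, a))
})

test_that("RA-responsive calls use a strict > 2.5 boundary", {
  pc <- 0.1
  un <- c(1, 1, 1, 0)
  ra <- c((un[1] + pc) * 2^2.5 - pc,   # exactly 2.5 -> not responsive
          (un[2] + pc) * 2^2.51 - pc,  # just above  -> responsive
          un[3],                       # unchanged
          0)                           # all-zero gene
  tab <- data.frame(gene_id = letters[1:4], UN = un, RA = ra)
  res <- classify_ra_responsive(tab, "RA", "UN")
  expect_equal(res$dlog2_ra[1], 2.5)
  expect_equal(res$responsive, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$dlog2_ra[4], 0)
  expect_false(res$eligible[4])  # never-expressed gene is ineligible
})

test_that("impairment is strict < -1 and confined to responsive genes", {
  pc <- 0.1
  wt_ra <- c(63.9, 63.9, 63.9, 5)
  mut_ra <- c(wt_ra[1],                    # unchanged -> not impaired
              (wt_ra[2] + pc) / 2 - pc,    # exactly -1 -> not impaired
              (wt_ra[3] + pc) * 2^-1.01 - pc,  # below -> impaired
              0.1)                         # not responsive
  tab <- data.frame(gene_id = letters[1:4], UN = c(1, 1, 1, 5),
                    WT_RA = wt_ra, MUT_RA = mut_ra)
  resp <- classify_ra_responsive(tab, "WT_RA", "UN")
  expect_equal(resp$responsive, c(TRUE, TRUE, TRUE, FALSE))
  imp <- classify_impaired(tab, "MUT_RA", "WT_RA", resp)
  expect_equal(imp$impaired, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(all(!imp$impaired | imp$responsive))  # impaired => responsive
})

test_that("dysregulated calls are strict, disjoint and match enumeration", {
  set.seed(3)
  pc <- 0.1
  wt <- runif(20, 0.5, 50)
  d <- seq(-2, 2, length.out = 20)
  mut <- (wt + pc) * 2^d - pc
  tab <- data.frame(gene_id = sprintf("g%02d", 1:20), WT = wt, MUT = mut)
  dys <- classify_dysregulated(tab, "MUT", "WT")
  expect_setequal(dys$down, tab$gene_id[d < -1])
  expect_setequal(dys$up, tab$gene_id[d > 1])
  expect_length(intersect(dys$down, dys$up), 0)

  flat <- data.frame(gene_id = c("a", "b"), WT = c(1, 2), MUT = c(1, 2))
  dys2 <- classify_dysregulated(flat, "MUT", "WT")
  expect_length(dys2$down, 0)
  expect_length(dys2$up, 0)

  # exactly 2-fold (dlog2 = -1) is excluded
  edge <- data.frame(gene_id = "a", WT = 3.9, MUT = (3.9 + pc) / 2 - pc)
  expect_length(classify_dysregulated(edge, "MUT", "WT")$down, 0)
})

test_that("summarize_fraction reproduces printed one-decimal percentages", {
  expect_equal(summarize_fraction(152, 543), 28.0)
  expect_equal(summarize_fraction(0, 10), 0)
  expect_equal(summarize_fraction(10, 10), 100)
  expect_equal(summarize_fraction(c("a"), c("a", "b", "c")), 33.3)
  expect_error(summarize_fraction(5, 3), "subset")
  expect_error(summarize_fraction(0, 0), "")
})

test_that("raising the responsive threshold never enlarges the called set", {
  set.seed(9)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:300),
                    UN = rlnorm(300, 1, 1), RA = rlnorm(300, 2, 1.5))
  prev <- Inf
  for (thr in c(1, 2, 2.5, 3, 4)) {
    n <- sum(classify_ra_responsive(
      tab, "RA", "UN", response_thresholds(ra_responsive_dlog2 = thr)
    )$responsive)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("common rescaling shifts dlog2 by a bounded pseudocount term", {
  # with pseudocount pc, scaling both conditions by c changes dlog2 by
  # log2((ca+pc)/(cb+pc)) - log2((a+pc)/(b+pc)); check against closed form
  pc <- 0.1
  a <- c(0.2, 1, 10); b <- c(0.5, 2, 5); cc <- 7
  got <- dlog2(cc * a, cc * b, pc) - dlog2(a, b, pc)
  want <- log2((cc * a + pc) / (cc * b + pc)) - log2((a + pc) / (b + pc))
  expect_equal(got, want)
  # and the deviation vanishes as pc -> 0
  expect_equal(dlog2(cc * a, cc * b, 1e-12), dlog2(a, b, 1e-12),
               tolerance = 1e-6)
})

test_that("responsive and impaired fractions are recovered on synthetic data", {
  # parameter recovery across seeds at the configured fractions
  fr <- 0.2; fi <- 0.28
  hits_r <- hits_i <- n_r <- 0
  n <- 800
  for (seed in 1:10) {
    syn <- synth_generate(
      small_synth_config(seed = seed, n_genes = n,
                         frac_ra_responsive = fr,
                         frac_impaired_given_responsive = fi),
      what = "expression")
    resp <- classify_ra_responsive(syn$expression, "WT_RA", "WT")
    imp <- classify_impaired(syn$expression, "dSET_RA", "WT_RA", resp)
    hits_r <- hits_r + sum(resp$responsive)
    hits_i <- hits_i + sum(imp$impaired)
    n_r <- n_r + sum(resp$responsive)
  }
  p_hat <- hits_r / (10 * n)
  se <- sqrt(fr * (1 - fr) / (10 * n))
  expect_lt(abs(p_hat - fr), 3 * se)
  p_imp <- hits_i / n_r
  se_i <- sqrt(fi * (1 - fi) / n_r)
  expect_lt(abs(p_imp - fi), 3 * se_i)
})
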