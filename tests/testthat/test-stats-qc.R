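test_that("percent input is dilution-corrected and homogeneous", {
  expect_equal(percent_input(1, 1), 100)
  expect_equal(percent_input(0.001, 1, 0.1), 0.01)
  expect_equal(percent_input(2, 4, 0.5), 25)
  set.seed(12)
  ip <- runif(20, 0.01, 5); inp <- runif(20, 1, 10)
  expect_equal(percent_input(2 * ip, inp), 2 * percent_input(ip, inp))
  # scale invariance to simultaneous rescaling
  expect_equal(percent_input(3 * ip, 3 * inp), percent_input(ip, inp))
  expect_error(percent_input(0, 1), "> 0")
  expect_error(percent_input(1, 1, 1.5), "input_fraction")
})

test_that("background subtraction clips at zero and counts clips", {
  expect_equal(as.numeric(subtract_background(0.05, 0.01)), 0.04)
  out <- subtract_background(c(0.05, 0.005, 0.02), 0.01)
  expect_equal(as.numeric(out), c(0.04, 0, 0.01))
  expect_equal(attr(out, "n_clipped"), 1)
  x <- c(0.3, 0.7)
  expect_equal(as.numeric(subtract_background(x, 0)), x)
})

test_that("replicate summaries use the n-1 denominator", {
  s <- summarize_replicates(c(2, 4))
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$mean, 3)
  expect_error(summarize_replicates(5), ">= 2")
})

test_that("pooled Student's t matches the closed form and handles
           degenerate groups", {
  a <- c(1, 2, 3); b <- a + 10
  got <- two_sample_t(a, b)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, 2 * pt(-abs(t_manual), 4), tolerance = 1e-12)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  const <- two_sample_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(const$t, 0)
  expect_equal(const$p_value, 1)
  shift <- two_sample_t(c(5, 5), c(6, 6))
  expect_equal(shift$p_value, 0)

  set.seed(23)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), 1)
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    tm <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    expect_equal(two_sample_t(x, y)$t, tm, tolerance = 1e-10)
  }
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("penetrance percentages reproduce a printed skeletal-phenotype
           table", {
  # printed counts: +/+ n=12 (0 affected), het n=36 (19 affected),
  # hom n=25 (20 affected)
  affected <- rbind(
    "fusion_arch_atlas"    = c(0,  6,  5),
    "incomplete_ventral"   = c(0,  2,  2),
    "broadened_neural_arch"= c(0, 15, 14),
    "fusion_neural_arch"   = c(0,  1,  1),
    "ectopic_rib_c7"       = c(0,  1,  3),
    "t1_to_c7"             = c(0,  1,  0),
    "abnormal_rib_cage"    = c(0,  2,  1),
    "l6_to_s1"             = c(0,  2,  0))
  colnames(affected) <- c("wt", "het", "hom")
  res <- penetrance_table(affected,
                          n_analyzed = c(wt = 12, het = 36, hom = 25),
                          n_affected = c(wt = 0, het = 19, hom = 20))
  expect_equal(unname(res$percent["fusion_arch_atlas", ]), c(0, 17, 20))
  expect_equal(unname(res$percent["incomplete_ventral", ]), c(0, 6, 8))
  expect_equal(unname(res$percent["broadened_neural_arch", ]),
               c(0, 42, 56))
  expect_equal(unname(res$percent["fusion_neural_arch", ]), c(0, 3, 4))
  expect_equal(unname(res$percent["ectopic_rib_c7", ]), c(0, 3, 12))
  expect_equal(unname(res$percent["t1_to_c7", ]), c(0, 3, 0))
  expect_equal(unname(res$percent["abnormal_rib_cage", ]), c(0, 6, 4))
  expect_equal(unname(res$percent["l6_to_s1", ]), c(0, 6, 0))
  expect_equal(unname(res$total_affected_percent), c(0, 53, 80))
  expect_equal(unname(res$total_unaffected_percent), c(100, 47, 20))
  expect_error(penetrance_table(affected, c(wt = 12, het = 36)),
               "missing")
  expect_error(
    penetrance_table(matrix(5, 1, 1, dimnames = list("p", "g")),
                     c(g = 0)), "> 0")
})

test_that("half-up rounding matches printed conventions", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)   # not banker's rounding
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(27.95, 1), 28.0)
  expect_equal(round_half_up(100 * 19 / 36), 53)
  expect_equal(round_half_up(100 * 17 / 36), 47)
})
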