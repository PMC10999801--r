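test_that("summarize_values reports mean, t-interval and range", {
  s <- summarize_values(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  # direct-formula oracle for the 95% t-interval
  half <- qt(0.975, 4) * sd(1:5) / sqrt(5)
  expect_equal(s$ci_low, 3 - half, tolerance = 1e-12)
  expect_equal(s$ci_high, 3 + half, tolerance = 1e-12)

  cst <- summarize_values(rep(4.2, 6))
  expect_equal(cst$ci_high - cst$ci_low, 0)

  one <- summarize_values(7)
  expect_equal(one$mean, 7)
  expect_false(one$ci_defined)
  expect_true(is.na(one$ci_low))
  expect_error(summarize_values(numeric(0)), "no non-missing")
})

test_that("paired_t matches the closed form and its symmetries", {
  x <- c(2, 4, 7); y <- c(1, 2, 4)   # differences 1, 2, 3
  res <- paired_t(x, y)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-10)
  # sign-flip antisymmetry
  swapped <- paired_t(y, x)
  expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  # shift invariance: adding a constant to both members changes nothing
  shifted <- paired_t(x + 11.5, y + 11.5)
  expect_equal(shifted$statistic, res$statistic, tolerance = 1e-10)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("paired sample excludes incomplete pairs and reports the count", {
  df <- tibble::tibble(a = c(1, 2, NA, 4, 5), b = c(0, NA, 1, 1, 2))
  res <- paired_t(df, a, b)
  expect_equal(res$n_used, 3)
  expect_equal(res$n_excluded, 2)
})

test_that("wilcoxon_pratt exact path: hand cases", {
  r <- wilcoxon_pratt(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$method, "WILCOXON_PRATT_EXACT")
  expect_equal(r$p_value, 0.25)       # 2 * P(W+ >= 6) = 2/8
  expect_equal(r$statistic, 6)

  zeros <- wilcoxon_pratt(c(5, 5, 5), c(5, 5, 5))
  expect_equal(zeros$p_value, 1)

  sym <- wilcoxon_pratt(c(0, 1, -1), c(0, 0, 0))
  expect_equal(sym$p_value, 1)
})

test_that("wilcoxon_pratt equals brute-force enumeration on random instances", {
  set.seed(20240917)
  for (i in 1:200) {
    m <- sample(2:10, 1)
    # integer-ish differences with ties and zeros
    d <- sample(-4:4, m, replace = TRUE)
    x <- d; y <- rep(0, m)
    res <- wilcoxon_pratt(x, y)
    oracle <- wilcoxon_pratt_bruteforce(x, y)
    expect_equal(res$statistic, oracle$statistic,
                 info = paste("instance", i))
    expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12,
                 info = paste("instance", i))
  }
})

test_that("wilcoxon_pratt switches to the labeled normal approximation", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  res <- wilcoxon_pratt(x, y, exact_cutoff = 20)
  expect_equal(res$method, "WILCOXON_PRATT_APPROX")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # same data under a huge cutoff runs exact and stays labeled so
  exact <- wilcoxon_pratt(x[1:12], y[1:12], exact_cutoff = 20)
  expect_equal(exact$method, "WILCOXON_PRATT_EXACT")
  # approximation should be close to exact for moderate m
  appr <- wilcoxon_pratt(x[1:12], y[1:12], exact_cutoff = 5)
  expect_equal(appr$p_value, exact$p_value, tolerance = 0.1)
})

test_that("bonferroni thresholds and reporting convention", {
  b6 <- bonferroni(0.05, 6)
  expect_equal(b6$threshold, 0.05 / 6, tolerance = 1e-12)
  expect_equal(b6$reported_threshold, 0.008)
  expect_equal(bonferroni(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni(0.05, 5)$threshold, 0.01)
  expect_error(bonferroni(0.05, 0), "m")
  # monotone: significant at adjusted implies significant at raw
  p <- 0.004
  expect_identical(p < bonferroni(0.05, 6)$threshold, p < 0.05 / 6)
  expect_true(all(vapply(1:10, function(m)
    bonferroni(0.05, m)$threshold <= 0.05, logical(1))))
})

test_that("frequency_table reproduces printed-percentage conventions", {
  # 43/8/1 of 52 assessed -> 82.7 / 15.4 / 1.9
  ft <- frequency_table(rep(c(1, 2, 3), c(43, 8, 1)))
  expect_equal(ft$pct, c(82.7, 15.4, 1.9))
  expect_equal(attr(ft, "n_assessed"), 52)

  # 57 + 2 of 61 with 2 not assessed -> 96.6% in the first category
  x <- c(rep(1, 57), rep(2, 2), rep(NA, 2))
  ft2 <- frequency_table(x, categories = c(0, 1, 2, 3))
  expect_equal(ft2$pct[ft2$category == 1], 96.6)
  expect_equal(attr(ft2, "n_not_assessed"), 2)

  expect_equal(frequency_table(rep(2, 9))$pct, 100)
  expect_error(frequency_table(c(NA, NA)), "no assessed")
  expect_error(frequency_table(c(1, 5), categories = c(1, 2)),
               "outside")
})

test_that("frequency_table percentages sum to 100 within rounding slack", {
  set.seed(30)
  for (i in 1:25) {
    x <- sample(0:3, sample(20:80, 1), replace = TRUE)
    ft <- frequency_table(x, categories = 0:3)
    expect_lte(abs(sum(ft$pct) - 100), 0.1 * 4)
  }
})

test_that("pairwise_comparison_report mirrors the Table-4 layout rules", {
  ids <- sprintf("b%02d", 1:52)
  long <- tidyr::expand_grid(biopsy_id = ids,
                             location = c("ILEUM", "RIGHT_COLON"),
                             stain = c("HE", "WAS", "VG"))
  long$value <- ifelse(long$stain == "HE", 0, 1)
  rep1 <- pairwise_comparison_report(long)
  expect_equal(nrow(rep1), 2 * 3)
  hw <- rep1[rep1$comparison == "HE vs WAS" & rep1$location == "ILEUM", ]
  expect_lt(hw$p_value, 0.001)
  expect_true(hw$significant)
  wv <- rep1[rep1$comparison == "WAS vs VG", ]
  expect_equal(wv$p_value, c(1, 1))
  expect_false(any(wv$significant))

  # m = 6 comparisons -> threshold reported as 0.008
  cmp6 <- list(c("HE", "WAS"), c("HE", "VG"), c("HE", "MT"),
               c("WAS", "VG"), c("WAS", "MT"), c("MT", "VG"))
  expect_equal(bonferroni(0.05, length(cmp6))$reported_threshold, 0.008)
  expect_error(
    pairwise_comparison_report(long, comparisons = list(c("HE", "MT"))),
    "missing")
})

test_that("cohort_flow applies exclusions", {
  cf <- cohort_flow(78, c(diarrhea = 16, adenocarcinoma = 1))
  expect_equal(cf$included, 61)
  expect_error(cohort_flow(10, 11), "exclude")
})
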