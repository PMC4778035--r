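test_that("descriptives match hand computations", {
  d <- describeSample(c(1, 2, 3), "mean_sem")
  expect_equal(d$mean, 2)
  expect_equal(d$sem, stats::sd(1:3) / sqrt(3), tolerance = 1e-12)
  q <- describeSample(c(1, 2, 3, 4), "median_iqr")
  expect_equal(q$median, 2.5)
  expect_equal(c(q$iqr_low, q$iqr_high), c(1.75, 3.25))
  one <- describeSample(5, "mean_sem")
  expect_true(is.na(one$sem) && one$flagged)
  singleMed <- describeSample(5, "median_iqr")
  expect_equal(singleMed$median, 5)
  expect_equal(singleMed$iqr_low, singleMed$iqr_high)
})

test_that("complete separation gives U = 0 and a small p", {
  res <- compareGroups(list(a = 1:10, b = 11:20), design = "two_indep")
  expect_equal(unname(res$statistic), 0)
  expect_lt(res$p_value, 1e-3)
})

test_that("identical groups are non-significant everywhere", {
  g <- list(a = c(1.2, 3.4, 2.2, 4.1, 2.9), b = c(1.2, 3.4, 2.2, 4.1, 2.9),
            c = c(1.2, 3.4, 2.2, 4.1, 2.9))
  res <- compareGroups(g, design = "k_indep_nonparametric",
                       posthoc = "bonferroni")
  expect_gt(res$p_value, 0.9)
  expect_true(all(res$posthoc$p_adjusted > 0.9))
  resP <- compareGroups(g, design = "k_indep_parametric",
                        posthoc = "newman_keuls")
  expect_false(any(resP$posthoc$significant))
})

test_that("Bonferroni adjustment is exactly min(1, m p)", {
  set.seed(5)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res <- compareGroups(g, design = "k_indep_nonparametric",
                       posthoc = "bonferroni")
  expect_equal(res$posthoc$p_adjusted,
               pmin(1, 3 * res$posthoc$p_raw), tolerance = 1e-15)
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p_raw))
})

test_that("all-tied rank data are flagged, not crashed", {
  expect_warning(res <- compareGroups(list(a = rep(2, 5), b = rep(2, 6)),
                                      design = "two_indep"), "tied")
  expect_true(res$tied)
  expect_equal(res$p_value, 1)
})

test_that("Newman-Keuls blocks nested comparisons under a failed span", {
  set.seed(9)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 0.05), c = rnorm(10, 0.1))
  nk <- newmanKeuls(g)
  widest <- nk[nk$span == 3, ]
  if (!widest$significant) {
    inner <- nk[nk$span == 2, ]
    expect_true(all(!inner$significant))
    expect_true(all(is.na(inner$p_value)))
  }
  ## clearly separated means are all significant
  g2 <- list(a = rnorm(10, 0, 0.1), b = rnorm(10, 5, 0.1),
             c = rnorm(10, 10, 0.1))
  nk2 <- newmanKeuls(g2)
  expect_true(all(nk2$significant))
})

test_that("rank-test type-I error is near nominal under the null", {
  set.seed(1234)
  reject <- vapply(seq_len(1000), function(i) {
    x <- rnorm(12); y <- rnorm(12)
    stats::wilcox.test(x, y)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})
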