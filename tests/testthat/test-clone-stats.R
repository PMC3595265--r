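test_that("chi-square tail matches the df-4 closed form", {
  x <- seq(0, 100, by = 0.5)
  expect_equal(chisq_sf(x, 4), exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(chisq_sf(0, 4), 1)
  expect_equal(chisq_sf(0, 7), 1)
  expect_error(chisq_sf(-1, 4), "non-negative")
  expect_error(chisq_sf(5, 0), "freedom")
})

test_that("critical values invert the tail probability", {
  expect_equal(chisq_critical(0.5, 2), 2 * log(2), tolerance = 1e-10)
  for (alpha in c(0.001, 0.01, 0.05, 0.5, 0.99)) {
    for (df in c(1, 4, 8)) {
      expect_equal(chisq_sf(chisq_critical(alpha, df), df), alpha,
                   tolerance = 1e-10)
    }
  }
  expect_error(chisq_critical(0, 4), "alpha")
  expect_error(chisq_critical(1, 4), "alpha")
})

test_that("goodness of fit accumulates (O-E)^2/E over transfers and types", {
  expect_equal(chisq_gof(data.frame(count_Z = 30, count_Y = 30),
                         0.5)$statistic, 0)
  one <- chisq_gof(data.frame(count_Z = 36, count_Y = 24), 0.5)
  expect_equal(one$statistic, 2.4)  # (36-30)^2/30 + (24-30)^2/30
  five <- chisq_gof(data.frame(count_Z = rep(36, 5), count_Y = rep(24, 5)),
                    0.5)
  expect_equal(five$statistic, 12)
  expect_equal(five$df, 4)                 # n - 1 convention
  expect_equal(five$p, chisq_sf(12, 4))
  orthodox <- chisq_gof(data.frame(count_Z = rep(36, 5),
                                   count_Y = rep(24, 5)),
                        0.5, df_convention = "orthodox")
  expect_equal(orthodox$df, 5)             # n * (types - 1)
  # asymmetric expected frequency
  g <- chisq_gof(data.frame(count_Z = 30, count_Y = 30), 0.25)
  expect_equal(g$statistic, (30 - 15)^2 / 15 + (30 - 45)^2 / 45)
})

test_that("degenerate expected frequencies are refused", {
  s <- data.frame(count_Z = 30, count_Y = 30)
  expect_error(chisq_gof(s, 0), "strictly inside")
  expect_error(chisq_gof(s, 1), "strictly inside")
  expect_error(chisq_gof(data.frame(count_Z = integer(), count_Y = integer()),
                         0.5), "at least one")
})

test_that("Fisher combination is -2 sum ln(P) on df = 2k", {
  expect_equal(fisher_combine(c(1, 1, 1, 1))$statistic, 0)
  fc <- fisher_combine(c(0.5, 0.1))
  expect_equal(fc$statistic, -2 * (log(0.5) + log(0.1)))
  expect_equal(fc$df, 4)
  expect_equal(fc$p_combined, chisq_sf(fc$statistic, 4))
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "at least one")
  # underflowed p-values are clamped, not infinite
  expect_true(is.finite(fisher_combine(c(1e-320, 0.5))$statistic))
})

test_that("Fisher combination is permutation-invariant and additive", {
  set.seed(14)
  for (rep in 1:20) {
    p1 <- runif(sample(1:5, 1))
    p2 <- runif(sample(1:5, 1))
    expect_equal(fisher_combine(sample(p1))$statistic,
                 fisher_combine(p1)$statistic)
    expect_equal(fisher_combine(c(p1, p2))$statistic,
                 fisher_combine(p1)$statistic + fisher_combine(p2)$statistic)
  }
})

test_that("significance uses strict inequality at the critical value", {
  expect_true(significance_call(18.34, 0.01, 4)$significant)
  expect_false(significance_call(11.99, 0.01, 4)$significant)
  crit <- chisq_critical(0.01, 4)
  expect_false(significance_call(crit, 0.01, 4)$significant)
  expect_true(significance_call(crit + 1e-9, 0.01, 4)$significant)
  # result objects carry their own df
  g <- chisq_gof(data.frame(count_Z = rep(45, 5), count_Y = rep(15, 5)), 0.5)
  expect_true(significance_call(g, 0.01)$significant)
  expect_error(significance_call(5, 0.01), "df")
})
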