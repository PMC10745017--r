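test_that("median and IQR use linear interpolation between order statistics", {
  s <- summarize_numeric(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  s <- summarize_numeric(5)
  expect_equal(c(s$median, s$q1, s$q3), c(5, 5, 5))
  s <- summarize_numeric(1:8)
  expect_equal(c(s$q1, s$q3), c(2.75, 6.25))
  expect_error(summarize_numeric(numeric(0)), "non-empty")
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  gc <- compare_groups(rep(c(3, 1, 4), 2), rep(c("a", "b"), each = 3))
  expect_equal(gc$statistic, 0, tolerance = 1e-12)
  expect_equal(gc$p_value, 1, tolerance = 1e-12)
  # ranks 1..6, rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 21 = 27/7
  gc <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(gc$statistic, 27 / 7, tolerance = 1e-10)
  expect_lt(gc$p_value, 0.05)
  expect_identical(gc$test_name, "kruskal_wallis")
  expect_error(compare_groups(c(1, 2), factor(c("a", "a"), c("a", "b"))),
               "non-empty|two groups")
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(81)
  x <- rnorm(30)
  g <- rep(letters[1:3], each = 10)
  h1 <- compare_groups(x, g)$statistic
  h2 <- compare_groups(exp(x), g)$statistic
  h3 <- compare_groups(rank(x), g)$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("Kruskal-Wallis holds its nominal level under the null", {
  set.seed(91)
  rejections <- 0
  for (rep in 1:2000) {
    x <- rnorm(30)
    g <- rep(1:3, each = 10)
    if (compare_groups(x, g)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 2000, 0.05 - 0.015)
  expect_lt(rejections / 2000, 0.05 + 0.015)
})

test_that("categorical comparison picks chi-square or Fisher by expected counts", {
  gc <- compare_categorical(matrix(10, 2, 2))
  expect_identical(gc$test_name, "chi_square")
  expect_equal(gc$statistic, 0, tolerance = 1e-12)
  expect_equal(gc$p_value, 1, tolerance = 1e-12)
  # an expected cell below 5 fires the exact test
  gc <- compare_categorical(matrix(c(8, 2, 1, 9), 2))
  expect_identical(gc$test_name, "fisher_exact")
  expect_error(compare_categorical(matrix(0, 2, 2)), "at least one")
})

test_that("Fisher exact p equals the hypergeometric enumeration", {
  fisher_oracle <- function(tab) {
    # sum of P(table) over all tables with the observed margins whose
    # probability does not exceed the observed one
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    a <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  # exhaustive over every 2x2 table with total at most 12
  for (a in 0:4) for (b in 0:4) for (c in 0:4) for (d in 0:4) {
    tab <- matrix(c(a, c, b, d), 2)
    if (sum(tab) == 0 || sum(tab) > 12) next
    expect_equal(suppressWarnings(stats::fisher.test(tab)$p.value),
                 fisher_oracle(tab), tolerance = 1e-10)
  }
  # random larger tables through the package interface
  set.seed(101)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 30) next
    gc <- compare_categorical(tab)
    if (gc$test_name == "fisher_exact") {
      expect_equal(gc$p_value, fisher_oracle(tab), tolerance = 1e-10)
    }
  }
})

test_that("Spearman correlation handles ranks, ties and constants", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1, tolerance = 1e-12)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1, tolerance = 1e-12)
  # d = (-1, 1, -1, 1, 0): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_correlation(1:5, c(2, 1, 4, 3, 5))$rho, 0.8,
               tolerance = 1e-12)
  set.seed(111)
  x <- rnorm(20)
  expect_equal(spearman_correlation(x, x)$rho, 1, tolerance = 1e-12)
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})
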