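test_that("Welch t has the null identity, antisymmetry, and summary consistency", {
  x <- c(1, 2, 3, 4)
  expect_identical(welch_t(x, x)$statistic, 0)
  expect_identical(welch_t(x, x)$p_value, 1)
  set.seed(61)
  a <- rnorm(28, 1, 2)
  b <- rnorm(28, 0.5, 1)
  r1 <- welch_t(a, b)
  r2 <- welch_t(b, a)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-14)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-14)
  # statistic equals the summary-statistics route applied to sample moments
  rs <- t_from_summary(group_summary(mean(a), sd(a), 28),
                       group_summary(mean(b), sd(b), 28), pooled = FALSE)
  expect_equal(r1$statistic, rs$statistic, tolerance = 1e-12)
  expect_equal(r1$df, rs$df, tolerance = 1e-12)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "undefined")
})

test_that("summary-statistics t handles pooled and Welch forms", {
  a <- group_summary(10, 2, 20)
  b <- group_summary(10, 5, 25)
  expect_identical(t_from_summary(a, b, pooled = TRUE)$statistic, 0)
  expect_identical(t_from_summary(a, b, pooled = TRUE)$df, 43)
  # with equal group sizes the pooled and Welch statistics coincide
  c1 <- group_summary(3.2, 1.1, 28)
  c2 <- group_summary(2.7, 2.9, 28)
  expect_equal(t_from_summary(c1, c2, pooled = TRUE)$statistic,
               t_from_summary(c1, c2, pooled = FALSE)$statistic,
               tolerance = 1e-12)
  expect_gt(t_from_summary(c1, c2, pooled = TRUE)$df,
            t_from_summary(c1, c2, pooled = FALSE)$df)
  expect_error(t_from_summary(group_summary(1, 0, 5), group_summary(2, 0, 5)),
               "undefined")
})

test_that("Mann-Whitney U matches enumeration and the normal approximation", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(r$statistic, 0)
  # exhaustive oracle: all C(4,2) splits of the pooled ranks
  pool <- 1:4
  splits <- combn(4, 2)
  us <- apply(splits, 2, function(ix) {
    sum(rank(pool)[ix]) - 2 * 3 / 2
  })
  p_exact <- mean(us <= min(us)) * 2
  expect_equal(r$p_value, p_exact, tolerance = 1e-12)

  ident <- mann_whitney_u(1:10, 1:10)
  expect_identical(ident$statistic, 50)         # n^2 / 2
  expect_lt(abs(ident$z), 0.05)

  # z agrees with a direct evaluation of the corrected formula
  set.seed(62)
  x <- rnorm(28)
  y <- rnorm(28, 0.8)
  r2 <- mann_whitney_u(x, y)
  rk <- rank(c(x, y))
  u1 <- sum(rk[1:28]) - 28 * 29 / 2
  dev <- u1 - 28 * 28 / 2
  z_oracle <- (dev - sign(dev) * 0.5) / sqrt(28 * 28 * 57 / 12)
  expect_equal(r2$z, z_oracle, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("chi-square on 2x2 tables is exact on hand cases and symmetric", {
  expect_identical(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  hand <- chi_square_2x2(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-12)
  tab <- matrix(c(11, 17, 14, 14), 2, 2)
  expect_equal(chi_square_2x2(tab)$statistic,
               chi_square_2x2(t(tab))$statistic, tolerance = 1e-12)
  expect_gt(chi_square_2x2(tab)$statistic,
            chi_square_2x2(tab, yates = TRUE)$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "marginals")
})

test_that("Levene detects a five-fold spread difference", {
  set.seed(63)
  hits <- vapply(1:200, function(i) {
    levene(rnorm(28, sd = 1), rnorm(28, sd = 5))$p_value < 0.01
  }, NA)
  expect_gte(mean(hits), 0.95)
  expect_error(levene(1, 1:5), "n >= 2")
})

test_that("TANOVA is null on identical groups and symmetric under relabeling", {
  set.seed(64)
  a <- matrix(rnorm(6 * 19), 6, 19)
  r <- tanova(a, a, n_permutations = 200, seed = 1)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_identical(r$p_value, 1)
  b <- a + matrix(rnorm(6 * 19, sd = 0.1), 6, 19)
  r_ab <- tanova(a, b, n_permutations = 500, seed = 2)
  r_ba <- tanova(b, a, n_permutations = 500, seed = 2)
  expect_equal(r_ab$statistic, r_ba$statistic, tolerance = 1e-12)
  expect_error(tanova(a[1, , drop = FALSE], a), ">= 2 subjects")
  expect_error(tanova(a, a, n_permutations = 0), ">= 1")
  expect_error(tanova(a, matrix(0, 6, 19)), "zero-GFP")
})

test_that("TANOVA flags planted topographic differences", {
  p1 <- make_prototype_maps(19, 2, seed = 65)
  set.seed(66)
  a <- matrix(rep(p1[1, ], each = 10), 10) + matrix(rnorm(10 * 19, sd = 0.15), 10)
  b <- matrix(rep(p1[2, ], each = 10), 10) + matrix(rnorm(10 * 19, sd = 0.15), 10)
  r <- tanova(a, b, n_permutations = 1000, seed = 3)
  expect_lte(r$p_value, 0.05)
})
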