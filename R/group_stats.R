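#' Statistical test result container
#'
#' @param test_name Name of the test.
#' @param statistic Test statistic (t, U, z, chi-squared, or W).
#' @param df Degrees of freedom, or `NULL` when undefined.
#' @param p_value Two-sided p-value.
#' @param direction_note Sign convention of the statistic.
#' @param extra Optional named list of auxiliary quantities (e.g. z for U tests).
#' @return A `stat_result`.
#' @export
stat_result <- function(test_name, statistic, df = NULL, p_value,
                        direction_note = "", extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, direction_note = direction_note), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g%s, p = %.4g\n", x$test_name, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %.4g", x$df) else "",
              x$p_value))
  if (nzchar(x$direction_note)) cat("  ", x$direction_note, "\n", sep = "")
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test; the statistic's sign follows
#' (mean(x) - mean(y)) / SE. When both samples are constant with equal
#' means the statistic is 0 with p = 1 (the degenerate null).
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return A `stat_result`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_result("welch_t", 0, df = length(x) + length(y) - 2,
                         p_value = 1,
                         direction_note = "t > 0 when mean(x) > mean(y)"))
    }
    stop("both samples constant with different means: t undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  stat_result("welch_t", unname(ht$statistic), df = unname(ht$parameter),
              p_value = ht$p.value,
              direction_note = "t > 0 when mean(x) > mean(y)")
}

#' Group summary (mean, SD, n)
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return A `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "group_summary")
}

#' Two-sample t-test from summary statistics
#'
#' Reconstructs the t statistic and two-sided p-value from published group
#' means, SDs and sizes — the reporting convention of clinical tables.
#' `pooled = TRUE` gives Student's t with df = n1 + n2 - 2;
#' `pooled = FALSE` gives Welch's t with Welch-Satterthwaite df. The sign
#' is (mean_a - mean_b) / SE.
#'
#' @param a,b `group_summary` objects (or lists with mean, sd, n).
#' @param pooled Use the pooled-variance (Student) form.
#' @return A `stat_result`.
#' @export
t_from_summary <- function(a, b, pooled = FALSE) {
  a <- do.call(group_summary, unclass(a)[c("mean", "sd", "n")])
  b <- do.call(group_summary, unclass(b)[c("mean", "sd", "n")])
  if (a$sd == 0 && b$sd == 0) stop("both SDs are zero: t undefined", call. = FALSE)
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  stat_result(if (pooled) "student_t_summary" else "welch_t_summary",
              t, df = df, p_value = 2 * stats::pt(-abs(t), df),
              direction_note = "t > 0 when mean_a > mean_b")
}

#' Mann-Whitney U test
#'
#' Reports U = min(U1, U2) with midrank ties, the z statistic from the
#' normal approximation with tie and continuity corrections (signed from
#' the first sample's U), and the two-sided p-value from
#' [stats::wilcox.test()] (exact when sample sizes permit and there are no
#' ties, otherwise the corrected normal approximation).
#'
#' @param x,y Numeric samples.
#' @return A `stat_result` with `statistic` = U and extra fields `z`, `U1`, `U2`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  nn <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  dev <- u1 - n1 * n2 / 2
  cc <- if (sigma2 > 0) sign(dev) * min(abs(dev), 0.5) else 0
  z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
  p <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE)$p.value)
  stat_result("mann_whitney_u", u, df = NULL, p_value = p,
              direction_note = "z < 0 when ranks of x fall below ranks of y",
              extra = list(z = z, U1 = u1, U2 = u2))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of counts with all marginals positive.
#' @param yates Apply Yates' continuity correction.
#' @return A `stat_result` with df = 1.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all marginals must be positive", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  stat_result("chi_square_2x2", unname(ht$statistic), df = 1,
              p_value = ht$p.value,
              direction_note = "two-sided association test")
}

#' Levene's test for equality of variances (mean-centered)
#'
#' Levene's W on absolute deviations from the group means, F-distributed
#' under the null. Two identical constant samples return the degenerate
#' W = 0, p = 1 by convention.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return A `stat_result`.
#' @export
levene <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(stat_result("levene", 0, df = length(x) + length(y) - 2,
                       p_value = 1, direction_note = "degenerate: both samples constant"))
  }
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lt <- car::leveneTest(c(x, y) ~ g, center = mean)
  stat_result("levene", lt$`F value`[1L], df = lt$Df[2L],
              p_value = lt$`Pr(>F)`[1L],
              direction_note = "W large when spreads differ")
}

#' Permutation TANOVA on scalp topographies
#'
#' Topographic analysis of variance: each subject's map is average-
#' referenced and scaled to unit GFP; the test statistic is the GFP of the
#' difference between the two groups' mean normalized maps. The null
#' distribution is built by shuffling group labels; the p-value uses the
#' add-one permutation convention.
#'
#' @param group_a_maps,group_b_maps Subjects x channels matrices (>= 2 rows each).
#' @param n_permutations Number of label shuffles (default 1000).
#' @param seed RNG seed.
#' @return A `stat_result` (statistic = observed GFP of the mean-map difference).
#' @export
tanova <- function(group_a_maps, group_b_maps, n_permutations = 1000, seed = 1) {
  a <- as.matrix(group_a_maps)
  b <- as.matrix(group_b_maps)
  if (ncol(a) != ncol(b)) stop("channel counts differ between groups", call. = FALSE)
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  norm_gfp <- function(m) {
    m <- m - rowMeans(m)
    g <- sqrt(rowMeans(m^2))
    if (any(g == 0)) stop("flat (zero-GFP) subject map", call. = FALSE)
    m / g
  }
  pooled <- rbind(norm_gfp(a), norm_gfp(b))
  na <- nrow(a)
  n <- nrow(pooled)
  stat <- function(ia) {
    d <- colMeans(pooled[ia, , drop = FALSE]) -
      colMeans(pooled[-ia, , drop = FALSE])
    sqrt(mean((d - mean(d))^2))
  }
  observed <- stat(seq_len(na))
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
    stat(sample.int(n, na)), 0))
  p <- (1 + sum(perm >= observed)) / (n_permutations + 1)
  stat_result("tanova", observed, df = NULL, p_value = min(p, 1),
              direction_note = "GFP of normalized mean-map difference",
              extra = list(n_permutations = n_permutations))
}
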