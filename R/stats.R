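#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's Z of g1) and
#' kurtosis (Anscombe-Glynn's Z of g2) into the omnibus statistic
#' `K2 = Zg1^2 + Zg2^2`, which is chi-squared with 2 degrees of freedom
#' under normality.
#'
#' @param x Numeric vector, `n >= 8` (kurtosis transform is undefined
#'   below).
#' @return A one-row tibble: `k2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  e_g2 <- -6 / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - e_g2) / sqrt(var_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  tibble::tibble(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
                 z_skew = z1, z_kurt = z2, n = n)
}

#' Summarize a sample the way its distribution warrants
#'
#' Normality is assessed with the D'Agostino-Pearson test only in samples
#' large enough (`n > 30`); samples that pass (p >= 0.05) are described as
#' mean +/- SEM, all others as median (25th, 75th percentile). Below `n = 3`
#' no summary is formed and the raw values are echoed.
#'
#' @param values Numeric vector.
#' @param alpha Normality-test level (default 0.05).
#' @return A one-row tibble: `n`, `form` (`"mean_sem"`, `"median_iqr"`, or
#'   `"raw"`), `centre`, `spread_low`, `spread_high`, `normal_p`.
#' @export
summarize_values <- function(values, alpha = 0.05) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 3) {
    return(tibble::tibble(n = n, form = "raw", centre = NA_real_,
                          spread_low = NA_real_, spread_high = NA_real_,
                          normal_p = NA_real_,
                          values = list(x)))
  }
  normal_p <- if (n > 30) dagostino_pearson(x)$p_value else NA_real_
  if (n > 30 && !is.na(normal_p) && normal_p >= alpha) {
    sem <- sd(x) / sqrt(n)
    tibble::tibble(n = n, form = "mean_sem", centre = mean(x),
                   spread_low = mean(x) - sem, spread_high = mean(x) + sem,
                   normal_p = normal_p, values = list(x))
  } else {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(n = n, form = "median_iqr", centre = q[2],
                   spread_low = q[1], spread_high = q[3],
                   normal_p = normal_p, values = list(x))
  }
}

#' Compare two groups with the test their distributions warrant
#'
#' An unpaired two-tailed t-test when both groups are large (`n > 30`) and
#' pass the D'Agostino-Pearson normality test at 0.05; otherwise the
#' Mann-Whitney-Wilcoxon rank-sum test (exact when the smaller group has 8
#' or fewer observations and there are no ties, normal approximation with
#' continuity/tie correction otherwise).
#'
#' @param a,b Numeric vectors, each `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `significant`,
#'   plus nested `summary_a`, `summary_b`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) abort("both groups need n >= 3")
  both_normal <- length(a) > 30 && length(b) > 30 &&
    dagostino_pearson(a)$p_value >= 0.05 &&
    dagostino_pearson(b)$p_value >= 0.05
  if (both_normal) {
    ht <- t.test(a, b, var.equal = FALSE)
    test <- "t_test"
  } else {
    exact <- min(length(a), length(b)) <= 8 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE))
    test <- "mann_whitney"
  }
  tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    significant = ht$p.value < alpha,
    summary_a = list(summarize_values(a)),
    summary_b = list(summarize_values(b))
  )
}

#' Compare three or more groups (Kruskal-Wallis)
#'
#' @param groups A list of numeric vectors, `k >= 3`, each non-empty.
#' @param alpha Significance level.
#' @return A one-row tibble: `test`, `statistic` (H), `df`, `p_value`,
#'   `significant`.
#' @export
compare_k_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3) {
    abort("need at least 3 groups; use compare_two_groups() for 2")
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    abort("every group must be non-empty")
  }
  ht <- kruskal.test(groups)
  tibble::tibble(
    test = "kruskal_wallis",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    significant = ht$p.value < alpha
  )
}
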