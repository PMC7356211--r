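#' Parametric and non-parametric summary of one sample
#'
#' Mean, SD, t-based 95% confidence interval
#' (`mean +/- t[0.975, n-1] * SD / sqrt(n)`), and the median with
#' interquartile range (quartiles by linear interpolation, `quantile`
#' type 7).
#'
#' @param values Numeric sample, n >= 2; missing values dropped.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `group_summary` with fields `n`, `mean`,
#'   `sd`, `ci_lower`, `ci_upper`, `median`, `iqr`.
#' @examples
#' describe_sample(c(12, 14, 15, 17))
#' @export
describe_sample <- function(values, conf_level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("insufficient data: need at least 2 non-missing values")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s,
                 ci_lower = m - half, ci_upper = m + half,
                 median = stats::median(values),
                 iqr = stats::IQR(values, type = 7)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d: mean %.3g (95%% CI %.3g, %.3g) SD %.3g; median %.3g (IQR %.3g)\n",
              x$n, x$mean, x$ci_lower, x$ci_upper, x$sd, x$median, x$iqr))
  invisible(x)
}

#' Normality assessment with the Shapiro-Wilk test and moment rules
#'
#' A sample is flagged non-normal when the Shapiro-Wilk p-value falls below
#' `alpha`, or when the sample skewness or excess kurtosis exceeds 3 in
#' magnitude (both in the SPSS convention, `e1071` type 2).
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return List: `normal` (logical), `shapiro_p`, `skewness`, `kurtosis`.
#' @export
normality_flag <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("insufficient data: need at least 3 values")
  # shapiro.test caps n at 5000; subsample deterministically beyond that
  sw <- if (length(values) > 5000)
    stats::shapiro.test(values[seq(1, length(values), length.out = 5000)])
  else stats::shapiro.test(values)
  sk <- e1071::skewness(values, type = 2)
  ku <- e1071::kurtosis(values, type = 2)
  list(normal = sw$p.value >= alpha && abs(sk) <= 3 && abs(ku) <= 3,
       shapiro_p = sw$p.value, skewness = sk, kurtosis = ku)
}

#' Two-sample t-test from raw samples or summary moments
#'
#' Pooled (Student) or Welch two-sided t-test. Each group may be given as a
#' raw numeric vector or as a summary `list(mean =, sd =, n =)`; both forms
#' give identical results when the raw sample has exactly those moments.
#' With zero pooled variance the statistic is 0 (p = 1) for equal means and
#' an error for unequal means (infinite t).
#'
#' @param a,b Numeric vectors, or lists/named vectors with `mean`, `sd`, `n`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List: `t`, `df`, `p`, `mean_diff`, `variant`.
#' @examples
#' two_sample_t(list(mean = 38.9, sd = 11.7, n = 29),
#'              list(mean = 41.2, sd = 11.0, n = 21))  # p = 0.49
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  mom <- function(x) {
    if (is.list(x) || !is.null(names(x))) {
      x <- as.list(x)
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(m = as.numeric(x$mean), s = as.numeric(x$sd), n = as.numeric(x$n))
    } else {
      x <- x[!is.na(x)]
      list(m = mean(x), s = stats::sd(x), n = length(x))
    }
  }
  A <- mom(a); B <- mom(b)
  if (A$n < 2 || B$n < 2) stop("each group needs n >= 2")
  d <- A$m - B$m
  if (variant == "pooled") {
    sp2 <- ((A$n - 1) * A$s^2 + (B$n - 1) * B$s^2) / (A$n + B$n - 2)
    df <- A$n + B$n - 2
    se <- sqrt(sp2 * (1 / A$n + 1 / B$n))
  } else {
    v1 <- A$s^2 / A$n; v2 <- B$s^2 / B$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (A$n - 1) + v2^2 / (B$n - 1))
  }
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1, mean_diff = 0, variant = variant))
    stop("zero pooled variance with unequal means: t statistic is infinite")
  }
  t <- d / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = d, variant = variant)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by complete enumeration of the null distribution of U
#' when `n1 + n2 <= 20` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The method
#' actually used is reported.
#'
#' @param a,b Numeric samples.
#' @return List: `U` (statistic for sample `a`), `p`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("each sample needs n >= 1")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n1 + n2 <= 20 && !ties) {
    # exact null distribution of the rank sum via the standard recursion
    cnt <- .u_null_counts(n1, n2)
    total <- choose(n1 + n2, n1)
    u_obs <- min(U, n1 * n2 - U)   # two-sided: fold the distribution
    p <- min(1, 2 * sum(cnt[seq_len(u_obs + 1L)]) / total)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(a, b))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 == 0) return(list(U = U, p = 1, method = "normal_approx"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity correction
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal_approx")
  }
}

# counts of the exact null distribution of U for sample sizes m, n:
# cnt[u + 1] = number of arrangements with statistic u, u = 0..m*n.
# These are the coefficients of the Gaussian binomial [m+n choose m]_q,
# built up as prod_i (1 - q^(n+i)) / (1 - q^i).
.u_null_counts <- function(m, n) {
  coefs <- 1
  for (i in seq_len(m)) {
    num <- rep(0, n * m + 1)
    num[1] <- 1
    if (n + i <= n * m) num[n + i + 1] <- -1
    coefs <- .poly_mult(coefs, num, n * m + 1)
    coefs <- .poly_divide_one_minus_qk(coefs, i)
  }
  coefs
}

.poly_mult <- function(a, b, len) {
  out <- rep(0, len)
  for (i in seq_along(a)) if (a[i] != 0)
    for (j in seq_along(b)) if (b[j] != 0) {
      k <- i + j - 1
      if (k <= len) out[k] <- out[k] + a[i] * b[j]
    }
  out
}

# divide polynomial by (1 - q^k), exact for Gaussian binomials
.poly_divide_one_minus_qk <- function(a, k) {
  out <- a
  for (i in seq_along(out)) if (i + k <= length(out))
    out[i + k] <- out[i + k] + out[i]
  out
}

#' Paired t-test and Wilcoxon signed-rank test for limb comparisons
#'
#' The paired t-test is the one-sample t on the within-subject differences.
#' The signed-rank test drops zero differences (Wilcoxon's original
#' convention), ranks the absolute differences with average ranks for
#' ties, and reports `W`, the rank sum of the positive differences; the
#' p-value comes from `stats::wilcox.test` on the same differences (exact
#' when free of ties and small, normal approximation otherwise).
#'
#' @param limb1,limb2 Paired numeric samples of equal length.
#' @return List with `t` (`statistic`, `df`, `p`) and `wilcoxon`
#'   (`W`, `p`, `n_nonzero`).
#' @export
paired_tests <- function(limb1, limb2) {
  stopifnot(length(limb1) == length(limb2))
  keep <- !(is.na(limb1) | is.na(limb2))
  d <- limb2[keep] - limb1[keep]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) tt <- list(statistic = 0, df = length(d) - 1, p = 1)
    else stop("all differences identical and non-zero: paired t is infinite")
  } else {
    tstat <- mean(d) / (sd_d / sqrt(length(d)))
    tt <- list(statistic = tstat, df = length(d) - 1,
               p = 2 * stats::pt(-abs(tstat), length(d) - 1))
  }
  dz <- d[d != 0]
  if (length(dz) < 1L)
    stop("Wilcoxon signed-rank undefined: all paired differences are zero")
  rk <- rank(abs(dz))
  W <- sum(rk[dz > 0])
  wp <- suppressWarnings(stats::wilcox.test(dz, mu = 0)$p.value)
  list(t = tt, wilcoxon = list(W = W, p = wp, n_nonzero = length(dz)))
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rho on average ranks; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df; confidence
#' interval by Fisher's z transform, `tanh(atanh(rho) +/- z* / sqrt(n-3))`.
#'
#' @param x,y Paired numeric samples, n >= 4.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `rho`, `p`, `ci_lower`, `ci_upper`, `n`.
#' @export
spearman_rho <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  ci <- spearman_fisher_ci(rho, n, conf_level)
  list(rho = rho, p = p, ci_lower = ci[1], ci_upper = ci[2], n = n)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' `tanh(atanh(rho) +/- z* / sqrt(n - 3))`.
#'
#' @param rho Correlation estimate in (-1, 1).
#' @param n Number of pairs (>= 4).
#' @param conf_level Confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @examples
#' spearman_fisher_ci(0.460, 29)  # upper bound 0.707
#' @export
spearman_fisher_ci <- function(rho, n, conf_level = 0.95) {
  stopifnot(n >= 4, abs(rho) <= 1)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  tanh(atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * zc / sqrt(n - 3))
}

#' Intra-individual percent change between limbs
#'
#' `100 * (limb2 - limb1) / limb1` per subject; the group value is the mean
#' of per-subject percent changes.
#'
#' @param limb1,limb2 Numeric values or paired vectors; `limb1` must be
#'   non-zero.
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(limb1, limb2) {
  stopifnot(length(limb1) == length(limb2))
  if (any(limb1 == 0, na.rm = TRUE))
    stop("undefined percent change: first-limb value is zero")
  100 * (limb2 - limb1) / limb1
}
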