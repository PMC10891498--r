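# The paired-method comparison primitives: Wilcoxon signed rank (normal
# approximation), McNemar, Spearman rank correlation, and Bland-Altman
# limits of agreement. These are implemented here with explicitly stated
# conventions (zero handling, tie correction, continuity correction)
# because relative-validity results depend on exactly these choices; the
# test suite cross-checks them against independent implementations and
# exact enumeration.

#' Wilcoxon signed rank test, normal approximation
#'
#' Tests whether paired differences are symmetric around zero. Zero
#' differences are dropped (classic Wilcoxon convention; the statistics
#' suite behind any given published analysis may differ, which is why the
#' convention is explicit and configurable). Tied absolute differences
#' share average ranks and the null variance is tie-corrected. The
#' two-sided p-value comes from the normal approximation. The exact null
#' distribution is discrete at small n, so against exact enumeration of
#' all sign assignments the approximation can deviate by up to about 0.2
#' at n = 5-7 non-zero differences and up to about 0.1 at n = 8-10; the
#' error vanishes as n grows.
#'
#' @param differences Numeric vector of paired differences.
#' @param zero_method `"drop"` (default) discards zero differences;
#'   `"pratt"` ranks them but excludes them from the statistic.
#' @param correct Apply a 0.5 continuity correction, default `FALSE`.
#' @return One-row tibble: `n_nonzero`, `statistic` (sum of positive
#'   ranks), `z`, `p_value`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(-3, -1, 1, 3))$p_value # symmetric: 1
wilcoxon_signed_rank <- function(differences,
                                 zero_method = c("drop", "pratt"),
                                 correct = FALSE) {
  zero_method <- match.arg(zero_method)
  d <- differences[!is.na(differences)]
  if (length(d) == 0) abort("no non-missing differences")
  if (all(d == 0)) {
    warn("all differences are zero; p-value set to 1")
    return(tibble(n_nonzero = 0L, statistic = 0, z = 0, p_value = 1))
  }
  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
    keep <- rep(TRUE, length(d))
  } else {
    r <- rank(abs(d))
    keep <- d != 0
  }
  n_used <- sum(keep)
  w_plus <- sum(r[keep][d[keep] > 0])
  if (zero_method == "drop") {
    e_w <- n_used * (n_used + 1) / 4
    v_w <- n_used * (n_used + 1) * (2 * n_used + 1) / 24
  } else {
    # Pratt: zeros occupy the lowest ranks but contribute nothing.
    n_all <- length(d)
    n0 <- n_all - n_used
    e_w <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
    v_w <- (n_all * (n_all + 1) * (2 * n_all + 1) -
      n0 * (n0 + 1) * (2 * n0 + 1)) / 24
  }
  ties <- table(r[keep])
  v_w <- v_w - sum(ties^3 - ties) / 48
  if (v_w <= 0) {
    warn("degenerate variance in signed rank test; p-value set to 1")
    return(tibble(n_nonzero = n_used, statistic = w_plus, z = 0, p_value = 1))
  }
  num <- w_plus - e_w
  if (correct) num <- num - sign(num) * 0.5
  z <- num / sqrt(v_w)
  tibble(
    n_nonzero = as.integer(n_used), statistic = w_plus, z = z,
    p_value = min(1, 2 * pnorm(-abs(z)))
  )
}

#' McNemar test on paired consumer indicators
#'
#' Tests whether the probability of being a consumer differs between two
#' methods, using the discordant pairs b (consumer under A only) and c
#' (consumer under B only). With enough discordant pairs the chi-squared
#' statistic (b - c)^2 / (b + c) on 1 df is used (continuity correction
#' configurable, default off); below `exact_threshold` discordant pairs an
#' exact two-sided binomial test replaces the approximation.
#'
#' @param consumer_a,consumer_b Logical vectors of equal length.
#' @param correct Apply the continuity correction `(|b-c|-1)^2 / (b+c)`.
#' @param exact_threshold Use the exact binomial p when `b + c` is below
#'   this count, default 10.
#' @return One-row tibble: `b`, `c`, `statistic` (NA for the exact
#'   branch), `p_value`, `method`.
#' @export
mcnemar <- function(consumer_a, consumer_b, correct = FALSE,
                    exact_threshold = 10) {
  if (length(consumer_a) != length(consumer_b)) {
    abort("paired vectors must have equal length")
  }
  b <- sum(consumer_a & !consumer_b)
  cc <- sum(!consumer_a & consumer_b)
  if (b + cc == 0) {
    warn("no discordant pairs; p-value set to 1")
    return(tibble(
      b = 0L, c = 0L, statistic = NA_real_, p_value = 1, method = "degenerate"
    ))
  }
  if (b + cc < exact_threshold) {
    p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
    return(tibble(
      b = as.integer(b), c = as.integer(cc), statistic = NA_real_,
      p_value = p, method = "exact_binomial"
    ))
  }
  num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
  stat <- num / (b + cc)
  tibble(
    b = as.integer(b), c = as.integer(cc), statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = "chi_squared"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of average (tie-aware) ranks. A constant vector has
#' no rank ordering, so the coefficient is undefined and returned as `NA`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return The correlation coefficient, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("spearman correlation needs n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("constant vector; spearman correlation undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Bland-Altman limits of agreement
#'
#' Differences x - y against per-pair means; the 95% limits of agreement
#' are the mean difference plus/minus 1.96 sample standard deviations
#' (n - 1 denominator).
#'
#' @param x,y Paired measurements (method A, method B), n >= 2.
#' @return An object of class `dv_bland_altman`: a list with
#'   `mean_difference`, `sd_difference`, `loa_low`, `loa_high`, `n`, and
#'   the per-pair `data` tibble. Supports [generics::tidy()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' tidy(ba)
bland_altman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2) abort("bland_altman needs at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  out <- list(
    mean_difference = m, sd_difference = s,
    loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
    n = length(d),
    data = tibble(pair_mean = (x + y) / 2, difference = d)
  )
  class(out) <- "dv_bland_altman"
  out
}

#' @export
print.dv_bland_altman <- function(x, ...) {
  cat(
    "Bland-Altman agreement (n = ", x$n, ")\n",
    "  mean difference: ", format(x$mean_difference, digits = 4), "\n",
    "  95% limits of agreement: [",
    format(x$loa_low, digits = 4), ", ",
    format(x$loa_high, digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Relevance flag for a paired difference
#'
#' A difference between methods counts as relevant when it is both
#' statistically significant (p below `alpha`) and practically large: the
#' absolute difference in medians exceeds `threshold` (default 10%) of the
#' reference-method median. A zero reference median makes the relative
#' rule non-evaluable, flagged as `NA`. Vectorized over rows.
#'
#' @param median_a Test-method medians.
#' @param median_b Reference-method medians.
#' @param p_value Paired-test p-values.
#' @param alpha Significance level, default 0.05 (strict `<`).
#' @param threshold Relative difference threshold, default 0.10 (strict `>`).
#' @return A tibble with columns `relevant` (logical, `NA` when not
#'   evaluable) and `direction` (`method_a_lower`, `method_a_higher`,
#'   `none`).
#' @export
#' @examples
#' relevance_flag(83, 130, 0.005) # relevant, method_a_lower
relevance_flag <- function(median_a, median_b, p_value, alpha = 0.05,
                           threshold = 0.10) {
  relevant <- if_else(
    median_b == 0,
    NA,
    p_value < alpha & abs(median_a - median_b) > threshold * median_b
  )
  tibble(
    relevant = relevant,
    direction = case_when(
      !is.na(relevant) & relevant & median_a < median_b ~ "method_a_lower",
      !is.na(relevant) & relevant & median_a > median_b ~ "method_a_higher",
      TRUE ~ "none"
    )
  )
}

#' Median of a set of correlation coefficients
#'
#' @param rhos Numeric vector of correlation coefficients (at least one);
#'   missing values are ignored.
#' @return The median (mean of the central pair for even counts).
#' @export
median_of_correlations <- function(rhos) {
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0) abort("no correlation coefficients supplied")
  median(rhos)
}
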