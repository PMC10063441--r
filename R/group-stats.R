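#' Descriptive group summary (mean, s.e.m., median, n)
#'
#' @param values Numeric vector, one value per animal.
#' @return One-row tibble with `mean`, `sem`, `median`, `n`; `sem` is the
#'   sample SD over the square root of n and is `NA` for a single value.
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("at least one finite value required")
  tibble::tibble(
    mean = mean(values),
    sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
    median = median(values),
    n = n
  )
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis transforms into the omnibus
#' statistic `K2 = Z1(g1)^2 + Z2(g2)^2`, referred to a chi-square with
#' 2 degrees of freedom. Moments use the population (biased) convention
#' of the original test. Requires at least 8 observations.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (K2) and `p_value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_not_evaluable("D'Agostino-Pearson test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop_not_evaluable("zero variance: normality not evaluable")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2          # non-excess kurtosis

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (term1 - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

comparison_result <- function(test_used, statistic, p_value,
                              pairwise = NULL, alpha = 0.05, extra = list()) {
  structure(c(list(test_used = test_used, statistic = statistic,
                   p_value = p_value, pairwise = pairwise,
                   significant = is.finite(p_value) && p_value < alpha),
              extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g%s\n",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Each group is tested for normality with the D'Agostino-Pearson test at
#' `normality_alpha`; if both pass, a two-sided Student's t-test is used,
#' otherwise the two-sided Mann-Whitney test. For groups below the
#' normality test's minimum of 8 observations the gate cannot be applied
#' and the procedure falls back to Mann-Whitney (the conservative choice).
#'
#' @param x,y Numeric vectors, each with at least 3 values.
#' @param normality_alpha Gate significance level.
#' @param var_equal Passed to [stats::t.test()] (pooled-variance t).
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result` with `test_used` of `"t"` or
#'   `"mann_whitney"`.
#' @export
compare_two <- function(x, y, normality_alpha = 0.05, var_equal = TRUE,
                        alpha = 0.05) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop_not_evaluable("two-group comparison needs n >= 3 per group")
  }
  gate <- NULL
  normal <- FALSE
  if (length(x) >= 8 && length(y) >= 8) {
    gate <- tryCatch(
      c(dagostino_pearson(x)$p_value, dagostino_pearson(y)$p_value),
      murineEP_not_evaluable = function(e) NULL
    )
    normal <- !is.null(gate) && all(gate >= normality_alpha)
  }
  if (normal) {
    tt <- t.test(x, y, var.equal = var_equal)
    comparison_result("t", unname(tt$statistic), tt$p.value, alpha = alpha,
                      extra = list(normality_p = gate))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    comparison_result("mann_whitney", unname(wt$statistic), wt$p.value,
                      alpha = alpha, extra = list(normality_p = gate))
  }
}

#' Three-group comparison: one-way ANOVA with Tukey's HSD
#'
#' @param groups Named list of three numeric vectors (n >= 3 each).
#' @param alpha Significance level.
#' @return A `comparison_result` with a `pairwise` tibble of Tukey
#'   adjusted p values.
#' @export
compare_three <- function(groups, alpha = 0.05) {
  if (length(groups) != 3) stop("exactly three groups required")
  if (is.null(names(groups))) names(groups) <- paste0("g", 1:3)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop_not_evaluable("each group needs n >= 3")
  }
  values <- unlist(groups, use.names = FALSE)
  if (sd(values) == 0) {
    stop_not_evaluable("all values identical: ANOVA not evaluable")
  }
  d <- data.frame(
    value = values,
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pw <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    adjusted_p = tk[, "p adj"]
  )
  comparison_result("anova_tukey", an[["F value"]][1], an[["Pr(>F)"]][1],
                    pairwise = pw, alpha = alpha)
}

#' Chi-square comparison of per-group proportions
#'
#' Pearson chi-square on the k x 2 contingency table of flagged versus
#' unflagged animals (or successful versus failed maneuvers), without
#' continuity correction by default.
#'
#' @param flagged,total Integer vectors: flagged count and group size per
#'   group.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @param alpha Significance level.
#' @return A `comparison_result`.
#' @export
compare_proportions <- function(flagged, total, correct = FALSE,
                                alpha = 0.05) {
  if (length(flagged) != length(total) || length(flagged) < 2) {
    stop("need flagged/total counts for at least two groups")
  }
  if (any(total < 1)) stop("zero-total group")
  if (any(flagged > total) || any(flagged < 0)) stop("invalid counts")
  tab <- cbind(flagged = flagged, unflagged = total - flagged)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  comparison_result("chi_square", unname(ct$statistic), ct$p.value,
                    alpha = alpha)
}
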