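# Group-comparison statistics used in the figure-level analyses. Implemented
# as explicit closed forms so the pipeline's numerical surface is directly
# testable; cross-checked in the test suite against stats::t.test /
# stats::oneway.test and permutation oracles.

#' Significance stars
#'
#' The star convention used throughout: `ns` for p > 0.05, `*` p < 0.05,
#' `**` p < 0.005, `***` p < 0.0005.
#'
#' @param p A p-value in \[0, 1\].
#' @return Character label.
#' @export
significance_stars <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.0005) "***" else if (p < 0.005) "**" else if (p < 0.05) "*"
  else "ns"
}

group_comparison <- function(test, groups, statistic, df, p) {
  p <- min(max(p, 0), 1)
  structure(list(test = test, groups = groups, statistic = statistic,
                 df = df, p_value = p, stars = significance_stars(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' Two-tailed Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' When both groups have zero variance and equal means the comparison is
#' vacuous and `p = 1` by convention.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param labels Length-2 group labels.
#' @return A `group_comparison` with fields `statistic` (t), `df`,
#'   `p_value`, `stars` and a per-group summary data.frame.
#' @export
welch_ttest <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  groups <- data.frame(label = labels, n = c(na, nb),
                       mean = c(mean(a), mean(b)),
                       sd = c(sqrt(va), sqrt(vb)), stringsAsFactors = FALSE)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    equal <- mean(a) == mean(b)
    return(group_comparison("Welch's t-test", groups,
                            statistic = if (equal) 0 else Inf,
                            df = NA_real_, p = if (equal) 1 else 0))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  group_comparison("Welch's t-test", groups, tstat, df, p)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test of equal group means. Zero between-group
#' sum of squares gives `F = 0`, `p = 1`; zero within-group variance with
#' distinct means gives `F = Inf`, `p = 0`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return A `group_comparison` with the F `statistic`, `df` (numerator,
#'   denominator), `p_value` and `stars`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- sprintf("group%d", seq_along(groups))
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  gmean <- sum(ns * means) / sum(ns)
  ss_between <- sum(ns * (means - gmean)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- sum(ns) - length(groups)
  summary <- data.frame(label = labels, n = ns, mean = means,
                        sd = vapply(groups, stats::sd, 0),
                        stringsAsFactors = FALSE)
  if (ss_between == 0) {
    return(group_comparison("one-way ANOVA", summary, 0, c(df1, df2), 1))
  }
  if (ss_within == 0) {
    return(group_comparison("one-way ANOVA", summary, Inf, c(df1, df2), 0))
  }
  fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  group_comparison("one-way ANOVA", summary, fstat, c(df1, df2), p)
}
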