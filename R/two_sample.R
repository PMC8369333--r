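#' Two-sample summary statistics
#'
#' Collapse two numeric samples to the sufficient statistics used by every
#' test in this package: per-group size, mean and standard deviation
#' (denominator `n - 1`).
#'
#' @param group1,group2 Numeric vectors with at least two finite values each.
#' @return An object of class `two_sample_summary` with fields `n1`, `n2`,
#'   `mean1`, `mean2`, `sd1`, `sd2`.
#' @seealso [two_sample_summary()] to build one directly from published
#'   summary statistics.
#' @examples
#' summarize(c(1, 2, 3), c(2, 4, 6))
#' @export
summarize <- function(group1, group2) {
  check_group <- function(g, name) {
    if (!is.numeric(g)) stop("'", name, "' must be numeric", call. = FALSE)
    if (length(g) < 2) {
      stop("'", name, "' needs at least 2 values", call. = FALSE)
    }
    if (!all(is.finite(g))) {
      stop("'", name, "' contains non-finite values", call. = FALSE)
    }
  }
  check_group(group1, "group1")
  check_group(group2, "group2")
  two_sample_summary(
    n1 = length(group1), mean1 = mean(group1), sd1 = stats::sd(group1),
    n2 = length(group2), mean2 = mean(group2), sd2 = stats::sd(group2)
  )
}

#' Construct a two-sample summary from published statistics
#'
#' @param n1,n2 Group sizes (integers, at least 2).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (strictly positive).
#' @return An object of class `two_sample_summary`.
#' @export
two_sample_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (!(n1 >= 2 && n2 >= 2)) stop("group sizes must be >= 2", call. = FALSE)
  vals <- c(n1, mean1, sd1, n2, mean2, sd2)
  if (!all(is.finite(vals))) stop("summary values must be finite", call. = FALSE)
  if (!(sd1 > 0 && sd2 > 0)) {
    stop("standard deviations must be > 0 (degenerate, constant group)",
         call. = FALSE)
  }
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2),
         mean1 = mean1, mean2 = mean2, sd1 = sd1, sd2 = sd2),
    class = "two_sample_summary"
  )
}

#' @export
print.two_sample_summary <- function(x, ...) {
  cat("Two-sample summary\n")
  cat(sprintf("  group 1: n = %d, mean = %.6g, sd = %.6g\n",
              x$n1, x$mean1, x$sd1))
  cat(sprintf("  group 2: n = %d, mean = %.6g, sd = %.6g\n",
              x$n2, x$mean2, x$sd2))
  invisible(x)
}

.check_summary <- function(s) {
  if (!inherits(s, "two_sample_summary")) {
    stop("expected a 'two_sample_summary' object", call. = FALSE)
  }
  s
}

#' Pooled (Student) two-sample t-statistic
#'
#' The equal-variance t-statistic underlying the Bayes-factor models in this
#' package: all interval Bayes factors condition on the pooled t, its degrees
#' of freedom `n1 + n2 - 2`, and the effective sample size
#' `n1 * n2 / (n1 + n2)` which scales the effect size into the noncentrality
#' parameter.
#'
#' @param s A [two_sample_summary()].
#' @return An object of class `t_test_result` with fields `t`, `df`,
#'   `effective_n`, `p_two_sided` and `kind`.
#' @export
pooled_t <- function(s) {
  s <- .check_summary(s)
  df <- s$n1 + s$n2 - 2
  sp2 <- ((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) / df
  se <- sqrt(sp2 * (1 / s$n1 + 1 / s$n2))
  tstat <- (s$mean1 - s$mean2) / se
  t_test_result(tstat, df, s, kind = "pooled")
}

#' Welch two-sample t-statistic
#'
#' Unequal-variance t-statistic with Welch--Satterthwaite degrees of freedom.
#' Used by [tost()] and for descriptive output; the Bayes-factor models use
#' [pooled_t()] (their derivation assumes a common standard deviation).
#'
#' @inheritParams pooled_t
#' @return An object of class `t_test_result`.
#' @export
welch_t <- function(s) {
  s <- .check_summary(s)
  v1 <- s$sd1^2 / s$n1
  v2 <- s$sd2^2 / s$n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s$n1 - 1) + v2^2 / (s$n2 - 1))
  tstat <- (s$mean1 - s$mean2) / se
  t_test_result(tstat, df, s, kind = "welch")
}

t_test_result <- function(tstat, df, s, kind) {
  structure(
    list(t = tstat, df = df,
         effective_n = s$n1 * s$n2 / (s$n1 + s$n2),
         p_two_sided = 2 * stats::pt(-abs(tstat), df),
         kind = kind),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.4f, df = %.2f, p = %.4g (n_delta = %.2f)\n",
              x$kind, x$t, x$df, x$p_two_sided, x$effective_n))
  invisible(x)
}

#' Standardized effect size for two groups with unequal variances
#'
#' `delta = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`, the Cohen-type
#' standardized mean difference with the root-mean-square of the two
#' standard deviations as standardizer.
#'
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (> 0).
#' @return The standardized effect size, a single number.
#' @examples
#' cohen_delta(2.89, 1.84, 3.5, 1.56)   # approximately -0.357
#' @export
cohen_delta <- function(mean1, sd1, mean2, sd2) {
  if (!(sd1 > 0 && sd2 > 0)) stop("sds must be > 0", call. = FALSE)
  (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Equivalence region
#'
#' An interval of parameter values treated as practically equivalent to no
#' effect. Regions on the `standardized_effect` scale apply to the effect
#' size delta (the Bayes-factor and ROPE tests); regions on the
#' `raw_difference` scale apply to the raw mean difference (the [tost()]
#' procedure).
#'
#' @param lower,upper Region boundaries, `lower < upper`.
#' @param scale `"standardized_effect"` (default) or `"raw_difference"`.
#' @return An object of class `equivalence_region`.
#' @examples
#' equivalence_region(-0.1, 0.1)
#' @export
equivalence_region <- function(lower, upper,
                               scale = c("standardized_effect",
                                         "raw_difference")) {
  scale <- match.arg(scale)
  if (!is.finite(lower) || !is.finite(upper) || !(lower < upper)) {
    stop("need finite region bounds with lower < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, scale = scale),
            class = "equivalence_region")
}

#' @export
print.equivalence_region <- function(x, ...) {
  cat(sprintf("equivalence region [%g, %g] on the %s scale\n",
              x$lower, x$upper, x$scale))
  invisible(x)
}

.check_region <- function(region) {
  if (!inherits(region, "equivalence_region")) {
    stop("expected an 'equivalence_region' object", call. = FALSE)
  }
  region
}

#' Frequentist TOST equivalence test
#'
#' Two one-sided Welch tests of `H01: theta < lower` and `H02: theta > upper`
#' for the raw mean difference `theta = mean1 - mean2`. Equivalence is
#' established when both one-sided null hypotheses are rejected at level
#' `alpha` (strict `p < alpha` on both sides).
#'
#' @param s A [two_sample_summary()].
#' @param region An [equivalence_region()] on the `raw_difference` scale.
#' @param alpha One-sided significance level, in (0, 1).
#' @return A list with elements `p_lower`, `p_upper`, `significant_lower`,
#'   `significant_upper` and `equivalence_established`.
#' @export
tost <- function(s, region, alpha = 0.05) {
  s <- .check_summary(s)
  region <- .check_region(region)
  if (region$scale != "raw_difference") {
    stop("tost needs a region on the raw_difference scale", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  v1 <- s$sd1^2 / s$n1
  v2 <- s$sd2^2 / s$n2
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s$n1 - 1) + v2^2 / (s$n2 - 1))
  diff <- s$mean1 - s$mean2
  # reject theta < lower when the difference is significantly above lower
  p_lower <- stats::pt((diff - region$lower) / se, df, lower.tail = FALSE)
  # reject theta > upper when the difference is significantly below upper
  p_upper <- stats::pt((diff - region$upper) / se, df, lower.tail = TRUE)
  sig_l <- p_lower < alpha
  sig_u <- p_upper < alpha
  list(p_lower = p_lower, p_upper = p_upper,
       significant_lower = sig_l, significant_upper = sig_u,
       equivalence_established = sig_l && sig_u)
}

#' Read two-group data from a CSV file
#'
#' Supports two layouts: wide (two named numeric columns, one per group) and
#' long (a value column plus a group-label column with exactly two levels).
#' The file must use `.` as decimal separator.
#'
#' @param path Path to the CSV file.
#' @param col1,col2 Column names of the two groups (wide layout).
#' @param value_col,group_col Value and group-label column names (long
#'   layout). Supply either `col1`/`col2` or `value_col`/`group_col`.
#' @return A list with numeric vectors `group1` and `group2` (long layout:
#'   groups in the sort order of the labels).
#' @export
read_two_group_csv <- function(path, col1 = NULL, col2 = NULL,
                               value_col = NULL, group_col = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col1) && !is.null(col2)) {
    for (cl in c(col1, col2)) {
      if (!cl %in% names(dat)) {
        stop("column '", cl, "' not found in ", path, call. = FALSE)
      }
    }
    g1 <- dat[[col1]][!is.na(dat[[col1]])]
    g2 <- dat[[col2]][!is.na(dat[[col2]])]
  } else if (!is.null(value_col) && !is.null(group_col)) {
    for (cl in c(value_col, group_col)) {
      if (!cl %in% names(dat)) {
        stop("column '", cl, "' not found in ", path, call. = FALSE)
      }
    }
    labs <- sort(unique(dat[[group_col]]))
    if (length(labs) != 2) {
      stop("group column must have exactly 2 levels, found ", length(labs),
           call. = FALSE)
    }
    g1 <- dat[[value_col]][dat[[group_col]] == labs[1]]
    g2 <- dat[[value_col]][dat[[group_col]] == labs[2]]
  } else {
    stop("supply either col1/col2 or value_col/group_col", call. = FALSE)
  }
  if (!is.numeric(g1) || !is.numeric(g2)) {
    stop("group values must be numeric", call. = FALSE)
  }
  list(group1 = as.numeric(g1), group2 = as.numeric(g2))
}
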