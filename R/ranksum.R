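# Two-sample Wilcoxon rank-sum (Mann-Whitney) inference, implemented from
# first principles: an exact null distribution of the U statistic by
# dynamic programming for small tie-free samples, and a tie-corrected,
# continuity-corrected normal approximation otherwise. The exact path is
# also what inverts into the Hodges-Lehmann confidence interval.

# Null distribution of the Mann-Whitney U statistic for sample sizes m, n:
# under the null every assignment of the m + n ranks to the first group is
# equally likely, so count m-subsets of {1..m+n} by rank sum W with a
# subset-sum dynamic program, then shift to U = W - m(m+1)/2. The
# distribution is symmetric, so it serves both orientations. Returns the
# vector of counts over u = 0..m*n (total choose(m+n, m)).
ranksum_null_counts <- function(m, n) {
  N <- m + n
  wmax <- m * N
  # f[k+1, w+1]: number of k-subsets of the ranks seen so far with sum w
  f <- matrix(0, m + 1, wmax + 1)
  f[1, 1] <- 1
  for (j in seq_len(N)) {
    for (k in min(j, m):1) {
      w <- j:wmax
      f[k + 1, w + 1] <- f[k + 1, w + 1] + f[k, w - j + 1]
    }
  }
  offset <- m * (m + 1) / 2
  f[m + 1, (offset:(offset + m * n)) + 1]
}

# Exact null CDF P(U <= u)
ranksum_exact_cdf <- function(u, m, n, counts = ranksum_null_counts(m, n)) {
  total <- sum(counts)
  vapply(u, function(ui) {
    if (ui < 0) return(0)
    sum(counts[seq_len(min(floor(ui), m * n) + 1)]) / total
  }, numeric(1))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Mann-Whitney U test of \code{y} against \code{x} (U counts pairs with
#' \code{y > x}, ties counted 1/2). For tie-free data with
#' \code{min(n) <= exact_cap[1]} and \code{max(n) <= exact_cap[2]} the
#' p-value is exact, from full enumeration of the null distribution of U;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. The two-sided p-value doubles the smaller
#' tail, capped at 1. If every pooled value is identical the test is
#' degenerate and p = 1.
#'
#' @param x control-group values.
#' @param y treatment-group values.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (y shifted up), or \code{"less"}.
#' @param exact_cap integer pair: largest \code{min(n)} and \code{max(n)}
#'   for which the exact path is taken.
#' @return list with \code{statistic} (U for y vs x), \code{p_value} and
#'   \code{method} ("exact", "normal-approximation" or "degenerate").
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          exact_cap = c(10L, 20L)) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y))
    ns_validation_error("both groups must be non-empty")
  pooled <- c(x, y)
  if (anyNA(pooled)) ns_validation_error("missing values not allowed")
  m <- length(x); n <- length(y)

  if (length(unique(pooled)) == 1L)
    return(list(statistic = m * n / 2, p_value = 1, method = "degenerate"))

  r <- rank(pooled)                      # midranks
  u <- sum(r[(m + 1):(m + n)]) - n * (n + 1) / 2   # U for y vs x
  ties <- any(duplicated(pooled))

  if (!ties && min(m, n) <= exact_cap[1] && max(m, n) <= exact_cap[2]) {
    counts <- ranksum_null_counts(m, n)
    p_le <- ranksum_exact_cdf(u, m, n, counts)
    p_ge <- 1 - ranksum_exact_cdf(u - 1, m, n, counts)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  if (ties && min(m, n) <= exact_cap[1] && max(m, n) <= exact_cap[2])
    message("ties present: falling back from exact enumeration to the normal approximation")
  N <- m + n
  mu <- m * n / 2
  tie_tab <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  z_up <- (u - mu - 0.5) / sqrt(sigma2)  # continuity-corrected tails
  z_lo <- (u - mu + 0.5) / sqrt(sigma2)
  p_ge <- stats::pnorm(z_up, lower.tail = FALSE)
  p_le <- stats::pnorm(z_lo)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  list(statistic = u, p_value = p, method = "normal-approximation")
}

#' Hodges-Lehmann location shift with confidence interval
#'
#' The Hodges-Lehmann estimate of the shift of \code{y} relative to
#' \code{x}: the median of all \code{length(x) * length(y)} pairwise
#' differences \code{y_j - x_i} (orientation: treatment minus control). The
#' confidence interval takes the k-th smallest and (mn + 1 - k)-th smallest
#' pairwise differences, with k from inverting the exact rank-sum null
#' distribution for small tie-free samples, or its normal approximation
#' otherwise. When the requested confidence is unattainable at the given
#' sample sizes, the interval widens to the extreme differences with a
#' warning.
#'
#' @param x control-group values (>= 2).
#' @param y treatment-group values (>= 2).
#' @param confidence confidence level, default 0.95.
#' @param exact_cap as in \code{\link{rank_sum_test}}.
#' @return list with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{confidence}, \code{method}.
#' @export
hodges_lehmann_shift <- function(x, y, confidence = 0.95,
                                 exact_cap = c(10L, 20L)) {
  if (length(x) < 2L || length(y) < 2L)
    ns_insufficient_data_error("Hodges-Lehmann shift needs >= 2 values per group")
  m <- length(x); n <- length(y)
  diffs <- sort(as.vector(outer(y, x, "-")))
  est <- stats::median(diffs)
  alpha <- 1 - confidence
  ties <- any(duplicated(c(x, y)))

  if (!ties && min(m, n) <= exact_cap[1] && max(m, n) <= exact_cap[2]) {
    counts <- ranksum_null_counts(m, n)
    cdf <- cumsum(counts) / sum(counts)     # P(U <= u), u = 0..mn
    # largest k with P(U <= k - 1) <= alpha/2
    k <- sum(cdf <= alpha / 2)
    method <- "exact"
  } else {
    sigma <- sqrt(m * n * (m + n + 1) / 12)
    k <- floor(m * n / 2 - stats::qnorm(1 - alpha / 2) * sigma + 0.5)
    method <- "normal-approximation"
  }
  if (k < 1) {
    warning(sprintf("confidence %.2f unattainable at n = (%d, %d); returning the extreme pairwise differences",
                    confidence, m, n), call. = FALSE)
    k <- 1
  }
  list(estimate = est, ci_low = diffs[k], ci_high = diffs[m * n + 1 - k],
       confidence = confidence, method = method)
}

#' Median and interquartile summary
#'
#' Quartiles use the linear-interpolation convention (quantile type 7, the
#' mainstream default), so reported medians and IQRs are reproducible.
#'
#' @param values numeric vector (>= 1 value).
#' @return named vector \code{(median, q1, q3)}.
#' @export
group_summary <- function(values) {
  if (!length(values)) ns_validation_error("no values supplied")
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Compare two groups of normalized expression values
#'
#' Assembles the full reporting unit used for one target x reference pair:
#' per-group median and interquartile range, the Hodges-Lehmann location
#' shift (treatment minus control) with its confidence interval, and the
#' two-sided rank-sum p-value.
#'
#' @param norm a \code{normalized_expression} data frame (from
#'   \code{\link{normalize_dataset}}), or any data frame with columns
#'   \code{group} and \code{ratio}.
#' @param control control group label; defaults to the object's declared
#'   control.
#' @param confidence confidence level for the shift interval.
#' @param value column holding the values to compare (default
#'   \code{"ratio"}).
#' @return object of class \code{group_comparison}.
#' @export
compare_groups <- function(norm, control = NULL, confidence = 0.95,
                           value = "ratio") {
  df <- as.data.frame(norm)
  if (is.null(control)) control <- attr(norm, "control")
  groups <- sort(unique(df$group))
  if (length(groups) != 2L)
    ns_validation_error("exactly two groups required, found %d", length(groups))
  if (is.null(control) || !control %in% groups)
    ns_validation_error("control group must be one of: %s",
                        paste(groups, collapse = ", "))
  treatment <- setdiff(groups, control)
  x <- df[[value]][df$group == control]
  y <- df[[value]][df$group == treatment]
  if (length(x) < 2L || length(y) < 2L)
    ns_insufficient_data_error("each group needs >= 2 values")

  test <- rank_sum_test(x, y)
  hl <- hodges_lehmann_shift(x, y, confidence = confidence)
  sx <- group_summary(x)
  sy <- group_summary(y)
  structure(list(group_a_label = control, group_b_label = treatment,
                 n_a = length(x), n_b = length(y),
                 median_a = unname(sx["median"]), iqr_a = unname(sx[c("q1", "q3")]),
                 median_b = unname(sy["median"]), iqr_b = unname(sy[c("q1", "q3")]),
                 hl_shift = hl$estimate, ci_low = hl$ci_low,
                 ci_high = hl$ci_high, confidence = confidence,
                 statistic = test$statistic, p_value = test$p_value,
                 method = test$method),
            class = "group_comparison")
}

#' @export
format.group_comparison <- function(x, digits = 3, ...) {
  sprintf(paste0("%s vs. %s, median (interquartile): %s (%s, %s) vs. %s (%s, %s), ",
                 "location shift (%d%%CI): %s (%s to %s), p = %s"),
          x$group_a_label, x$group_b_label,
          signif(x$median_a, digits), signif(x$iqr_a[1], digits),
          signif(x$iqr_a[2], digits),
          signif(x$median_b, digits), signif(x$iqr_b[1], digits),
          signif(x$iqr_b[2], digits),
          round(100 * x$confidence),
          signif(x$hl_shift, digits), signif(x$ci_low, digits),
          signif(x$ci_high, digits), signif(x$p_value, 2))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}
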