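# Two-group differential expression with empirical-Bayes variance
# moderation. The moderated t machinery (scaled-F moment estimation of the
# variance prior, posterior variance shrinkage, B statistic) is implemented
# here from the published closed forms rather than called from an external
# package, so every number the stage reports is produced by code in this
# file; external implementations serve as cross-checks in the test suite.

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share one empirical distribution: each
#' column's sorted values are replaced by the mean of sorted values across
#' columns. Tied values within a column receive the mean of the reference
#' values their rank range spans. With a single sample the matrix is
#' returned unchanged with a warning.
#'
#' @param mat an \code{\link{expression_matrix}} or plain numeric matrix.
#' @return matrix of the same shape (and class/flags) with identical
#'   per-column distributions.
#' @export
quantile_normalize <- function(mat) {
  m <- unclass(mat)
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity", call. = FALSE)
    return(mat)
  }
  ref <- rowMeans(apply(m, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- m
  for (j in seq_len(ncol(m))) {
    lo <- rank(m[, j], ties.method = "min")
    hi <- rank(m[, j], ties.method = "max")
    out[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (inherits(mat, "expression_matrix"))
    expression_matrix(out, log2 = attr(mat, "log2"))
  else out
}

#' Per-gene two-group linear fit
#'
#' The ordinary two-group model underlying moderated inference: per gene,
#' \code{logFC} is the treatment-minus-control mean difference,
#' \code{AveExpr} the grand mean, \code{s2} the pooled within-group
#' variance on \code{df = n - 2} degrees of freedom.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param labels per-sample group labels (named by sample id or in column
#'   order); exactly two groups, each with >= 2 samples.
#' @param control control group label; default alphabetically first.
#' @return data frame with \code{probeset_id}, \code{logFC},
#'   \code{AveExpr}, \code{s2}, \code{df}; group sizes and the unscaled
#'   standard deviation \code{sqrt(1/n1 + 1/n2)} are attached as
#'   attributes.
#' @export
fit_two_group <- function(mat, labels, control = NULL) {
  m <- unclass(mat)
  labs <- if (!is.null(names(labels))) labels[colnames(m)] else labels
  if (length(labs) != ncol(m) || anyNA(labs))
    ns_validation_error("labels must cover every sample column")
  groups <- sort(unique(as.character(labs)))
  if (length(groups) != 2L)
    ns_validation_error("exactly two groups required")
  if (is.null(control)) control <- groups[1]
  if (!control %in% groups)
    ns_validation_error("control label '%s' not among groups", control)
  treatment <- setdiff(groups, control)
  i_c <- labs == control
  i_t <- labs == treatment
  n1 <- sum(i_c); n2 <- sum(i_t)
  if (n1 < 2L || n2 < 2L)
    ns_validation_error("each group needs >= 2 samples (found %d and %d)", n1, n2)

  mean_c <- rowMeans(m[, i_c, drop = FALSE])
  mean_t <- rowMeans(m[, i_t, drop = FALSE])
  ss <- rowSums((m[, i_c, drop = FALSE] - mean_c)^2) +
    rowSums((m[, i_t, drop = FALSE] - mean_t)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(probeset_id = rownames(m),
                    logFC = unname(mean_t - mean_c),
                    AveExpr = unname(rowMeans(m)),
                    s2 = unname(ss / df),
                    df = df,
                    stringsAsFactors = FALSE)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  attr(out, "stdev_unscaled") <- sqrt(1 / n1 + 1 / n2)
  attr(out, "control") <- control
  attr(out, "treatment") <- treatment
  out
}

# Inverse of the trigamma function by Newton iteration on 1/x scaling
# (monotone decreasing; the iteration converges in a handful of steps).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, numeric(1))
}

# Moment estimation of the variance prior (d0, s0^2) under the hierarchical
# model s2_g ~ s0^2 * F(df, d0) / ... i.e. scaled F: fit on z = log(s2)
# using E[z] and Var[z] in terms of digamma/trigamma functions.
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread beyond pure sampling: point-mass prior at the
    # geometric mean of the observed variances
    list(d0 = Inf, s0_sq = exp(mean(z)))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s0_sq = s0_sq)
  }
}

# Moment estimate of the prior variance v0 of true log-fold-changes among
# differentially expressed genes, from the top proportion/2 of |t| values:
# each top-ranked statistic is matched to its mixture-implied tail quantile
# and solved for the v0 that would produce it; negative solutions truncate
# to zero and the estimates are averaged.
estimate_coef_prior_var <- function(tstat, stdev_unscaled, df_total,
                                    proportion) {
  g <- length(tstat)
  k <- ceiling(proportion / 2 * g)
  if (k < 1) return(NA_real_)
  p <- max(k / g, proportion)
  at <- abs(tstat)
  ord <- order(at, decreasing = TRUE)[seq_len(k)]
  t_top <- at[ord]
  v1 <- rep(stdev_unscaled^2, length.out = g)[ord]
  p0 <- 2 * stats::pt(-t_top, df = df_total)
  p_target <- ((seq_len(k) - 0.5) / g - (1 - p) * p0) / p
  v0 <- numeric(k)
  pos <- p_target > p0 & p_target > 0
  if (any(pos)) {
    q_target <- stats::qt(p_target[pos] / 2, df = df_total, lower.tail = FALSE)
    v0[pos] <- v1[pos] * pmax((t_top[pos] / q_target)^2 - 1, 0)
  }
  mean(v0)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks each gene's pooled variance toward a prior estimated from all
#' genes: the prior degrees of freedom \code{d0} and prior variance
#' \code{s0_sq} are obtained by moment matching on \code{log(s2)} (whose
#' null distribution is a scaled F), the posterior variance is
#' \deqn{\tilde{s}^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g),}
#' and the moderated t statistic \code{logFC / (s~ * sqrt(1/n1 + 1/n2))}
#' is referred to a t distribution on \code{d0 + df} degrees of freedom.
#' The B statistic is the log posterior odds of differential expression
#' for a prior DE proportion \code{proportion_de}.
#'
#' If the between-gene spread of log variances is no larger than its
#' pure-sampling expectation the moment estimate of d0 is infinite and all
#' variances shrink completely to \code{s0_sq} (logged via message). A
#' degenerate input where every \code{s2 = 0} is handled the same way.
#'
#' @param fits output of \code{\link{fit_two_group}}.
#' @param proportion_de prior probability that a gene is differentially
#'   expressed (default 0.01), used by the B statistic.
#' @param d0_override force the prior degrees of freedom (e.g. \code{Inf}
#'   for complete shrinkage); mainly for limit-case testing.
#' @return list with \code{prior} (\code{d0}, \code{s0_sq},
#'   \code{proportion_de}, \code{var_prior_coef}) and \code{table}: the fit
#'   table extended with \code{s2_post}, \code{t}, \code{df_total},
#'   \code{p_value}, \code{B}.
#' @export
ebayes_moderate <- function(fits, proportion_de = 0.01, d0_override = NULL) {
  if (proportion_de <= 0 || proportion_de >= 1)
    ns_validation_error("proportion_de must lie in (0, 1)")
  s2 <- fits$s2
  df <- fits$df[1]
  if (nrow(fits) < 10L)
    warning("fewer than 10 genes: the variance-prior moment estimates are unstable",
            call. = FALSE)
  if (all(s2 == 0)) {
    message("all residual variances are zero; complete shrinkage (d0 = Inf)")
    prior <- list(d0 = Inf, s0_sq = mean(s2) + .Machine$double.eps)
  } else {
    prior <- estimate_variance_prior(s2, df)
    if (!is.finite(prior$d0))
      message("log-variance spread at or below sampling expectation; complete shrinkage (d0 = Inf)")
  }
  if (!is.null(d0_override)) prior$d0 <- d0_override

  d0 <- prior$d0
  s2_post <- if (is.finite(d0)) (d0 * prior$s0_sq + df * s2) / (d0 + df)
  else rep(prior$s0_sq, length(s2))
  df_total <- if (is.finite(d0)) d0 + df else Inf
  su <- attr(fits, "stdev_unscaled")
  tstat <- fits$logFC / (sqrt(s2_post) * su)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  v0 <- estimate_coef_prior_var(tstat, su, df_total, proportion_de)
  v1 <- su^2
  r <- (v1 + v0) / v1
  if (!is.finite(v0) || v0 <= 0) {
    r <- 1 + 0 * tstat
    B <- rep(log(proportion_de / (1 - proportion_de)), length(tstat))
  } else {
    t2 <- tstat^2
    kernel <- if (is.finite(df_total))
      (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
    else t2 / 2 * (1 - 1 / r)
    B <- log(proportion_de / (1 - proportion_de)) - 0.5 * log(r) + kernel
  }

  tab <- fits
  tab$s2_post <- s2_post
  tab$t <- tstat
  tab$df_total <- df_total
  tab$p_value <- p
  tab$B <- B
  list(prior = list(d0 = d0, s0_sq = prior$s0_sq,
                    proportion_de = proportion_de, var_prior_coef = v0),
       table = tab)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: sort p-values ascending, form
#' \code{p_(i) * m / i}, take running minima from the largest rank down,
#' cap at 1, and return in the original order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    ns_validation_error("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  scaled <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-group differential expression pipeline
#'
#' Optional quantile normalization (skip with \code{pre_normalized} when
#' the matrix already carries quantile-normalized log2 intensities),
#' per-gene two-group fit, empirical-Bayes moderation, and
#' Benjamini-Hochberg adjustment, with optional probeset-to-gene
#' annotation.
#'
#' @param mat log2 \code{\link{expression_matrix}} (probesets x samples).
#' @param labels per-sample two-group labels.
#' @param annotation optional data frame with \code{probeset_id},
#'   \code{gene_symbol} (see \code{\link{read_probeset_annotation}}).
#' @param pre_normalized skip quantile normalization.
#' @param control control group label.
#' @param proportion_de prior DE proportion for the B statistic.
#' @return data frame of class \code{de_results} with columns
#'   \code{probeset_id}, \code{gene_symbol}, \code{logFC}, \code{AveExpr},
#'   \code{t}, \code{p_value}, \code{adj_p_value}, \code{B}; the estimated
#'   prior is attached as attribute \code{prior}.
#' @export
run_de <- function(mat, labels, annotation = NULL, pre_normalized = FALSE,
                   control = NULL, proportion_de = 0.01) {
  if (!pre_normalized) mat <- quantile_normalize(mat)
  fits <- fit_two_group(mat, labels, control = control)
  mod <- ebayes_moderate(fits, proportion_de = proportion_de)
  tab <- mod$table
  tab$adj_p_value <- bh_adjust(tab$p_value)
  gene_symbol <- if (!is.null(annotation))
    annotation$gene_symbol[match(tab$probeset_id, annotation$probeset_id)]
  else NA_character_
  out <- data.frame(probeset_id = tab$probeset_id, gene_symbol = gene_symbol,
                    logFC = tab$logFC, AveExpr = tab$AveExpr, t = tab$t,
                    p_value = tab$p_value, adj_p_value = tab$adj_p_value,
                    B = tab$B, stringsAsFactors = FALSE)
  class(out) <- c("de_results", "data.frame")
  attr(out, "prior") <- mod$prior
  out
}
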