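#' Expected maximal fold change implied by log2-scale variability
#'
#' Converts the standard deviation of a gene's log2 signal across a
#' compendium of arrays into the fold change spanned by the central 95\% of
#' its expression: \code{2^(z * sd_log2)} with \code{z = 1.96}. A perfectly
#' stable gene (sd 0) has a bound of 1; a "stable" reference with sd 0.45
#' already admits ~1.8-fold swings, larger than most treatment effects in
#' biological psychiatry.
#'
#' @param sd_log2 standard deviation(s) of log2 signal, >= 0.
#' @param z central-mass multiplier, default 1.96 (95\%).
#' @return fold change(s) >= 1.
#' @export
expected_max_fold_change <- function(sd_log2, z = 1.96) {
  if (any(sd_log2 < 0)) ns_validation_error("sd_log2 must be non-negative")
  2^(z * sd_log2)
}

#' Per-gene stability of a log2 expression compendium
#'
#' Computes, for every gene (row) of a log2-scale expression matrix, the
#' median and sample standard deviation across samples and the implied
#' expected maximal fold change (\code{\link{expected_max_fold_change}}).
#'
#' @param mat an \code{\link{expression_matrix}} whose \code{log2} flag is
#'   TRUE; matrices not declared log2 are refused so the caller transforms
#'   explicitly.
#' @param z multiplier passed to \code{expected_max_fold_change}.
#' @return data frame of class \code{stability_table}: \code{gene_id},
#'   \code{median_log2}, \code{sd_log2}, \code{expected_max_fc},
#'   \code{n_samples}, sorted by gene_id.
#' @export
gene_stability <- function(mat, z = 1.96) {
  if (!isTRUE(attr(mat, "log2")))
    ns_validation_error("matrix is not declared log2-scale; transform explicitly and set the log2 flag")
  if (ncol(mat) < 3L)
    ns_insufficient_data_error("stability assessment needs >= 3 samples")
  m <- unclass(mat)
  out <- data.frame(gene_id = rownames(m),
                    median_log2 = apply(m, 1, stats::median),
                    sd_log2 = apply(m, 1, stats::sd),
                    n_samples = ncol(m),
                    stringsAsFactors = FALSE)
  out$expected_max_fc <- expected_max_fold_change(out$sd_log2, z = z)
  out <- out[order(out$gene_id), c("gene_id", "median_log2", "sd_log2",
                                   "expected_max_fc", "n_samples")]
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Rank candidate reference genes by stability and treatment independence
#'
#' Orders genes by ascending log2-scale SD (ties broken by gene id) and,
#' when two-group treatment labels are available, tests each gene for a
#' treatment effect with the rank-sum test. A gene is selected as a
#' candidate normalizer only if it is both stable (\code{sd_log2 <= sd_max})
#' and not significantly treatment-responsive (\code{p >= p_floor}); the
#' first selected gene in the ranking is the recommended normalizer. This
#' mirrors the practice of picking the most stable compendium gene that the
#' treatment itself leaves alone.
#'
#' @param mat an \code{\link{expression_matrix}} (log2 scale).
#' @param treatment_labels optional per-sample group labels (named by
#'   sample or in column order); exactly two groups.
#' @param sd_max stability cap in log2 units (default Inf: rank only).
#' @param p_floor minimum treatment p-value for selection (default 0.05).
#' @return data frame of class \code{candidate_ranking} with columns
#'   \code{gene_id}, \code{sd_log2}, \code{treatment_p_value},
#'   \code{selected}; the recommended normalizer (or NA) is in attribute
#'   \code{recommended}.
#' @export
rank_reference_candidates <- function(mat, treatment_labels = NULL,
                                      sd_max = Inf, p_floor = 0.05) {
  stab <- gene_stability(mat)
  ord <- order(stab$sd_log2, stab$gene_id)
  out <- stab[ord, c("gene_id", "sd_log2")]

  if (!is.null(treatment_labels)) {
    labs <- if (!is.null(names(treatment_labels)))
      treatment_labels[colnames(mat)] else treatment_labels
    if (length(labs) != ncol(mat) || anyNA(labs))
      ns_validation_error("treatment labels must cover every sample")
    groups <- sort(unique(labs))
    if (length(groups) != 2L)
      ns_validation_error("treatment labels must define exactly two groups")
    m <- unclass(mat)
    out$treatment_p_value <- vapply(out$gene_id, function(g)
      rank_sum_test(m[g, labs == groups[1]], m[g, labs == groups[2]])$p_value,
      numeric(1))
    out$selected <- out$sd_log2 <= sd_max & out$treatment_p_value >= p_floor
  } else {
    out$treatment_p_value <- NA_real_
    out$selected <- out$sd_log2 <= sd_max
  }
  rownames(out) <- NULL
  if (!any(out$selected))
    warning("no gene satisfies the stability cap and treatment-independence floor",
            call. = FALSE)
  class(out) <- c("candidate_ranking", "data.frame")
  attr(out, "recommended") <- if (any(out$selected))
    out$gene_id[which(out$selected)[1]] else NA_character_
  attr(out, "sd_max") <- sd_max
  attr(out, "p_floor") <- p_floor
  out
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("Candidate reference genes (ascending log2 SD):\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n", sep = "")
  cat("Recommended normalizer: ", attr(x, "recommended"), "\n", sep = "")
  invisible(x)
}
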