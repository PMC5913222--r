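#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 input quantity across a dilution
#' series. The amplification efficiency is \code{E = 10^(-1/slope)}; perfect
#' doubling gives a slope of -3.3219 and E = 2. A fit with r-squared at or
#' below 0.99 is returned with a warning, mirroring the usual acceptance
#' criterion for assay standard curves; it is not an error because marginal
#' curves are still interpretable.
#'
#' @param gene_id gene identifier the curve belongs to.
#' @param log10_input log10 of input template quantity (dimensionless).
#' @param cq observed quantification cycles, same length.
#' @return object of class \code{standard_curve} with elements
#'   \code{gene_id}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{efficiency} and the fitted \code{points}.
#' @export
fit_standard_curve <- function(gene_id, log10_input, cq) {
  if (length(log10_input) != length(cq))
    ns_validation_error("log10_input and cq lengths differ")
  if (length(cq) < 3L || length(unique(log10_input)) < 3L)
    ns_insufficient_data_error(
      "standard curve for '%s' needs >=3 distinct dilution levels", gene_id)
  fit <- stats::lm(cq ~ log10_input)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    ns_fit_error("standard curve for '%s' has non-negative slope (%.4g); more input must lower Cq",
                 gene_id, slope)
  r2 <- summary(fit)$r.squared
  if (r2 <= 0.99)
    warning(sprintf("standard curve for '%s': r-squared %.4f is not > 0.99",
                    gene_id, r2), call. = FALSE)
  eff <- 10^(-1 / slope)
  if (eff <= 1 || eff > 2.2)
    warning(sprintf("efficiency %.4f for '%s' outside the plausible (1, 2.2] range",
                    eff, gene_id), call. = FALSE)
  structure(list(gene_id = gene_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, efficiency = eff,
                 points = data.frame(log10_input = log10_input, cq = cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve for %s: slope %.4f, intercept %.2f, E = %.4f, r^2 = %.4f (%d points)\n",
              x$gene_id, x$slope, x$intercept, x$efficiency, x$r_squared,
              nrow(x$points)))
  invisible(x)
}

#' Read standard curves from CSV
#'
#' CSV with columns \code{gene}, \code{log10_input}, \code{cq}; one curve is
#' fitted per gene.
#'
#' @param path CSV path.
#' @return named list of \code{standard_curve} objects.
#' @export
read_standard_curves <- function(path) {
  if (!file.exists(path)) ns_io_error("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (length(setdiff(c("gene", "log10_input", "cq"), names(df))))
    ns_format_error("standard-curve CSV requires columns gene, log10_input, cq")
  curves <- lapply(split(df, df$gene), function(d)
    fit_standard_curve(d$gene[1], d$log10_input, d$cq))
  curves[order(names(curves))]
}

#' Efficiencies from a list of standard curves
#'
#' @param curves named list of \code{standard_curve} objects.
#' @return named numeric vector of amplification efficiencies.
#' @export
curve_efficiencies <- function(curves) {
  vapply(curves, function(cv) cv$efficiency, numeric(1))
}

#' Collapse technical replicates with SD-based quality control
#'
#' Averages replicate Cq values per sample x gene and flags entries whose
#' replicate standard deviation (sample SD, n-1 denominator) is at or above
#' the threshold. The default threshold of 0.05 cycles implements the strict
#' duplicate-agreement filter; QC failure is a flag, never an error. A
#' single-replicate entry has SD 0 and passes, with a note.
#'
#' @param ds a \code{\link{cq_dataset}}.
#' @param sd_threshold cycles; entries pass only if \code{sd < sd_threshold}.
#' @return data frame of class \code{collapsed_cq}: \code{sample_id},
#'   \code{group}, \code{gene}, \code{plate}, \code{mean_cq},
#'   \code{replicate_sd}, \code{passed_qc}.
#' @export
collapse_replicates <- function(ds, sd_threshold = 0.05) {
  stopifnot(inherits(ds, "cq_dataset"))
  rep_cols <- attr(ds, "rep_cols")
  cq <- as.matrix(as.data.frame(ds)[rep_cols])
  if (ncol(cq) == 1L)
    message("single technical replicate: replicate SD taken as 0, all entries pass QC")
  mean_cq <- rowMeans(cq)
  replicate_sd <- if (ncol(cq) == 1L) rep(0, nrow(cq)) else apply(cq, 1, stats::sd)
  out <- data.frame(sample_id = ds$sample_id, group = ds$group,
                    gene = ds$gene, plate = ds$plate,
                    mean_cq = mean_cq, replicate_sd = replicate_sd,
                    passed_qc = replicate_sd < sd_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("collapsed_cq", "data.frame")
  attr(out, "sd_threshold") <- sd_threshold
  attr(out, "control") <- attr(ds, "control")
  out
}

#' Efficiency-corrected relative expression ratio
#'
#' The efficiency-corrected ratio of a target gene to a reference gene,
#' \deqn{R = E_t^{\Delta Cq_t} / E_r^{\Delta Cq_r}, \quad
#'       \Delta Cq = Cq_{calibrator} - Cq_{sample},}
#' computed in log2 space to avoid overflow. All arguments are vectorized.
#'
#' @param cq_target_sample,cq_target_calibrator Cq of the target gene in the
#'   sample and in the calibrator.
#' @param e_target amplification efficiency of the target assay, in (1, 2.2].
#' @param cq_ref_sample,cq_ref_calibrator Cq of the reference gene.
#' @param e_ref efficiency of the reference assay.
#' @return strictly positive ratio (linear scale).
#' @export
pfaffl_ratio <- function(cq_target_sample, cq_target_calibrator, e_target,
                         cq_ref_sample, cq_ref_calibrator, e_ref) {
  if (any(e_target <= 1) || any(e_ref <= 1))
    ns_validation_error("amplification efficiency must exceed 1")
  if (any(e_target > 2.2) || any(e_ref > 2.2))
    warning("efficiency above 2.2 is not physically plausible", call. = FALSE)
  if (!all(is.finite(c(cq_target_sample, cq_target_calibrator,
                       cq_ref_sample, cq_ref_calibrator))))
    ns_validation_error("all Cq values must be finite")
  log2r <- (cq_target_calibrator - cq_target_sample) * log2(e_target) -
    (cq_ref_calibrator - cq_ref_sample) * log2(e_ref)
  2^log2r
}

#' Normalize a Cq dataset against one reference gene
#'
#' Runs replicate QC, derives a per-gene calibrator Cq, and computes one
#' efficiency-corrected ratio per sample whose target AND reference entries
#' both pass QC. Samples excluded by QC are recorded (with reasons) in the
#' \code{excluded} attribute.
#'
#' The calibrator is a per-gene Cq anchor. \code{"control_mean"} (default)
#' uses the mean of QC-passing control-group mean Cq values for the gene, so
#' control-group ratios centre near 1; \code{"grand_mean"} pools both
#' groups; a sample identifier uses that sample's mean Cq.
#'
#' @param ds a \code{\link{cq_dataset}}.
#' @param target target gene identifier.
#' @param reference reference (normalizing) gene identifier.
#' @param efficiencies named vector or list mapping gene to amplification
#'   efficiency; genes absent from the map default to E = 2 with a message.
#' @param sd_threshold replicate QC threshold in cycles (see
#'   \code{\link{collapse_replicates}}).
#' @param calibrator \code{"control_mean"}, \code{"grand_mean"}, or a
#'   sample identifier.
#' @param control control group label; defaults to the dataset's declared
#'   control.
#' @param allow_self permit target == reference (identity check only).
#' @return data frame of class \code{normalized_expression}: one row per
#'   surviving sample with \code{sample_id}, \code{group}, \code{target},
#'   \code{reference}, \code{log2_ratio}, \code{ratio}.
#' @export
normalize_dataset <- function(ds, target, reference, efficiencies = NULL,
                              sd_threshold = 0.05,
                              calibrator = "control_mean",
                              control = NULL, allow_self = FALSE) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (identical(target, reference) && !allow_self)
    ns_validation_error("target and reference are both '%s'; set allow_self = TRUE for identity checks",
                        target)
  genes <- attr(ds, "genes")
  if (!target %in% genes) ns_validation_error("target gene '%s' not in dataset", target)
  if (!reference %in% genes) ns_validation_error("reference gene '%s' not in dataset", reference)
  if (is.null(control)) control <- attr(ds, "control")

  get_e <- function(g) {
    e <- efficiencies[[g]]
    if (is.null(e) || is.na(e)) {
      message("no efficiency supplied for '", g, "'; assuming perfect doubling (E = 2)")
      return(2)
    }
    if (e <= 1) ns_validation_error("efficiency for '%s' must exceed 1", g)
    as.numeric(e)
  }
  e_t <- get_e(target)
  e_r <- get_e(reference)

  coll <- collapse_replicates(ds, sd_threshold = sd_threshold)
  coll <- coll[coll$gene %in% c(target, reference), , drop = FALSE]

  wide_pass <- tapply(coll$passed_qc, list(coll$sample_id, coll$gene), all)
  wide_cq <- tapply(coll$mean_cq, list(coll$sample_id, coll$gene), mean)
  samples <- rownames(wide_cq)
  grp <- stats::setNames(ds$group[match(samples, ds$sample_id)], samples)

  ok <- wide_pass[, target] & wide_pass[, reference]
  excluded <- data.frame(sample_id = character(0), reason = character(0))
  if (any(!ok)) {
    why <- ifelse(!wide_pass[!ok, target] & !wide_pass[!ok, reference],
                  "replicate SD over threshold for target and reference",
                  ifelse(!wide_pass[!ok, target],
                         "replicate SD over threshold for target",
                         "replicate SD over threshold for reference"))
    excluded <- data.frame(sample_id = samples[!ok], reason = why,
                           stringsAsFactors = FALSE)
    message("excluded ", sum(!ok), " sample(s) failing replicate QC: ",
            paste(samples[!ok], collapse = ", "))
  }

  keep <- samples[ok]
  if (any(table(factor(grp[keep], levels = unique(grp))) < 2))
    ns_insufficient_data_error(
      "fewer than 2 QC-passing samples remain in one group")

  calib_cq <- function(gene) {
    if (calibrator == "control_mean") {
      mean(wide_cq[keep[grp[keep] == control], gene])
    } else if (calibrator == "grand_mean") {
      mean(wide_cq[keep, gene])
    } else {
      if (!calibrator %in% samples)
        ns_validation_error("calibrator sample '%s' not found", calibrator)
      wide_cq[calibrator, gene]
    }
  }
  cal_t <- calib_cq(target)
  cal_r <- calib_cq(reference)

  log2_ratio <- (cal_t - wide_cq[keep, target]) * log2(e_t) -
    (cal_r - wide_cq[keep, reference]) * log2(e_r)
  out <- data.frame(sample_id = keep, group = unname(grp[keep]),
                    target = target, reference = reference,
                    log2_ratio = unname(log2_ratio),
                    ratio = unname(2^log2_ratio),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("normalized_expression", "data.frame")
  attr(out, "control") <- control
  attr(out, "efficiencies") <- c(stats::setNames(e_t, target)[1],
                                 stats::setNames(e_r, reference)[1])
  attr(out, "calibrator") <- calibrator
  attr(out, "excluded") <- excluded
  out
}

#' Remove outliers by the z-times-SD rule
#'
#' Single pass: the mean and sample SD are computed on all values (outlier
#' candidates included) and values further than \code{z} SDs from the mean
#' are removed. No re-iteration is performed. With small n this rule can
#' mask gross outliers because they inflate the SD they are judged against;
#' that behaviour is intentional and documented.
#'
#' @param values numeric vector (>= 3 values).
#' @param z SD multiplier (default 1.96, the central-95\% normal quantile).
#' @return list with \code{kept} (values retained), \code{removed}
#'   (integer indices into the input), \code{mean}, \code{sd}.
#' @export
remove_outliers <- function(values, z = 1.96) {
  if (length(values) < 3L)
    ns_insufficient_data_error("outlier screening needs >= 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  removed <- if (s == 0) integer(0) else which(abs(values - m) > z * s)
  list(kept = if (length(removed)) values[-removed] else values,
       removed = removed, mean = m, sd = s)
}
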