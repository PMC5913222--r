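#' Normalization-sensitivity report
#'
#' The question this package exists to answer: does the apparent treatment
#' effect on a target gene survive a change of reference gene? For each
#' requested reference the target is Pfaffl-normalized, outlier-screened
#' (z-times-SD rule on the pooled ratios), and compared across groups with
#' the rank-sum test and Hodges-Lehmann shift; each reference gets a
#' direction call (up / down / NS at \code{alpha}) and the report states
#' whether all non-NS directions agree.
#'
#' @param ds a \code{\link{cq_dataset}}.
#' @param target target gene identifier.
#' @param references character vector of reference gene identifiers.
#' @param efficiencies named gene-to-efficiency map (see
#'   \code{\link{normalize_dataset}}).
#' @param sd_threshold replicate QC threshold (cycles).
#' @param outlier_z z multiplier for post-normalization outlier removal.
#' @param alpha two-sided significance level for direction calls.
#' @param confidence confidence level for shift intervals.
#' @param control control group label (defaults to the dataset's).
#' @return object of class \code{sensitivity_report}: a per-reference
#'   table, the underlying \code{group_comparison} objects, and a
#'   concordance flag.
#' @export
run_sensitivity <- function(ds, target, references, efficiencies = NULL,
                            sd_threshold = 0.05, outlier_z = 1.96,
                            alpha = 0.05, confidence = 0.95,
                            control = NULL) {
  stopifnot(inherits(ds, "cq_dataset"))
  if (is.null(control)) control <- attr(ds, "control")
  missing_genes <- setdiff(c(target, references), attr(ds, "genes"))
  if (length(missing_genes))
    ns_validation_error("gene(s) not in dataset: %s",
                        paste(missing_genes, collapse = ", "))

  comparisons <- list()
  rows <- vector("list", length(references))
  for (i in seq_along(references)) {
    ref <- references[i]
    res <- tryCatch({
      norm <- normalize_dataset(ds, target, ref, efficiencies = efficiencies,
                                sd_threshold = sd_threshold,
                                control = control,
                                allow_self = identical(ref, target))
      n_qc <- nrow(attr(norm, "excluded"))
      scr <- remove_outliers(norm$ratio, z = outlier_z)
      kept <- if (length(scr$removed)) norm[-scr$removed, , drop = FALSE] else norm
      attr(kept, "control") <- control
      cmp <- compare_groups(kept, control = control, confidence = confidence)
      dir <- if (cmp$p_value >= alpha) "NS"
      else if (cmp$hl_shift > 0) "up" else "down"
      list(row = data.frame(reference = ref, direction = dir,
                            hl_shift = cmp$hl_shift, p_value = cmp$p_value,
                            n_control = cmp$n_a, n_treatment = cmp$n_b,
                            n_excluded_qc = n_qc,
                            n_excluded_outlier = length(scr$removed),
                            failed = FALSE, stringsAsFactors = FALSE),
           cmp = cmp)
    }, normsense_error = function(e) {
      warning(sprintf("reference '%s' failed: %s", ref, conditionMessage(e)),
              call. = FALSE)
      list(row = data.frame(reference = ref, direction = NA_character_,
                            hl_shift = NA_real_, p_value = NA_real_,
                            n_control = NA_integer_, n_treatment = NA_integer_,
                            n_excluded_qc = NA_integer_,
                            n_excluded_outlier = NA_integer_,
                            failed = TRUE, stringsAsFactors = FALSE),
           cmp = NULL)
    })
    rows[[i]] <- res$row
    comparisons[[ref]] <- res$cmp
  }
  tab <- do.call(rbind, rows)
  called <- tab$direction[!is.na(tab$direction) & tab$direction != "NS"]
  structure(list(target = target, table = tab, comparisons = comparisons,
                 concordant = length(unique(called)) <= 1L,
                 alpha = alpha, control = control),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Normalization-sensitivity report for target ", x$target, "\n", sep = "")
  for (i in seq_len(nrow(x$table))) {
    ref <- x$table$reference[i]
    if (x$table$failed[i]) {
      cat(sprintf("  vs %-10s FAILED\n", ref))
      next
    }
    cat(sprintf("  vs %-10s [%-4s] %s\n", ref,
                x$table$direction[i], format(x$comparisons[[ref]])))
    cat(sprintf("      excluded: %d by replicate QC, %d as ratio outliers\n",
                x$table$n_excluded_qc[i], x$table$n_excluded_outlier[i]))
  }
  cat(if (x$concordant) "All direction calls concordant.\n"
      else "Direction calls DISAGREE across references: the conclusion depends on the normalizer.\n")
  invisible(x)
}

#' Sensitivity report as a data frame
#'
#' @param x a \code{sensitivity_report}.
#' @param ... unused.
#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  tab <- x$table
  tab$target <- x$target
  ci <- t(vapply(tab$reference, function(r) {
    cmp <- x$comparisons[[r]]
    if (is.null(cmp)) c(NA_real_, NA_real_) else c(cmp$ci_low, cmp$ci_high)
  }, numeric(2)))
  tab$ci_low <- ci[, 1]
  tab$ci_high <- ci[, 2]
  tab[c("target", "reference", "direction", "hl_shift", "ci_low", "ci_high",
        "p_value", "n_control", "n_treatment", "n_excluded_qc",
        "n_excluded_outlier", "failed")]
}

#' Run a config-driven pipeline
#'
#' Executes the stages declared in a YAML configuration, in order, writing
#' versioned TSV/CSV artifacts plus a plain-text run log (ISO timestamps,
#' seeds, thresholds, package version) into the output directory. The
#' schema is validated before any stage runs. Supported stages:
#' \code{simulate_qpcr}, \code{sensitivity}, \code{stability},
#' \code{de}, \code{evidence}.
#'
#' @param path YAML configuration file.
#' @param out_dir output directory (default: \code{output} key of the
#'   config, else a tempdir subdirectory).
#' @return invisibly, a named list of artifact paths.
#' @export
run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) ns_io_error("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  known <- c("simulate_qpcr", "sensitivity", "stability", "de", "evidence")
  if (is.null(cfg$stages) || !length(cfg$stages))
    ns_validation_error("config declares no stages")
  stage_names <- vapply(cfg$stages, function(s) s$stage %||% "", character(1))
  bad <- setdiff(stage_names, known)
  if (length(bad))
    ns_validation_error("unknown stage name(s): %s (known: %s)",
                        paste(bad, collapse = ", "), paste(known, collapse = ", "))
  if (is.null(cfg$seed)) ns_validation_error("config must declare a seed")

  if (is.null(out_dir)) out_dir <- cfg$output %||% file.path(tempdir(), "normsense_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  say("normsense %s run from %s (seed %d)",
      as.character(utils::packageVersion("normsense")), path, cfg$seed)

  artifacts <- list()
  state <- list(qpcr = NULL)
  for (s in cfg$stages) {
    name <- s$stage
    say("stage %s", name)
    if (name == "simulate_qpcr") {
      sim <- simulate_qpcr(
        n_per_group = s$n_per_group %||% 13,
        animal_effect_sd = s$animal_effect_sd %||% 0.3,
        biological_sd = s$biological_sd %||% 0.2,
        technical_sd = s$technical_sd %||% 0.02,
        seed = cfg$seed)
      state$qpcr <- sim
      p <- file.path(out_dir, "cq_table.csv")
      write_cq_table(sim$dataset, p)
      artifacts$cq_table <- p
      say("wrote %s (%d rows)", p, nrow(sim$dataset))
    } else if (name == "sensitivity") {
      ds <- if (!is.null(s$cq_table))
        read_cq_table(s$cq_table, control = s$control)
      else state$qpcr$dataset
      if (is.null(ds))
        ns_validation_error("sensitivity stage needs a cq_table or a prior simulate_qpcr stage")
      rep <- run_sensitivity(ds, target = s$target, references = s$references,
                             sd_threshold = s$qc_sd_threshold %||% 0.05,
                             outlier_z = s$outlier_z %||% 1.96,
                             alpha = s$alpha %||% 0.05)
      p <- file.path(out_dir, "sensitivity_report.tsv")
      write_results_table(as.data.frame(rep), p)
      artifacts$sensitivity <- p
      say("wrote %s (concordant: %s)", p, rep$concordant)
    } else if (name == "stability") {
      mat <- if (!is.null(s$matrix)) read_expression_matrix(s$matrix)
      else simulate_compendium(n_samples = s$n_samples %||% 80, seed = cfg$seed)
      rk <- rank_reference_candidates(mat, sd_max = s$sd_max %||% Inf)
      p <- file.path(out_dir, "stability.tsv")
      write_results_table(cbind(as.data.frame(rk),
                                expected_max_fc = expected_max_fold_change(rk$sd_log2)),
                          p)
      artifacts$stability <- p
      say("wrote %s", p)
    } else if (name == "de") {
      if (!is.null(s$matrix)) {
        mat <- read_expression_matrix(s$matrix)
        labels <- read_labels(s$labels)
      } else {
        sim <- simulate_de_matrix(n_genes = s$n_genes %||% 1000,
                                  n_per_group = s$n_per_group %||% 6,
                                  fraction_de = s$fraction_de %||% 0.05,
                                  seed = cfg$seed)
        mat <- sim$matrix
        labels <- sim$labels
      }
      ann <- if (!is.null(s$annotation)) read_probeset_annotation(s$annotation)
      res <- run_de(mat, labels, annotation = ann,
                    pre_normalized = isTRUE(s$pre_normalized))
      p <- file.path(out_dir, "de_results.tsv")
      write_results_table(res, p)
      artifacts$de <- p
      say("wrote %s (%d probesets)", p, nrow(res))
    } else if (name == "evidence") {
      ev <- load_evidence_table()
      tal <- tally_outcomes(ev)
      aff <- tally_affected_normalizers(ev)
      p <- file.path(out_dir, "evidence_tally.tsv")
      write_results_table(data.frame(category = c(names(tal), "sig_up_affected_normalizer"),
                                     count = c(unname(tal), as.integer(aff))), p)
      artifacts$evidence <- p
      say("tallies: %s; affected-normalizer sig_up set-ups: %d",
          paste(sprintf("%s=%d", names(tal), tal), collapse = " "), aff)
    }
  }
  writeLines(log_lines, log_path)
  artifacts$log <- log_path
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
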