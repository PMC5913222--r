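# Seeded generators for every input the pipeline consumes. The qPCR
# generator encodes the mechanism the whole package is about: a treatment
# effect on the *reference* gene propagates, with opposite sign, into the
# normalized ratio of the target. Under shared efficiencies the expected
# log2 ratio of a Pfaffl-normalized target is exactly
# beta_target - beta_reference, so a null target normalized against an
# upregulated reference appears downregulated (the sign flip).

default_qpcr_genes <- function() {
  # Study-like panel: one target and three normalizers. The target carries
  # a modest true downregulation; one commonly used normalizer responds to
  # treatment more strongly than the target, the other two are clean.
  data.frame(gene = c("Bcl2", "Actb", "Mapk6", "Ankrd11"),
             mu = c(0, 2, 1, 0.5),
             beta = c(-0.2, -0.5, 0, 0),
             efficiency = c(2, 2, 2, 2),
             stringsAsFactors = FALSE)
}

#' Simulate a Cq-level qPCR dataset with known ground truth
#'
#' Generative model on the log2 expression scale:
#' \deqn{x_{ij} = \mu_j + \beta_j I(\mathrm{treated}_i) + a_i + \epsilon_{ij}}
#' with a per-animal global scaling effect \code{a_i ~ N(0, animal_effect_sd^2)}
#' (what normalization is meant to cancel) and biological noise
#' \code{eps ~ N(0, biological_sd^2)}; quantification cycles follow
#' \deqn{Cq_{ijr} = c_j - x_{ij} / \log_2 E_j + \tau_{ijr},}
#' \code{tau ~ N(0, technical_sd^2)}, so higher expression means lower Cq.
#'
#' @param n_per_group animals per group (default 13, a typical rodent qPCR
#'   design).
#' @param genes data frame with columns \code{gene}, \code{mu} (baseline
#'   log2 expression), \code{beta} (treatment effect, log2 units) and
#'   \code{efficiency}; the default panel is one target plus three
#'   normalizers with a built-in normalizer response.
#' @param animal_effect_sd SD of the per-animal global effect (log2 units,
#'   default 0.3).
#' @param biological_sd per gene x animal biological noise SD (log2 units,
#'   default 0.2).
#' @param technical_sd replicate noise SD in cycles (default 0.02).
#' @param replicates technical replicates per well (default 2).
#' @param cq_intercept baseline cycles \code{c_j} (default 28).
#' @param groups length-2 named character vector: \code{control},
#'   \code{treatment} labels.
#' @param seed mandatory integer seed.
#' @return list with \code{dataset} (a \code{\link{cq_dataset}}) and
#'   \code{truth} (the gene table, per-animal effects and the expected
#'   log2 ratio matrix \code{beta_target - beta_reference}).
#' @export
simulate_qpcr <- function(n_per_group = 13, genes = default_qpcr_genes(),
                          animal_effect_sd = 0.3, biological_sd = 0.2,
                          technical_sd = 0.02, replicates = 2,
                          cq_intercept = 28,
                          groups = c(control = "RF", treatment = "Li"),
                          seed) {
  if (missing(seed)) ns_validation_error("simulate_qpcr requires an explicit seed")
  if (any(c(animal_effect_sd, biological_sd, technical_sd) < 0))
    ns_validation_error("noise SDs must be non-negative")
  if (any(genes$efficiency <= 1 | genes$efficiency > 2.2))
    ns_validation_error("efficiencies must lie in (1, 2.2]")
  if (n_per_group < 2 || replicates < 1)
    ns_validation_error("need n_per_group >= 2 and >= 1 replicate")

  with_seed(seed, {
    n <- 2L * n_per_group
    sample_id <- sprintf("S%02d", seq_len(n))
    group <- rep(unname(groups[c("control", "treatment")]), each = n_per_group)
    treated <- as.numeric(group == groups[["treatment"]])
    a <- stats::rnorm(n, 0, animal_effect_sd)

    rows <- vector("list", nrow(genes))
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      x <- g$mu + g$beta * treated + a + stats::rnorm(n, 0, biological_sd)
      true_cq <- cq_intercept - x / log2(g$efficiency)
      reps <- matrix(true_cq, n, replicates) +
        matrix(stats::rnorm(n * replicates, 0, technical_sd), n, replicates)
      df <- data.frame(sample_id = sample_id, group = group, gene = g$gene,
                       plate = "P1", stringsAsFactors = FALSE)
      for (r in seq_len(replicates)) df[[paste0("cq_rep", r)]] <- reps[, r]
      rows[[j]] <- df
    }
    df <- do.call(rbind, rows)
    ds <- suppressMessages(cq_dataset(df, control = groups[["control"]]))

    beta <- stats::setNames(genes$beta, genes$gene)
    expected_log2_ratio <- outer(beta, beta, "-") # target row - reference col
    list(dataset = ds,
         truth = list(genes = genes, beta = beta, animal_effects = a,
                      expected_log2_ratio = expected_log2_ratio,
                      groups = groups, seed = seed))
  })
}

default_compendium_genes <- function() {
  # Emulates a hippocampal array compendium: a very stable candidate
  # reference, three commonly used normalizers and a target of interest
  # with similar, substantially larger variability.
  data.frame(gene = c("Ankrd11", "Actb", "Gapdh", "Mapk6", "Bcl2"),
             median_log2 = c(8, 11, 12, 9, 7),
             sd_log2 = c(0.12, 0.4, 0.51, 0.5, 0.48),
             stringsAsFactors = FALSE)
}

#' Simulate an expression compendium with known per-gene variability
#'
#' Draws each gene's log2 signal independently as
#' \code{N(median_log2, sd_log2^2)} across arrays; a stand-in for a
#' public-compendium query when scoring reference-gene stability.
#'
#' @param genes data frame with \code{gene}, \code{median_log2},
#'   \code{sd_log2}.
#' @param n_samples number of arrays (default 80).
#' @param seed mandatory integer seed.
#' @return an \code{\link{expression_matrix}} (log2 flag set).
#' @export
simulate_compendium <- function(genes = default_compendium_genes(),
                                n_samples = 80, seed) {
  if (missing(seed)) ns_validation_error("simulate_compendium requires an explicit seed")
  if (any(genes$sd_log2 < 0)) ns_validation_error("sd_log2 must be non-negative")
  if (n_samples < 1) ns_validation_error("n_samples must be positive")
  with_seed(seed, {
    m <- t(vapply(seq_len(nrow(genes)), function(j)
      stats::rnorm(n_samples, genes$median_log2[j], genes$sd_log2[j]),
      numeric(n_samples)))
    dimnames(m) <- list(genes$gene, sprintf("A%03d", seq_len(n_samples)))
    expression_matrix(m, log2 = TRUE)
  })
}

#' Simulate a two-group matrix with known differential-expression structure
#'
#' Per-gene variances are drawn from a scaled inverse chi-square with
#' \code{d0_true} degrees of freedom and scale \code{s0_sq_true} (the prior
#' the moderated-t stage estimates back); a fraction of genes receive a
#' true log2 fold change of \code{+/- logfc_magnitude}.
#'
#' @param n_genes number of genes (default 1000).
#' @param n_per_group samples per group (default 6).
#' @param fraction_de fraction of genes differentially expressed
#'   (default 0: a null matrix for calibration).
#' @param logfc_magnitude absolute true log2 fold change for DE genes.
#' @param d0_true,s0_sq_true variance-distribution parameters.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2 expression.
#' @param seed mandatory integer seed.
#' @return list with \code{matrix} (an \code{\link{expression_matrix}}),
#'   \code{labels} (named group vector) and \code{truth} (per-gene DE flag,
#'   signed true logFC and true variance).
#' @export
simulate_de_matrix <- function(n_genes = 1000, n_per_group = 6,
                               fraction_de = 0, logfc_magnitude = 1,
                               d0_true = 4, s0_sq_true = 0.05,
                               baseline_mean = 8, baseline_sd = 1.5,
                               seed) {
  if (missing(seed)) ns_validation_error("simulate_de_matrix requires an explicit seed")
  if (fraction_de < 0 || fraction_de > 1)
    ns_validation_error("fraction_de must lie in [0, 1]")
  with_seed(seed, {
    n <- 2L * n_per_group
    s2 <- d0_true * s0_sq_true / stats::rchisq(n_genes, df = d0_true)
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    is_de <- seq_len(n_genes) <= round(fraction_de * n_genes)
    sign_de <- ifelse(stats::runif(n_genes) < 0.5, -1, 1)
    true_lfc <- ifelse(is_de, sign_de * logfc_magnitude, 0)

    m <- matrix(stats::rnorm(n_genes * n, 0, 1), n_genes, n) * sqrt(s2) + mu
    treated_cols <- (n_per_group + 1):n
    m[, treated_cols] <- m[, treated_cols] + true_lfc
    dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("S%02d", seq_len(n)))
    labels <- stats::setNames(rep(c("control", "treatment"),
                                  each = n_per_group), colnames(m))
    list(matrix = expression_matrix(m, log2 = TRUE), labels = labels,
         truth = data.frame(gene = rownames(m), is_de = is_de,
                            true_logfc = true_lfc, s2 = s2,
                            stringsAsFactors = FALSE))
  })
}
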