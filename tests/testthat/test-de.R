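test_that("quantile normalization equalizes column distributions", {
  # hand-checked 2x2: columns (1,3) and (2,6) both become (1.5, 4.5)
  m <- matrix(c(1, 3, 2, 6), 2, 2)
  qn <- quantile_normalize(m)
  expect_equal(qn, matrix(c(1.5, 4.5, 1.5, 4.5), 2, 2))

  # definitional postcondition: identical sorted columns, means, medians, SDs
  set.seed(71)
  m2 <- matrix(rexp(500), 50, 10)
  qn2 <- quantile_normalize(m2)
  ref <- sort(qn2[, 1])
  for (j in 2:10) expect_equal(sort(qn2[, j]), ref, tolerance = 1e-12)
  expect_equal(var(colMeans(qn2)), 0, tolerance = 1e-24)

  # already-identical distributions are untouched; single sample warns
  expect_equal(quantile_normalize(qn2), qn2, tolerance = 1e-12)
  expect_warning(quantile_normalize(m2[, 1, drop = FALSE]), "single sample")
})

test_that("ties receive the mean of the reference values they span", {
  m <- matrix(c(1, 1, 4,
                1, 2, 3), 3, 2)
  qn <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  expect_equal(qn[1:2, 1], rep(mean(ref[1:2]), 2))
  expect_equal(qn[3, 1], ref[3])
  expect_equal(qn[, 2], ref)
  skip_if_not_installed("limma")
  expect_equal(qn, limma::normalizeQuantiles(m, ties = TRUE), tolerance = 1e-12)
})

test_that("two-group fits reproduce hand-computed pooled statistics", {
  m <- rbind(clean = c(1, 1, 3, 3), noisy = c(0, 2, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  labels <- c(s1 = "ctl", s2 = "ctl", s3 = "trt", s4 = "trt")
  fits <- fit_two_group(expression_matrix(m, log2 = TRUE), labels, control = "ctl")
  expect_equal(fits$logFC, c(2, 1))
  expect_equal(fits$AveExpr, c(2, 1.5))
  expect_equal(fits$s2, c(0, 2))   # SS = 1+1+1+1 = 4 on df = 2
  expect_equal(fits$df, c(2, 2))

  # permutation of samples changes nothing
  perm <- c(3, 1, 4, 2)
  fits_p <- fit_two_group(expression_matrix(m[, perm], log2 = TRUE),
                          labels[perm], control = "ctl")
  expect_equal(fits_p, fits)

  expect_error(fit_two_group(expression_matrix(m[, 1:3], log2 = TRUE),
                             labels[1:3], control = "ctl"),
               class = "ns_validation_error")
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_de_matrix(n_genes = 300, n_per_group = 4, fraction_de = 0.1,
                            seed = 83)
  fits <- fit_two_group(sim$matrix, sim$labels, control = "control")
  mod <- ebayes_moderate(fits)
  design <- cbind(1, as.numeric(sim$labels == "treatment"))
  ref <- limma::eBayes(limma::lmFit(unclass(sim$matrix), design))
  expect_equal(mod$prior$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(mod$prior$s0_sq, ref$s2.prior, tolerance = 1e-6)
  expect_equal(mod$table$t, unname(ref$t[, 2]), tolerance = 1e-9)
  expect_equal(mod$table$p_value, unname(ref$p.value[, 2]), tolerance = 1e-9)
  expect_equal(mod$table$B, unname(ref$lods[, 2]), tolerance = 1e-6)
})

test_that("shrinkage limit cases behave as the closed form dictates", {
  sim <- simulate_de_matrix(n_genes = 60, n_per_group = 4, seed = 91)
  fits <- fit_two_group(sim$matrix, sim$labels, control = "control")
  # complete shrinkage: every posterior variance is the prior variance
  mod_inf <- ebayes_moderate(fits, d0_override = Inf)
  expect_equal(mod_inf$table$s2_post, rep(mod_inf$prior$s0_sq, nrow(fits)),
               tolerance = 1e-12)
  # no shrinkage: moderated t collapses onto the ordinary t statistic
  mod_0 <- ebayes_moderate(fits, d0_override = 1e-9)
  su <- attr(fits, "stdev_unscaled")
  t_ordinary <- fits$logFC / (sqrt(fits$s2) * su)
  expect_equal(mod_0$table$t, t_ordinary, tolerance = 1e-6)
  # identical variances: moderated t equals ordinary t at any d0
  m <- rbind(a = c(0, 2, 3, 5), b = c(1, 3, 2, 4), d = c(5, 7, 8, 10))
  colnames(m) <- paste0("s", 1:4)
  labels <- c("c", "c", "t", "t")
  f2 <- fit_two_group(expression_matrix(m, log2 = TRUE), labels, control = "c")
  expect_true(all(abs(f2$s2 - f2$s2[1]) < 1e-12))
  mod2 <- suppressWarnings(suppressMessages(ebayes_moderate(f2)))
  expect_equal(mod2$table$s2_post, f2$s2, tolerance = 1e-12)
  expect_equal(mod2$table$t,
               f2$logFC / (sqrt(f2$s2) * attr(f2, "stdev_unscaled")),
               tolerance = 1e-8)
})

test_that("BH adjustment equals its defining minimisation and p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ns_validation_error")

  set.seed(103)
  for (rep in 1:40) {
    p <- sample(seq(0, 1, by = 0.01), sample(1:8, 1), replace = TRUE)
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }

  # elementwise >= input, order-preserving, permutation-consistent
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
})

test_that("the DE pipeline recovers planted effects and respects the null", {
  sim <- simulate_de_matrix(n_genes = 800, n_per_group = 6, fraction_de = 0.05,
                            logfc_magnitude = 1, seed = 111)
  res <- run_de(sim$matrix, sim$labels, pre_normalized = TRUE)
  expect_s3_class(res, "de_results")
  expect_true(all(res$adj_p_value >= res$p_value))
  expect_true(all(sign(res$t) == sign(res$logFC) | res$t == 0))

  hits <- res$probeset_id[res$adj_p_value < 0.05]
  truth <- sim$truth$gene[sim$truth$is_de]
  expect_gt(length(intersect(hits, truth)) / max(length(hits), 1), 0.8)
  # recovered logFC close to the planted +/-1
  de_rows <- res[res$probeset_id %in% truth, ]
  expect_equal(mean(abs(de_rows$logFC)), 1, tolerance = 0.15)

  # null data yields (almost) no discoveries
  null_sim <- simulate_de_matrix(n_genes = 800, n_per_group = 6,
                                 fraction_de = 0, seed = 113)
  null_res <- run_de(null_sim$matrix, null_sim$labels, pre_normalized = TRUE)
  expect_lte(sum(null_res$adj_p_value < 0.05), 2)

  # annotation maps probesets to gene symbols
  ann <- data.frame(probeset_id = sim$truth$gene[1:5],
                    gene_symbol = paste0("SYM", 1:5))
  res_ann <- run_de(sim$matrix, sim$labels, annotation = ann,
                    pre_normalized = TRUE)
  expect_identical(res_ann$gene_symbol[match(ann$probeset_id, res_ann$probeset_id)],
                   ann$gene_symbol)
})
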