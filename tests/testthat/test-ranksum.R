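test_that("exact p-values equal full enumeration on textbook cases", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), alternative = "greater")$p_value,
               1 / 6)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 1 / 3)
  # fully separated 4 vs 4: one extreme table per tail
  r <- rank_sum_test(1:4, 5:8)
  expect_equal(r$p_value, 2 / choose(8, 4))
  expect_identical(r$method, "exact")
  # perfect symmetry
  expect_equal(rank_sum_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  # degenerate: everything tied
  expect_identical(rank_sum_test(rep(2, 4), rep(2, 5))$method, "degenerate")
  expect_error(rank_sum_test(numeric(0), 1:3), class = "ns_validation_error")
})

test_that("the exact path agrees with brute-force enumeration for all sizes up to 7", {
  set.seed(101)
  for (m in 2:7) for (n in 2:7) {
    x <- rnorm(m)
    y <- rnorm(n) + runif(1, -1, 1)
    got <- rank_sum_test(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, brute_force_ranksum_p(x, y), tolerance = 1e-12,
                 info = sprintf("m=%d n=%d", m, n))
  }
})

test_that("exact and approximate paths agree with the standard implementation", {
  set.seed(7)
  # tie-free exact
  x <- rnorm(9); y <- rnorm(10) + 0.8
  expect_equal(rank_sum_test(x, y)$p_value, wilcox.test(y, x)$p.value,
               tolerance = 1e-12)
  # ties force the corrected normal approximation
  xt <- c(1, 1, 2, 3, 4, 4, 5, 7, 8)
  yt <- c(1, 2, 2, 5, 6, 6, 9, 9, 10, 11)
  got <- rank_sum_test(xt, yt)
  expect_identical(got$method, "normal-approximation")
  expect_equal(got$p_value,
               suppressWarnings(wilcox.test(yt, xt)$p.value), tolerance = 1e-12)
  # large samples take the approximation too
  xl <- rnorm(30); yl <- rnorm(30) + 0.5
  expect_identical(rank_sum_test(xl, yl)$method, "normal-approximation")
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- abs(rnorm(8)) + 0.1
  y <- abs(rnorm(9)) + 0.3
  p0 <- rank_sum_test(x, y)$p_value
  for (f in list(log, sqrt, function(v) v^3, function(v) 10 * v + 2)) {
    expect_equal(rank_sum_test(f(x), f(y))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("Hodges-Lehmann estimates equal the brute-force pairwise median", {
  # pure shift
  expect_equal(hodges_lehmann_shift(c(1, 2, 4), c(4, 5, 7))$estimate, 3)
  # enumerated differences (2, 9, 1, 8) -> median 5
  expect_equal(suppressWarnings(hodges_lehmann_shift(c(1, 2), c(3, 10)))$estimate, 5)
  # identical groups: estimate 0, CI straddles 0
  hl0 <- hodges_lehmann_shift(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(hl0$estimate, 0)
  expect_lte(hl0$ci_low, 0)
  expect_gte(hl0$ci_high, 0)
  # random cases vs brute force, up to 30x30
  set.seed(31)
  for (sizes in list(c(5, 9), c(12, 8), c(30, 30))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2]) + 0.4
    expect_equal(hodges_lehmann_shift(x, y)$estimate, brute_force_hl(x, y),
                 tolerance = 1e-12)
  }
})

test_that("HL estimate and CI match the standard exact-path implementation", {
  set.seed(41)
  x <- rnorm(9); y <- rnorm(8) + 1
  hl <- hodges_lehmann_shift(x, y)
  ref <- wilcox.test(y, x, conf.int = TRUE)
  expect_equal(hl$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(c(hl$ci_low, hl$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-12)
})

test_that("swapping group roles negates the shift and mirrors the CI", {
  set.seed(51)
  x <- rnorm(8); y <- rnorm(7) + 0.6
  a <- hodges_lehmann_shift(x, y)
  b <- hodges_lehmann_shift(y, x)
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-12)
  expect_equal(a$ci_low, -b$ci_high, tolerance = 1e-12)
  expect_equal(a$ci_high, -b$ci_low, tolerance = 1e-12)
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value,
               tolerance = 1e-12)
})

test_that("group summaries use the linear-interpolation quantile convention", {
  expect_equal(group_summary(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(group_summary(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(group_summary(7), c(median = 7, q1 = 7, q3 = 7))
})

test_that("compare_groups assembles the full reporting unit", {
  sim <- simulate_qpcr(n_per_group = 13, seed = 17)
  norm <- suppressMessages(normalize_dataset(sim$dataset, "Bcl2", "Mapk6"))
  cmp <- compare_groups(norm)
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$group_a_label, "RF")
  expect_identical(cmp$group_b_label, "Li")
  expect_true(cmp$ci_low <= cmp$hl_shift && cmp$hl_shift <= cmp$ci_high)
  expect_gte(cmp$p_value, 0)
  expect_lte(cmp$p_value, 1)
  expect_match(format(cmp), "location shift \\(95%CI\\)")

  # identical groups: p = 1, shift 0
  df <- data.frame(group = rep(c("RF", "Li"), each = 4),
                   ratio = rep(c(0.8, 0.9, 1.1, 1.3), 2))
  cmp0 <- compare_groups(df, control = "RF")
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$hl_shift, 0)

  expect_error(compare_groups(data.frame(group = "RF", ratio = 1),
                              control = "RF"),
               class = "ns_validation_error")
})
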