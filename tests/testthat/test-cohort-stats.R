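test_that("Welch's t matches the reference implementation and behaves at the null", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  ours <- welch_test(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  same <- welch_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  base <- welch_test(x, y)
  shifted <- welch_test(x + 10, y)
  expect_gt(abs(shifted$statistic), abs(base$statistic))
  expect_lt(shifted$p_value, base$p_value)
  expect_error(welch_test(1, y), class = "loadrisk_insufficient_data")
})

test_that("Welch and chi-square agree with the reference on random instances", {
  withr::with_seed(12, {
    for (i in 1:60) {
      nx <- sample(5:40, 1); ny <- sample(5:40, 1)
      x <- rnorm(nx, sd = runif(1, 0.5, 3))
      y <- rnorm(ny, mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
      ours <- welch_test(x, y)
      ref <- stats::t.test(x, y)
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)

      tab <- matrix(rpois(2 * sample(2:4, 1), 20) + 1, nrow = 2)
      ct <- chi_square_independence(tab)
      rf <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(ct$statistic, unname(rf$statistic), tolerance = 1e-8)
      expect_equal(ct$p_value, rf$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Hedges' g matches the full hand computation and is antisymmetric", {
  x <- c(2, 4); y <- c(0, 2)
  # pooled SD = sqrt(2), d = 2/sqrt(2) = sqrt(2), J = 1 - 3/(4*4 - 9) = 4/7
  expect_equal(hedges_g(x, y), sqrt(2) * (4 / 7), tolerance = 1e-12)
  expect_equal(hedges_g(y, x), -hedges_g(x, y), tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2, 3), c(2, 1, 3)), 0)
  expect_error(hedges_g(c(1, 1), c(1, 1)),
               class = "loadrisk_degenerate_error")
})

test_that("chi-square independence handles degenerate and perfect tables", {
  prop <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE)  # proportional
  ct <- chi_square_independence(prop)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$cramers_v, 0)

  diag2 <- matrix(c(10, 0, 0, 10), nrow = 2)
  expect_equal(chi_square_independence(diag2)$cramers_v, 1)

  tab <- matrix(c(20, 40, 30, 10), nrow = 2)
  base <- chi_square_independence(tab)
  scaled <- chi_square_independence(tab * 7)
  expect_equal(scaled$cramers_v, base$cramers_v, tolerance = 1e-12)
  expect_equal(scaled$statistic, base$statistic * 7, tolerance = 1e-10)

  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), nrow = 2)),
               class = "loadrisk_degenerate_error")
})

test_that("per-APOE-group tests flag deviating groups and pass the null", {
  # every group mirrors the cohort ratio: p ~ 1, V ~ 0
  codes <- rep(c(-1, 0, 1, 2), each = 100)
  labels <- rep(rep(c("case", "control"), c(25, 75)), 4)
  res <- apoe_group_tests(codes, labels)
  expect_true(all(res$per_group$p_value > 0.999))
  expect_equal(res$overall$cramers_v, 0, tolerance = 1e-12)

  # strong APOE effect: the extreme groups deviate from the cohort pattern
  ss <- simulate_summary_stats(n_snps = 5, seed = 31)
  hits <- vapply(1:20, function(s) {
    ch <- simulate_cohort(
      sim_params(n_cases = 1150, n_controls = 3850, n_snps = 5,
                 w_apoe = 1.2, w_score = 0, w_age = 0, w_diabetes = 0,
                 w_cholesterol = 0, noise_sd = 0.6, missing_rate = 0,
                 seed = s), ss)
    code <- call_apoe_diplotype(ch$apoe$rs429358, ch$apoe$rs7412)$apoe_code
    r <- apoe_group_tests(code, ch$phenotypes$label)
    pg <- r$per_group
    high <- pg$case_fraction[pg$apoe_code == 2] > mean(
      ch$phenotypes$label == "case")
    sig <- all(pg$p_value[pg$apoe_code %in% c(-1, 2)] < 0.05)
    high && sig
  }, logical(1))
  expect_gte(sum(hits), 18)

  # single group: overall undefined, per-group result still returned
  expect_warning(single <- apoe_group_tests(rep(0, 50),
                                            rep(c("case", "control"), 25)),
                 "single APOE group")
  expect_true(is.na(single$overall$statistic))
  expect_equal(nrow(single$per_group), 1)
})

test_that("the default cohort reproduces the observed effect-size ordering", {
  ss <- simulate_summary_stats(n_snps = 379, seed = 99)
  ok <- vapply(1:20, function(s) {
    ch <- simulate_cohort(sim_params(seed = s), ss)
    st <- cohort_stats(cohort_features(ch))
    e <- setNames(st$effect, st$variable)
    num <- abs(e[["z_score"]]) > abs(e[["age"]]) &&
      abs(e[["age"]]) > abs(e[["cholesterol"]])
    cat_ <- e[["apoe"]] > e[["diabetes"]]
    c(num, cat_)
  }, logical(2))
  expect_gte(sum(ok[1, ]), 18)
  expect_gte(sum(ok[2, ]), 18)
})

test_that("the cholesterol effect in cases is negative on a large default cohort", {
  ss <- simulate_summary_stats(n_snps = 60, seed = 47)
  ch <- simulate_cohort(sim_params(n_cases = 1150, n_controls = 3850,
                                   n_snps = 60, seed = 47), ss)
  st <- cohort_stats(cohort_features(ch))
  expect_lt(st$effect[st$variable == "cholesterol"], 0)
  expect_gt(st$effect[st$variable == "z_score"], 0)
})
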