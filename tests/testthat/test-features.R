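test_that("raw weighted score matches hand evaluation, including the sign flip", {
  ss <- tibble::tibble(snp_id = c("a", "b"), effect_allele = "A",
                       other_allele = "G", beta = c(0.5, 0.3))
  expect_equal(raw_weighted_score(c(a = 2, b = 0), ss),
               (2 + 1) * 0.5 + (0 + 1) * 0.3)   # 1.8

  zero <- dplyr::mutate(ss, beta = 0)
  expect_equal(raw_weighted_score(c(a = 2, b = 1), zero), 0)

  neg <- tibble::tibble(snp_id = "a", effect_allele = "A",
                        other_allele = "G", beta = -0.4)
  # dosage 0 flips to risk-oriented 2; contribution (2+1)*0.4
  expect_equal(raw_weighted_score(c(a = 0), neg), 1.2)

  expect_error(raw_weighted_score(c(zz = 1), ss),
               class = "loadrisk_alignment_error")
})

test_that("control standardization centers controls and is offset-invariant", {
  sc <- tibble::tibble(individual_id = c("c1", "c2", "k1"),
                       raw_score = c(1, 3, 3))
  z <- standardize_scores(sc, controls = c("c1", "c2"))
  expect_equal(z$z_score[3], 1 / sqrt(2))
  std <- attr(z, "standardization")
  expect_equal(std$mu_control, 2)
  expect_equal(std$sigma_control, sqrt(2))

  g <- toy_geno(n = 50, p = 12, seed = 1)
  ss <- simulate_summary_stats(n_snps = 12, seed = 1)
  ss$snp_id <- setdiff(names(g), "individual_id")
  ctl <- g$individual_id[1:30]
  base <- polygenic_scores(g, ss, controls = ctl)
  zb <- standardize_scores(base, ctl)
  # control z-scores have mean 0, SD 1 by construction
  in_ctl <- zb$individual_id %in% ctl
  expect_equal(mean(zb$z_score[in_ctl]), 0, tolerance = 1e-12)
  expect_equal(sd(zb$z_score[in_ctl]), 1, tolerance = 1e-12)
  # adding any constant per-individual offset leaves every z unchanged:
  # replacing (g+1) by (g+c) shifts raw scores by (c-1)*sum(|beta|)
  for (offset in c(-1, 4)) {
    shifted <- dplyr::mutate(base, raw_score = raw_score +
                               offset * sum(abs(ss$beta)))
    zs <- standardize_scores(shifted, ctl)
    expect_equal(zs$z_score, zb$z_score, tolerance = 1e-12)
  }

  const <- tibble::tibble(individual_id = c("c1", "c2"), raw_score = c(2, 2))
  expect_error(standardize_scores(const, c("c1", "c2")),
               class = "loadrisk_degenerate_controls")
})

test_that("APOE diplotype calling covers all nine genotype combinations", {
  combos <- expand.grid(rs429358 = 0:2, rs7412 = 0:2)
  res <- call_apoe_diplotype(combos$rs429358, combos$rs7412)
  expect_true(all(res$apoe_code %in% c(-1L, 0L, 1L, 2L)))
  lookup <- setNames(res$apoe_code,
                     paste(res$rs429358, res$rs7412))
  # the standard encoding table
  expect_equal(lookup[["0 0"]], -1L)  # e2/e2
  expect_equal(lookup[["0 1"]], -1L)  # e2/e3
  expect_equal(lookup[["0 2"]], 0L)   # e3/e3
  expect_equal(lookup[["1 1"]], 1L)   # double het -> e2/e4 by convention
  expect_equal(lookup[["1 2"]], 1L)   # e3/e4
  expect_equal(lookup[["2 2"]], 2L)   # e4/e4
  diplo <- setNames(res$diplotype, paste(res$rs429358, res$rs7412))
  expect_equal(diplo[["1 1"]], "e2/e4")
  expect_equal(diplo[["0 2"]], "e3/e3")

  expect_error(call_apoe_diplotype(3, 0), class = "loadrisk_domain_error")
})

test_that("phenotype encoding passes numerics through and rejects bad levels", {
  ph <- tibble::tibble(
    individual_id = c("a", "b"), label = c("case", "control"),
    age = c(72, 65.5), sex = c("female", "male"), smoker = c(1, 0),
    diabetes = c(1, 0), cholesterol = c(5.2, NA)
  )
  enc <- encode_phenotypes(ph)
  expect_equal(enc$sex, c(0, 1))
  expect_equal(enc$age, c(72, 65.5))
  expect_true(is.na(enc$cholesterol[2]))

  bad <- dplyr::mutate(ph, smoker = c(2, 0))
  expect_error(encode_phenotypes(bad), class = "loadrisk_domain_error")
})

test_that("the feature matrix is complete-case with a fixed column order", {
  ch <- test_cohort(n_cases = 23, n_controls = 77, n_snps = 10, seed = 13)
  ch$phenotypes$diabetes[4] <- NA
  f <- cohort_features(ch)
  expect_equal(names(f), c("individual_id", "label", "z_score", "apoe",
                           "age", "sex", "smoker", "diabetes",
                           "cholesterol"))
  expect_equal(nrow(f), 99)
  expect_equal(attr(f, "dropped"), ch$phenotypes$individual_id[4])
  expect_false(anyNA(f))

  mismatched <- dplyr::mutate(
    ch$apoe[-1, ],
    apoe_code = call_apoe_diplotype(rs429358, rs7412)$apoe_code)
  scores <- standardize_scores(
    polygenic_scores(ch$genotypes, ch$sumstats,
                     controls = control_ids(ch)), control_ids(ch))
  expect_error(build_feature_matrix(scores, mismatched,
                                    encode_phenotypes(ch$phenotypes)),
               class = "loadrisk_alignment_error")
})

test_that("column scaling standardizes training data and round-trips", {
  ch <- test_cohort(n_cases = 23, n_controls = 77, n_snps = 10, seed = 17)
  f <- cohort_features(ch)
  sc <- fit_scaler(f)
  scaled <- apply_scaler(f, sc)
  for (cl in sc$column) {
    expect_equal(mean(scaled[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(scaled[[cl]]), 1, tolerance = 1e-12)
  }
  back <- invert_scaler(scaled, sc)
  expect_equal(as.data.frame(back), as.data.frame(f), tolerance = 1e-10)

  # a row equal to the training mean vector maps to all zeros
  mean_row <- f[1, ]
  for (cl in sc$column) mean_row[[cl]] <- mean(f[[cl]])
  zeroed <- apply_scaler(mean_row, sc)
  expect_true(all(abs(unlist(zeroed[sc$column])) < 1e-12))

  const <- dplyr::mutate(f, smoker = 1)
  expect_warning(sc2 <- fit_scaler(const), "constant")
  expect_equal(sc2$scale[sc2$column == "smoker"], 1)
})

test_that("cohorts with positive APOE weight show a monotone case-risk gradient", {
  ss <- simulate_summary_stats(n_snps = 10, seed = 21)
  fracs <- sapply(1:10, function(s) {
    ch <- simulate_cohort(
      sim_params(n_cases = 150, n_controls = 450, n_snps = 10,
                 w_apoe = 1.2, w_score = 0, w_age = 0, w_diabetes = 0,
                 w_cholesterol = 0, noise_sd = 0.6, missing_rate = 0,
                 seed = s), ss)
    code <- call_apoe_diplotype(ch$apoe$rs429358, ch$apoe$rs7412)$apoe_code
    lab <- ch$phenotypes$label
    vapply(c(-1, 0, 2), function(g) mean(lab[code == g] == "case"),
           numeric(1))
  })
  avg <- rowMeans(fracs)
  expect_true(all(diff(avg) > 0))
})
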