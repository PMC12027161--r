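# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: distances are computed pairwise
# from their definitions and neighbours found by a full stable sort.

oracle_dist <- function(a, b, metric) {
  switch(metric,
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b)),
    cosine = 1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  )
}

# exhaustive sort-all-distances KNN vote
oracle_knn_prob <- function(train_x, y, query, k, metric) {
  d <- apply(train_x, 1, function(row) oracle_dist(row, query, metric))
  ord <- sort.list(d, method = "radix")  # stable: ties by training order
  mean(y[ord[seq_len(k)]])
}

# concordance probability with half credit for ties, by full enumeration
oracle_concordance <- function(y, prob) {
  pc <- prob[y == 1]
  pk <- prob[y == 0]
  tot <- 0
  for (a in pc) tot <- tot + sum(a > pk) + 0.5 * sum(a == pk)
  tot / (length(pc) * length(pk))
}

# small deterministic genotype tibble
toy_geno <- function(n = 60, p = 20, seed = 42, maf = NULL) {
  withr::with_seed(seed, {
    maf <- maf %||% runif(p, 0.1, 0.5)
    m <- matrix(rbinom(n * p, 2, rep(maf, each = n)), nrow = n)
    colnames(m) <- sprintf("s%03d", seq_len(p))
    tibble::tibble(individual_id = sprintf("i%03d", seq_len(n))) |>
      dplyr::bind_cols(tibble::as_tibble(m))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default-condition cohort scaled for test runtimes
test_cohort <- function(n_cases = 69, n_controls = 231, n_snps = 40,
                        seed = 7, ...) {
  ss <- simulate_summary_stats(n_snps = n_snps, seed = seed)
  ch <- simulate_cohort(sim_params(n_cases = n_cases,
                                   n_controls = n_controls,
                                   n_snps = n_snps, seed = seed, ...), ss)
  ch
}

control_ids <- function(cohort) {
  cohort$phenotypes$individual_id[cohort$phenotypes$label == "control"]
}

cohort_features <- function(cohort) {
  ctl <- control_ids(cohort)
  scores <- standardize_scores(
    polygenic_scores(cohort$genotypes, cohort$sumstats, controls = ctl), ctl)
  apoe <- dplyr::mutate(
    cohort$apoe,
    apoe_code = call_apoe_diplotype(cohort$apoe$rs429358,
                                    cohort$apoe$rs7412)$apoe_code)
  build_feature_matrix(scores, apoe, encode_phenotypes(cohort$phenotypes))
}
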