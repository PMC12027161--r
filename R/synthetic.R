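#' Simulation parameters for a synthetic case/control cohort
#'
#' Bundles every knob of the liability-threshold cohort generator. The
#' defaults describe a biobank-like late-onset Alzheimer's cohort: a 23:77
#' case:control imbalance, 379 risk SNPs, a strong polygenic-score effect,
#' a weaker age effect, an APOE diplotype risk gradient, a small diabetes
#' association, a small negative cholesterol association, and null sex and
#' smoking effects. Liability weights are on the standardized scale of each
#' predictor (per-SD for numeric predictors, per-unit for binaries and the
#' APOE ordinal code).
#'
#' @param n_cases,n_controls Number of cases and controls to return.
#' @param n_snps Number of risk SNPs (default 379).
#' @param maf_range Range the per-SNP minor allele frequency is drawn from;
#'   must lie within (0, 0.5].
#' @param beta_sd Standard deviation of simulated GWAS effect sizes.
#' @param w_score,w_apoe,w_age,w_diabetes,w_cholesterol,w_sex,w_smoker
#'   Liability weights of the standardized polygenic score, the APOE ordinal
#'   code, standardized age, diabetes status, standardized total cholesterol,
#'   sex and smoking status.
#' @param noise_sd Residual liability standard deviation.
#' @param missing_rate Fraction of genotype entries set to missing
#'   (missing completely at random), in `[0, 1)`.
#' @param prevalence Case fraction of the source population the cohort is
#'   drawn from, in (0, 1).
#' @param apoe_freqs Named allele frequencies of the APOE haplotypes
#'   `e2`, `e3`, `e4`; must sum to 1. Defaults are European-like.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' sim_params(n_cases = 50, n_controls = 150, n_snps = 20)
sim_params <- function(n_cases = 230,
                       n_controls = 770,
                       n_snps = 379,
                       maf_range = c(0.01, 0.5),
                       beta_sd = 0.05,
                       w_score = 0.48,
                       w_apoe = 0.73,
                       w_age = 0.35,
                       w_diabetes = 0.55,
                       w_cholesterol = -0.064,
                       w_sex = 0,
                       w_smoker = 0,
                       noise_sd = 0.62,
                       missing_rate = 0.05,
                       prevalence = 0.23,
                       apoe_freqs = c(e2 = 0.08, e3 = 0.78, e4 = 0.14),
                       seed = 1) {
  check_count(n_cases, "n_cases")
  check_count(n_controls, "n_controls")
  check_count(n_snps, "n_snps")
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (!is.numeric(beta_sd) || beta_sd < 0) abort("`beta_sd` must be >= 0")
  check_fraction(missing_rate, "missing_rate", upper_open = TRUE)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1)", class = "loadrisk_sim_exhausted")
  }
  w <- c(w_score, w_apoe, w_age, w_diabetes, w_cholesterol, w_sex, w_smoker)
  if (!all(is.finite(w))) abort("liability weights must be finite")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (length(apoe_freqs) != 3 || abs(sum(apoe_freqs) - 1) > 1e-8 ||
      any(apoe_freqs < 0)) {
    abort("`apoe_freqs` must be three non-negative frequencies summing to 1")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), maf_range = maf_range, beta_sd = beta_sd,
    w_score = w_score, w_apoe = w_apoe, w_age = w_age,
    w_diabetes = w_diabetes, w_cholesterol = w_cholesterol,
    w_sex = w_sex, w_smoker = w_smoker,
    noise_sd = noise_sd, missing_rate = missing_rate,
    prevalence = prevalence, apoe_freqs = apoe_freqs,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate GWAS-style summary statistics
#'
#' Stands in for published per-SNP effect sizes: each SNP gets a unique id,
#' an effect and other allele, a minor allele frequency drawn uniformly from
#' `maf_range`, and an effect size drawn from a zero-mean normal.
#'
#' @param n_snps Number of SNPs.
#' @param beta_sd Standard deviation of the effect-size distribution
#'   (0 gives all-zero effects).
#' @param maf_range Pair of frequencies within (0, 0.5].
#' @param seed Integer seed.
#' @return A tibble with columns `snp_id`, `effect_allele`, `other_allele`,
#'   `maf`, `beta`.
#' @export
#' @examples
#' simulate_summary_stats(n_snps = 5, seed = 1)
simulate_summary_stats <- function(n_snps = 379, beta_sd = 0.05,
                                   maf_range = c(0.01, 0.5), seed = 1) {
  check_count(n_snps, "n_snps")
  if (!is.numeric(beta_sd) || length(beta_sd) != 1 || beta_sd < 0) {
    abort("`beta_sd` must be a non-negative number")
  }
  if (!is.numeric(maf_range) || length(maf_range) != 2 ||
      any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    ea <- sample(bases, n_snps, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), character(1))
    tibble(
      snp_id = sprintf("rs%07d", 1000000 + seq_len(n_snps)),
      effect_allele = ea,
      other_allele = unname(oa),
      maf = runif(n_snps, maf_range[1], maf_range[2]),
      beta = rnorm(n_snps, 0, beta_sd)
    )
  })
}

# one batch of the source population; returns list of covariates + liability
simulate_source_batch <- function(n, params, stats) {
  p <- params$n_snps
  g <- matrix(rbinom(n * p, 2L, rep(stats$maf, each = n)), nrow = n, ncol = p)
  colnames(g) <- stats$snp_id

  # APOE: two haplotypes per individual under random mating
  hap <- matrix(sample(c("e2", "e3", "e4"), 2 * n, replace = TRUE,
                       prob = params$apoe_freqs), ncol = 2)
  rs429358 <- rowSums(hap == "e4")                 # C allele tags e4
  rs7412 <- rowSums(hap == "e3" | hap == "e4")     # C allele tags e3/e4
  apoe_code <- call_apoe_diplotype(rs429358, rs7412)$apoe_code

  age <- runif(n, 60, 99)
  sex <- rbinom(n, 1, 0.45)
  smoker <- rbinom(n, 1, 0.30)
  diabetes <- rbinom(n, 1, 0.10)
  cholesterol <- rnorm(n, 5.7, 1.1)

  # risk-oriented weighted score, standardized within the batch
  oriented <- orient_dosages(g, stats)
  raw <- as.vector((oriented$dosage + 1) %*% oriented$beta)
  z <- as.vector(scale(raw))

  liability <- params$w_score * z +
    params$w_apoe * apoe_code +
    params$w_age * as.vector(scale(age)) +
    params$w_diabetes * diabetes +
    params$w_cholesterol * as.vector(scale(cholesterol)) +
    params$w_sex * sex +
    params$w_smoker * smoker +
    rnorm(n, 0, params$noise_sd)

  list(g = g, rs429358 = rs429358, rs7412 = rs7412, age = age, sex = sex,
       smoker = smoker, diabetes = diabetes, cholesterol = cholesterol,
       liability = liability)
}

#' Simulate a case/control cohort under a liability-threshold disease model
#'
#' Genotypes are drawn per SNP as binomial(2, MAF) under Hardy-Weinberg
#' equilibrium; APOE diplotypes arise from random mating over the configured
#' haplotype frequencies. A latent liability is the weighted sum of the
#' standardized polygenic score, the APOE ordinal code, standardized age,
#' diabetes, standardized cholesterol, sex, smoking and Gaussian noise;
#' individuals above the `1 - prevalence` liability quantile of the source
#' population are cases. The source population is oversampled until the
#' requested case and control counts are reached, then genotype missingness
#' is injected at `params$missing_rate`.
#'
#' @param params A [sim_params()] object.
#' @param stats Summary statistics with `params$n_snps` rows, as returned by
#'   [simulate_summary_stats()].
#' @return A list of class `load_cohort` with elements `genotypes` (tibble,
#'   `individual_id` plus one dosage column per SNP, `NA` = missing), `apoe`
#'   (tibble of C-allele counts at rs429358 and rs7412), `phenotypes`
#'   (tibble with `label` in case/control plus clinical covariates),
#'   `liability` (tibble of true latent liabilities), `sumstats` and
#'   `params`.
#' @export
#' @examples
#' ss <- simulate_summary_stats(n_snps = 20, seed = 1)
#' ch <- simulate_cohort(sim_params(n_cases = 30, n_controls = 70,
#'                                  n_snps = 20, seed = 1), ss)
#' table(ch$phenotypes$label)
simulate_cohort <- function(params, stats) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(stats) != params$n_snps) {
    abort(sprintf("`stats` has %d rows but params$n_snps = %d",
                  nrow(stats), params$n_snps),
          class = "loadrisk_shape_error")
  }
  withr::with_seed(params$seed, {
    need_cases <- params$n_cases
    need_controls <- params$n_controls
    batch_n <- ceiling(max(need_cases / params$prevalence,
                           need_controls / (1 - params$prevalence)) * 1.25) + 50

    keep <- NULL
    for (attempt in 1:25) {
      b <- simulate_source_batch(batch_n, params, stats)
      thr <- quantile(b$liability, 1 - params$prevalence, names = FALSE)
      is_case <- b$liability > thr
      ci <- which(is_case)
      ki <- which(!is_case)
      if (length(ci) >= need_cases && length(ki) >= need_controls) {
        sel <- sort(c(ci[seq_len(need_cases)], ki[seq_len(need_controls)]))
        keep <- list(batch = b, sel = sel, is_case = is_case)
        break
      }
      batch_n <- batch_n * 2
    }
    if (is.null(keep)) {
      abort("could not reach the requested case/control counts",
            class = "loadrisk_sim_exhausted")
    }

    b <- keep$batch
    sel <- keep$sel
    ids <- sprintf("ind_%05d", seq_along(sel))

    g <- b$g[sel, , drop = FALSE]
    rownames(g) <- ids
    genotypes <- geno_tibble(g)
    if (params$missing_rate > 0) {
      genotypes <- inject_missingness(genotypes, params$missing_rate,
                                      seed = stage_seed(params$seed, "missingness"))
    }

    cohort <- list(
      genotypes = genotypes,
      apoe = tibble(individual_id = ids,
                    rs429358 = b$rs429358[sel],
                    rs7412 = b$rs7412[sel]),
      phenotypes = tibble(
        individual_id = ids,
        label = ifelse(keep$is_case[sel], "case", "control"),
        age = b$age[sel],
        sex = b$sex[sel],
        smoker = b$smoker[sel],
        diabetes = b$diabetes[sel],
        cholesterol = b$cholesterol[sel]
      ),
      liability = tibble(individual_id = ids, liability = b$liability[sel]),
      sumstats = stats,
      params = params
    )
    structure(cohort, class = "load_cohort")
  })
}

#' @export
print.load_cohort <- function(x, ...) {
  n <- nrow(x$phenotypes)
  nc <- sum(x$phenotypes$label == "case")
  cat(sprintf("<load_cohort> %d individuals (%d cases, %d controls), %d SNPs\n",
              n, nc, n - nc, ncol(x$genotypes) - 1L))
  invisible(x)
}

#' Set genotype entries to missing completely at random
#'
#' @param geno Genotype tibble (`individual_id` plus dosage columns).
#' @param rate Per-entry missingness probability in `[0, 1)`.
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @return The genotype tibble with entries replaced by `NA`.
#' @export
inject_missingness <- function(geno, rate, seed = 1) {
  check_fraction(rate, "rate", upper_open = TRUE)
  if (rate == 0) return(geno)
  m <- geno_matrix(geno)
  withr::with_seed(seed, {
    mask <- matrix(runif(length(m)) < rate, nrow = nrow(m))
  })
  m[mask] <- NA_real_
  out <- geno_tibble(m)
  attr(out, "planted") <- attr(geno, "planted")
  out
}

#' Plant known quality-control violations into a genotype matrix
#'
#' Overwrites randomly chosen SNP columns and individual rows so that each
#' of the four QC exclusion rules has known victims: constant columns,
#' columns with MAF below 0.01, columns with more than 10% missing entries,
#' and rows with more than 10% missing entries. Planted ids are recorded in
#' the `"planted"` attribute so round-trip tests can compare them with what
#' [apply_qc()] removes. Designed for an otherwise clean, low-missingness
#' matrix with at least 51 individuals (so a single minor allele yields
#' MAF < 0.01).
#'
#' @param geno Genotype tibble.
#' @param n_zero_variance,n_low_maf,n_high_missing_snps Number of SNP columns
#'   to overwrite for each rule.
#' @param n_high_missing_individuals Number of rows to overwrite.
#' @param seed Integer seed.
#' @return The modified genotype tibble with attribute `planted`, a list of
#'   id vectors per violation type.
#' @export
plant_qc_violations <- function(geno, n_zero_variance = 0, n_low_maf = 0,
                                n_high_missing_snps = 0,
                                n_high_missing_individuals = 0, seed = 1) {
  check_count(n_zero_variance, "n_zero_variance", positive = FALSE)
  check_count(n_low_maf, "n_low_maf", positive = FALSE)
  check_count(n_high_missing_snps, "n_high_missing_snps", positive = FALSE)
  check_count(n_high_missing_individuals, "n_high_missing_individuals",
              positive = FALSE)
  if (n_zero_variance + n_low_maf + n_high_missing_snps +
      n_high_missing_individuals == 0) {
    return(geno)
  }
  m <- geno_matrix(geno)
  n <- nrow(m); p <- ncol(m)
  n_cols <- n_zero_variance + n_low_maf + n_high_missing_snps
  if (n_cols > p) abort("requested column violations exceed the SNP count")
  if (n_high_missing_individuals > n) {
    abort("requested row violations exceed the individual count")
  }
  if (n_low_maf > 0 && n < 51) {
    abort("planting MAF < 0.01 needs at least 51 individuals")
  }

  withr::with_seed(seed, {
    cols <- if (n_cols > 0) sample(p, n_cols) else integer(0)
    zv_cols <- cols[seq_len(n_zero_variance)]
    lm_cols <- cols[n_zero_variance + seq_len(n_low_maf)]
    hm_cols <- cols[n_zero_variance + n_low_maf + seq_len(n_high_missing_snps)]
    rows <- if (n_high_missing_individuals > 0) {
      sample(n, n_high_missing_individuals)
    } else integer(0)

    for (j in zv_cols) m[, j] <- 1
    for (j in lm_cols) {
      m[, j] <- 0
      m[sample(n, 1), j] <- 1            # single minor allele: MAF = 1/(2n)
    }
    for (j in hm_cols) {
      col <- rbinom(n, 2L, 0.3)
      if (length(unique(col)) == 1) col[1:2] <- c(0, 1)
      col[sample(n, ceiling(0.2 * n))] <- NA_real_
      m[, j] <- col
    }
    eligible <- setdiff(seq_len(p), cols)
    for (i in rows) {
      hit <- sample(eligible, ceiling(0.15 * length(eligible)))
      m[i, hit] <- NA_real_
    }
  })

  out <- geno_tibble(m)
  snp_ids <- colnames(m)
  attr(out, "planted") <- list(
    zero_variance = snp_ids[zv_cols],
    low_maf = snp_ids[lm_cols],
    high_missing_snps = snp_ids[hm_cols],
    high_missing_individuals = rownames(m)[rows]
  )
  out
}
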