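#' Per-SNP quality-control statistics
#'
#' For each SNP, the missing rate, minor allele frequency and variance are
#' computed over the observed (non-missing) genotypes only. The effect-allele
#' frequency is `f = sum(dosage) / (2 * n_observed)` and
#' `MAF = min(f, 1 - f)`. A SNP with no observed genotypes gets missing rate
#' 1, zero variance and `NA` MAF.
#'
#' @param geno Genotype tibble (`individual_id` plus dosage columns in
#'   0/1/2/`NA`).
#' @return A tibble with one row per SNP: `snp_id`, `n_observed`,
#'   `missing_rate`, `maf`, `variance`.
#' @export
#' @examples
#' g <- tibble::tibble(individual_id = c("a", "b", "c", "d"),
#'                     s1 = c(0, 1, 2, 1), s2 = c(2, NA, 2, 2))
#' snp_qc_stats(g)
snp_qc_stats <- function(geno) {
  m <- geno_matrix(geno)
  if (nrow(m) == 0 || ncol(m) == 0) abort("empty genotype matrix")
  n <- nrow(m)
  n_obs <- colSums(!is.na(m))
  f <- colSums(m, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(f, 1 - f)
  maf[n_obs == 0] <- NA_real_
  v <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) 0 else var(col)
  })
  tibble(
    snp_id = colnames(m),
    n_observed = as.integer(unname(n_obs)),
    missing_rate = unname(1 - n_obs / n),
    maf = unname(maf),
    variance = unname(v)
  )
}

new_qc_result <- function(genotypes, removed_snps, removed_individuals,
                          n_before, n_after) {
  structure(list(
    genotypes = genotypes,
    report = list(
      removed_snps = removed_snps,
      removed_individuals = removed_individuals,
      n_before = n_before,
      n_after = n_after
    )
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> SNPs %d -> %d (removed %d); individuals %d -> %d (removed %d)\n",
    x$report$n_before$snps, x$report$n_after$snps,
    nrow(x$report$removed_snps),
    x$report$n_before$individuals, x$report$n_after$individuals,
    nrow(x$report$removed_individuals)))
  invisible(x)
}

#' @describeIn apply_qc tidy method: one row per removed SNP or individual
#'   with its removal reason.
#' @param x A `qc_result`.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) {
  bind_rows(
    x$report$removed_snps %>%
      mutate(axis = "snp") %>%
      dplyr::rename(id = "snp_id"),
    x$report$removed_individuals %>%
      mutate(axis = "individual") %>%
      dplyr::rename(id = "individual_id")
  ) %>% select(all_of(c("axis", "id", "reason")))
}

#' Filter SNPs by variance, missingness and minor allele frequency
#'
#' Removes SNPs with zero observed variance, missing rate strictly greater
#' than `max_missing`, or MAF strictly lower than `min_maf`. Thresholds are
#' strict, so boundary SNPs (missing rate exactly 10%, MAF exactly 0.01)
#' survive. When several rules match, the recorded reason follows the
#' precedence zero_variance, high_missingness, low_maf.
#'
#' @param geno Genotype tibble.
#' @param max_missing Maximum tolerated per-SNP missing rate (default 0.10).
#' @param min_maf Minimum tolerated minor allele frequency (default 0.01).
#' @return A `qc_result` with elements `genotypes` (filtered tibble) and
#'   `report`.
#' @export
filter_snps <- function(geno, max_missing = 0.10, min_maf = 0.01) {
  check_fraction(max_missing, "max_missing")
  check_fraction(min_maf, "min_maf")
  st <- snp_qc_stats(geno)
  reason <- rep(NA_character_, nrow(st))
  reason[is.na(reason) & st$variance == 0] <- "zero_variance"
  reason[is.na(reason) & st$missing_rate > max_missing] <- "high_missingness"
  reason[is.na(reason) & !is.na(st$maf) & st$maf < min_maf] <- "low_maf"

  removed <- tibble(snp_id = st$snp_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  keep_cols <- c("individual_id", st$snp_id[is.na(reason)])
  out <- geno[keep_cols]
  if (ncol(out) == 1) warn("all SNPs removed by quality filtering")
  new_qc_result(
    out, removed,
    tibble(individual_id = character(0), reason = character(0)),
    n_before = list(snps = nrow(st), individuals = nrow(geno)),
    n_after = list(snps = ncol(out) - 1L, individuals = nrow(geno))
  )
}

#' Filter individuals by genotype missingness
#'
#' Removes individuals whose missing fraction across the current SNP set is
#' strictly greater than `max_missing`.
#'
#' @inheritParams filter_snps
#' @param max_missing Maximum tolerated per-individual missing fraction
#'   (default 0.10).
#' @return A `qc_result`.
#' @export
filter_individuals <- function(geno, max_missing = 0.10) {
  check_fraction(max_missing, "max_missing")
  m <- geno_matrix(geno)
  if (ncol(m) == 0) abort("no SNP columns")
  miss <- rowMeans(is.na(m))
  drop <- miss > max_missing
  out <- geno[!drop, , drop = FALSE]
  if (nrow(out) == 0) warn("all individuals removed by quality filtering")
  new_qc_result(
    out,
    tibble(snp_id = character(0), reason = character(0)),
    tibble(individual_id = rownames(m)[drop],
           reason = rep("high_missingness", sum(drop))),
    n_before = list(snps = ncol(m), individuals = nrow(m)),
    n_after = list(snps = ncol(m), individuals = nrow(out))
  )
}

#' Apply the full genotype quality-control pass
#'
#' Single pass, SNPs first: SNP statistics are computed on the full
#' individual set and SNPs violating the variance / missingness / MAF rules
#' are removed; individuals are then filtered by missingness across the
#' retained SNPs. SNP statistics are not recomputed after individual
#' removal; set `iterate = TRUE` to repeat both filters until a fixed point.
#'
#' @inheritParams filter_snps
#' @param max_missing_snp Per-SNP missing-rate threshold (default 0.10).
#' @param min_maf MAF threshold (default 0.01).
#' @param max_missing_individual Per-individual missing-fraction threshold
#'   (default 0.10).
#' @param iterate Repeat the two filters until nothing more is removed
#'   (default `FALSE`, one pass).
#' @return A `qc_result`: `genotypes` (filtered tibble) and `report` with
#'   `removed_snps`, `removed_individuals` and before/after counts.
#' @export
#' @examples
#' g <- geno_fixture <- tibble::tibble(individual_id = letters[1:4],
#'   s1 = c(1, 1, 1, 1), s2 = c(0, 1, 2, 1))
#' apply_qc(g)$report$removed_snps
apply_qc <- function(geno, max_missing_snp = 0.10, min_maf = 0.01,
                     max_missing_individual = 0.10, iterate = FALSE) {
  n_before <- list(snps = ncol(geno) - 1L, individuals = nrow(geno))
  removed_snps <- tibble(snp_id = character(0), reason = character(0))
  removed_ind <- tibble(individual_id = character(0), reason = character(0))
  cur <- geno
  repeat {
    s <- filter_snps(cur, max_missing = max_missing_snp, min_maf = min_maf)
    i <- filter_individuals(s$genotypes, max_missing = max_missing_individual)
    removed_snps <- bind_rows(removed_snps, s$report$removed_snps)
    removed_ind <- bind_rows(removed_ind, i$report$removed_individuals)
    done <- nrow(s$report$removed_snps) == 0 &&
      nrow(i$report$removed_individuals) == 0
    cur <- i$genotypes
    if (!iterate || done) break
  }
  new_qc_result(cur, removed_snps, removed_ind, n_before,
                list(snps = ncol(cur) - 1L, individuals = nrow(cur)))
}
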