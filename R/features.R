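feature_columns <- c("z_score", "apoe", "age", "sex", "smoker",
                     "diabetes", "cholesterol")

# Align a dosage matrix to the summary statistics and orient every SNP so
# that the "risk homozygote" is the genotype that increases the score:
# for beta >= 0 the oriented dosage is the effect-allele count, for
# beta < 0 it is flipped to 2 - dosage and the weight becomes |beta|.
orient_dosages <- function(m, sumstats) {
  missing_snps <- setdiff(sumstats$snp_id, colnames(m))
  extra_snps <- setdiff(colnames(m), sumstats$snp_id)
  if (length(missing_snps) || length(extra_snps)) {
    abort(paste0(
      "genotypes and summary statistics cover different SNPs; ",
      "missing from genotypes: ",
      paste(head(missing_snps, 5), collapse = ", "),
      if (length(missing_snps) > 5) " ..." else "",
      "; not in summary statistics: ",
      paste(head(extra_snps, 5), collapse = ", "),
      if (length(extra_snps) > 5) " ..." else ""
    ), class = "loadrisk_alignment_error")
  }
  m <- m[, sumstats$snp_id, drop = FALSE]
  flip <- sumstats$beta < 0
  m[, flip] <- 2 - m[, flip]
  list(dosage = m, beta = abs(sumstats$beta))
}

impute_oriented <- function(m, policy, ref_rows = NULL) {
  if (!anyNA(m)) return(m)
  fill <- switch(policy,
    zero = rep(0, ncol(m)),
    overall_mean = colMeans(m, na.rm = TRUE),
    control_mean = {
      if (is.null(ref_rows)) {
        abort("missing_policy = \"control_mean\" needs control ids")
      }
      ref <- m[intersect(ref_rows, rownames(m)), , drop = FALSE]
      cm <- colMeans(ref, na.rm = TRUE)
      # all-missing among controls: fall back to the overall mean
      all_m <- !is.finite(cm)
      cm[all_m] <- colMeans(m[, all_m, drop = FALSE], na.rm = TRUE)
      cm
    },
    abort("unknown missing policy")
  )
  fill[!is.finite(fill)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- fill[idx[, 2]]
  m
}

#' Raw weighted polygenic score of a single individual
#'
#' Computes `sum((g_i + 1) * |beta_i|)` over the SNPs in `sumstats`, where
#' `g_i` is the risk-oriented dosage: the effect-allele count when
#' `beta_i >= 0` and its flip `2 - dosage` when `beta_i < 0`. The `+ 1`
#' offset makes every per-SNP term strictly positive (protective homozygote
#' 1, heterozygote 2, risk homozygote 3); because downstream scores are
#' control-standardized, the offset never changes a z-score.
#'
#' @param dosages Named numeric vector of effect-allele dosages (0/1/2/`NA`),
#'   names = SNP ids covering `sumstats$snp_id`.
#' @param sumstats Summary-statistics tibble with `snp_id` and `beta`.
#' @param missing_policy How to impute a missing dosage before summing:
#'   `"zero"` (oriented dosage 0) or `"overall_mean"` (mean oriented dosage,
#'   degenerate for a single individual).
#' @return The raw score, a single number.
#' @export
#' @examples
#' ss <- tibble::tibble(snp_id = c("a", "b"), effect_allele = "A",
#'                      other_allele = "G", beta = c(0.5, 0.3))
#' raw_weighted_score(c(a = 2, b = 0), ss)  # (2+1)*0.5 + (0+1)*0.3 = 1.8
raw_weighted_score <- function(dosages, sumstats,
                               missing_policy = c("zero", "overall_mean")) {
  missing_policy <- match.arg(missing_policy)
  m <- matrix(dosages, nrow = 1, dimnames = list("x", names(dosages)))
  o <- orient_dosages(m, sumstats)
  d <- impute_oriented(o$dosage, missing_policy)
  as.vector((d + 1) %*% o$beta)
}

#' Raw weighted polygenic scores for a cohort
#'
#' Vectorized form of [raw_weighted_score()] over a genotype table. Missing
#' dosages are imputed before summation; the default policy replaces a
#' missing oriented dosage with the mean oriented dosage of the control
#' group at that SNP.
#'
#' @param geno Genotype tibble (`individual_id` plus dosage columns).
#' @param sumstats Summary statistics (`snp_id`, `beta`).
#' @param controls Character vector of control individual ids (required for
#'   the `"control_mean"` policy).
#' @param missing_policy One of `"control_mean"`, `"overall_mean"`, `"zero"`.
#' @return Tibble with `individual_id` and `raw_score`.
#' @export
polygenic_scores <- function(geno, sumstats, controls = NULL,
                             missing_policy = c("control_mean",
                                                "overall_mean", "zero")) {
  missing_policy <- match.arg(missing_policy)
  m <- geno_matrix(geno)
  o <- orient_dosages(m, sumstats)
  d <- impute_oriented(o$dosage, missing_policy, ref_rows = controls)
  tibble(individual_id = rownames(m),
         raw_score = as.vector((d + 1) %*% o$beta))
}

#' Standardize raw scores against the control group
#'
#' `z = (raw - mu_control) / sigma_control`, with the mean and standard
#' deviation (n - 1 denominator) computed over the control individuals only.
#' By construction the control z-scores have mean 0 and SD 1, and any
#' constant offset in the raw score (such as the `+ 1` genotype offset)
#' cancels.
#'
#' @param scores Tibble with `individual_id` and `raw_score`.
#' @param controls Character vector of control individual ids (at least two,
#'   with distinct raw scores).
#' @return The input tibble with a `z_score` column added; the attribute
#'   `standardization` records `mu_control` and `sigma_control`.
#' @export
standardize_scores <- function(scores, controls) {
  stopifnot(is.data.frame(scores),
            all(c("individual_id", "raw_score") %in% names(scores)))
  ctrl <- scores$raw_score[scores$individual_id %in% controls]
  if (length(ctrl) < 2) abort("need at least two control scores")
  mu <- mean(ctrl)
  sigma <- sd(ctrl)
  if (!is.finite(sigma) || sigma == 0) {
    abort("control scores are constant; cannot standardize",
          class = "loadrisk_degenerate_controls")
  }
  out <- scores %>% mutate(z_score = (.data$raw_score - mu) / sigma)
  attr(out, "standardization") <- list(mu_control = mu, sigma_control = sigma)
  out
}

#' Call APOE diplotypes from rs429358 and rs7412 genotypes
#'
#' The APOE epsilon haplotypes are defined by the two coding SNPs:
#' epsilon2 = (rs429358-T, rs7412-T), epsilon3 = (T, C),
#' epsilon4 = (C, C). Given unphased C-allele counts at the two sites, the
#' diplotype is resolved assuming the rare epsilon1 haplotype is absent:
#' every C at rs429358 is assigned to an epsilon4 haplotype and remaining
#' T alleles at rs7412 to epsilon2 haplotypes. The ambiguous double
#' heterozygote therefore resolves to epsilon2/epsilon4. The ordinal risk
#' code is -1 for e2/e2 and e2/e3, 0 for e3/e3, 1 for e2/e4 and e3/e4, and
#' 2 for e4/e4.
#'
#' @param rs429358,rs7412 Integer vectors of C-allele counts (0, 1 or 2).
#' @return Tibble with `rs429358`, `rs7412`, `diplotype` (e.g. `"e3/e4"`)
#'   and `apoe_code` in \{-1, 0, 1, 2\}.
#' @export
#' @examples
#' call_apoe_diplotype(c(0, 1, 2), c(2, 1, 2))
call_apoe_diplotype <- function(rs429358, rs7412) {
  if (length(rs429358) != length(rs7412)) abort("inputs must be equal length")
  ok <- function(x) is.numeric(x) && all(is.na(x) | x %in% c(0, 1, 2))
  if (!ok(rs429358) || !ok(rs7412)) {
    abort("genotypes must be C-allele counts in {0, 1, 2}",
          class = "loadrisk_domain_error")
  }
  e4 <- rs429358
  remaining <- 2 - e4
  e2 <- pmin(2 - rs7412, remaining)
  e3 <- remaining - e2
  diplo <- character(length(e4))
  code <- integer(length(e4))
  for (i in seq_along(e4)) {
    if (is.na(e4[i]) || is.na(e2[i])) {
      diplo[i] <- NA_character_; code[i] <- NA_integer_; next
    }
    al <- c(rep("e2", e2[i]), rep("e3", e3[i]), rep("e4", e4[i]))
    diplo[i] <- paste(al, collapse = "/")
    code[i] <- if (e4[i] == 2) 2L else if (e4[i] == 1) 1L else
      if (e2[i] >= 1) -1L else 0L
  }
  tibble(rs429358 = rs429358, rs7412 = rs7412,
         diplotype = diplo, apoe_code = code)
}

#' Encode clinical phenotypes as numeric model inputs
#'
#' Binary risk factors (sex, smoking, diabetes) pass through as 0/1 (sex:
#' 0 = female, 1 = male); age and cholesterol are kept on their natural
#' numeric scales (years, mmol/L). Missing values are preserved; they are
#' dropped later by [build_feature_matrix()].
#'
#' @param pheno Tibble with columns `individual_id`, `label` (`"case"` /
#'   `"control"`), `age`, `sex`, `smoker`, `diabetes`, `cholesterol`. `sex`
#'   may be given as 0/1 or as `"female"` / `"male"`.
#' @return Tibble with the same columns, all predictors numeric.
#' @export
encode_phenotypes <- function(pheno) {
  need <- c("individual_id", "label", "age", "sex", "smoker", "diabetes",
            "cholesterol")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) abort(paste("missing phenotype columns:",
                                paste(miss, collapse = ", ")))
  if (!all(is.na(pheno$label) | pheno$label %in% c("case", "control"))) {
    abort("`label` must be \"case\" or \"control\"",
          class = "loadrisk_domain_error")
  }
  sex <- pheno$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    bad <- !is.na(sex) & !sex %in% c("female", "male")
    if (any(bad)) {
      abort(sprintf("non-binary sex value in row(s) %s",
                    paste(head(which(bad), 5), collapse = ", ")),
            class = "loadrisk_domain_error")
    }
    sex <- ifelse(sex == "male", 1, 0)
  }
  check_binary <- function(x, nm) {
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) {
      abort(sprintf("non-binary %s value in row(s) %s", nm,
                    paste(head(which(bad), 5), collapse = ", ")),
            class = "loadrisk_domain_error")
    }
    as.numeric(x)
  }
  tibble(
    individual_id = as.character(pheno$individual_id),
    label = pheno$label,
    age = as.numeric(pheno$age),
    sex = check_binary(sex, "sex"),
    smoker = check_binary(pheno$smoker, "smoker"),
    diabetes = check_binary(pheno$diabetes, "diabetes"),
    cholesterol = as.numeric(pheno$cholesterol)
  )
}

#' Assemble the model feature matrix
#'
#' Joins the standardized polygenic score, the APOE ordinal code and the
#' encoded phenotypes on `individual_id`, then drops every row with a
#' missing value (complete-case analysis; no phenotype imputation). The
#' fixed column order is `z_score`, `apoe`, `age`, `sex`, `smoker`,
#' `diabetes`, `cholesterol`.
#'
#' @param scores Tibble with `individual_id` and `z_score` (see
#'   [standardize_scores()]).
#' @param apoe Tibble with `individual_id` and `apoe_code`.
#' @param phenotypes Encoded phenotype tibble (see [encode_phenotypes()]).
#' @return Tibble `individual_id`, `label`, then the seven feature columns;
#'   attribute `dropped` lists the ids removed for missing data.
#' @export
build_feature_matrix <- function(scores, apoe, phenotypes) {
  ids <- scores$individual_id
  if (!setequal(ids, apoe$individual_id) ||
      !setequal(ids, phenotypes$individual_id)) {
    abort("individual ids of scores, apoe and phenotypes do not match",
          class = "loadrisk_alignment_error")
  }
  out <- scores %>%
    select(all_of(c("individual_id", "z_score"))) %>%
    left_join(apoe %>% select(all_of(c("individual_id", "apoe_code"))),
              by = "individual_id") %>%
    left_join(phenotypes, by = "individual_id") %>%
    dplyr::rename(apoe = "apoe_code") %>%
    select(all_of(c("individual_id", "label", feature_columns)))
  complete <- stats::complete.cases(out)
  dropped <- out$individual_id[!complete]
  out <- out[complete, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Column z-scaling fitted on training data
#'
#' `fit_scaler()` learns a per-column center (mean) and scale (SD, n - 1
#' denominator) on the training rows; `apply_scaler()` applies the same
#' transform to any data (the leakage-safe contract: test data is scaled
#' with training parameters); `invert_scaler()` undoes it. A constant
#' column keeps scale 1 with a warning.
#'
#' @param data Data frame with the columns to scale.
#' @param cols Character vector of columns to scale; defaults to the
#'   numeric feature columns present (excluding `individual_id`, `label`).
#' @return `fit_scaler()`: a `column_scaler` tibble (`column`, `center`,
#'   `scale`); `apply_scaler()` / `invert_scaler()`: the transformed data.
#' @export
fit_scaler <- function(data, cols = NULL) {
  cols <- cols %||% setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                            c("individual_id", "label"))
  if (nrow(data) < 2) abort("need at least two rows to fit a scaler")
  sc <- purrr::map_dfr(cols, function(cl) {
    x <- data[[cl]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warn(sprintf("column `%s` is constant; scale set to 1", cl))
      s <- 1
    }
    tibble(column = cl, center = mean(x), scale = s)
  })
  class(sc) <- c("column_scaler", class(sc))
  sc
}

#' @rdname fit_scaler
#' @param scaler A `column_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(data, scaler) {
  for (i in seq_len(nrow(scaler))) {
    cl <- scaler$column[i]
    data[[cl]] <- (data[[cl]] - scaler$center[i]) / scaler$scale[i]
  }
  data
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(data, scaler) {
  for (i in seq_len(nrow(scaler))) {
    cl <- scaler$column[i]
    data[[cl]] <- data[[cl]] * scaler$scale[i] + scaler$center[i]
  }
  data
}
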