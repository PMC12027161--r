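#' Welch's two-sample t-test
#'
#' Two-sided mean comparison assuming unequal variances, with
#' Welch-Satterthwaite degrees of freedom:
#' `t = (mean(x) - mean(y)) / sqrt(vx/nx + vy/ny)`.
#'
#' @param x Case-group values.
#' @param y Control-group values.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3), c(1, 2, 3, 4, 5, 6))
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two finite values",
          class = "loadrisk_insufficient_data")
  }
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    # identical constant groups: no evidence against equal means
    return(tibble(statistic = 0, df = nx + ny - 2, p_value = 1))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (mean(x) - mean(y)) / s_pooled`, with the pooled SD using
#' n - 1 denominators and the small-sample correction
#' `J = 1 - 3 / (4 (nx + ny) - 9)`. The sign convention is case minus
#' control: positive when cases have the larger mean.
#'
#' @param x Case-group values.
#' @param y Control-group values.
#' @return The effect size, a single number.
#' @export
#' @examples
#' hedges_g(c(2, 4), c(0, 2))
hedges_g <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    abort("each group needs at least two finite values",
          class = "loadrisk_insufficient_data")
  }
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) {
    abort("pooled standard deviation is zero",
          class = "loadrisk_degenerate_error")
  }
  j <- 1 - 3 / (4 * (nx + ny) - 9)
  j * (mean(x) - mean(y)) / sp
}

#' Pearson chi-square test of independence with Cramer's V
#'
#' Chi-square without continuity correction on an `r x c` contingency
#' table, `df = (r - 1)(c - 1)`, and
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))`.
#'
#' @param tab A contingency matrix/table of counts (typically 2 x C:
#'   rows = class, columns = predictor levels).
#' @param correct Apply the Yates continuity correction (2 x 2 tables only;
#'   default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `cramers_v`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(20, 40, 30, 10), nrow = 2))
chi_square_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || !all(tab == floor(tab))) {
    abort("`tab` must contain non-negative counts")
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    abort("contingency table has a zero margin",
          class = "loadrisk_degenerate_error")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct && all(dim(tab) == c(2, 2))) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  tibble(statistic = chi2, df = df, p_value = pchisq(chi2, df,
                                                     lower.tail = FALSE),
         cramers_v = v)
}

#' Case/control association of the APOE risk groups
#'
#' Overall: a chi-square independence test (with Cramer's V) of class
#' against the APOE ordinal code over the groups present. Per group: a
#' chi-square goodness-of-fit test of the group's case/control split
#' against the cohort-wide case/control proportions, asking whether that
#' risk group deviates from the overall pattern.
#'
#' @param apoe_codes Integer APOE codes (-1, 0, 1, 2).
#' @param labels Case/control labels.
#' @return List with `overall` (one-row tibble; `NA` statistics when only
#'   one group is present) and `per_group` (tibble with one row per code:
#'   counts, case fraction, `statistic`, `p_value`).
#' @export
apoe_group_tests <- function(apoe_codes, labels) {
  y <- as_case_indicator(labels)
  keep <- !is.na(apoe_codes) & !is.na(y)
  apoe_codes <- apoe_codes[keep]; y <- y[keep]
  groups <- sort(unique(apoe_codes))
  if (!length(groups)) abort("no APOE groups present")

  overall <- if (length(groups) >= 2) {
    chi_square_independence(table(factor(y, levels = c(0, 1)),
                                  factor(apoe_codes, levels = groups)))
  } else {
    warn("single APOE group: overall independence test undefined")
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
           cramers_v = NA_real_)
  }

  p_case <- mean(y)
  per_group <- purrr::map_dfr(groups, function(g) {
    yy <- y[apoe_codes == g]
    n <- length(yy); nc <- sum(yy)
    expected <- n * c(1 - p_case, p_case)
    observed <- c(n - nc, nc)
    if (any(expected == 0) || n == 0) {
      warn(sprintf("APOE group %d skipped (empty expected count)", g))
      return(tibble(apoe_code = g, n = n, n_case = nc,
                    case_fraction = if (n) nc / n else NaN,
                    statistic = NA_real_, p_value = NA_real_))
    }
    chi2 <- sum((observed - expected)^2 / expected)
    tibble(apoe_code = g, n = n, n_case = nc, case_fraction = nc / n,
           statistic = chi2,
           p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
  })
  list(overall = overall, per_group = per_group)
}

#' Case-versus-control inferential battery over the model predictors
#'
#' For each numeric predictor (`z_score`, `age`, `cholesterol`): Welch's
#' t-test and Hedges' g (case minus control). For each categorical
#' predictor (`apoe`, `sex`, `smoker`, `diabetes`): the chi-square
#' independence test and Cramer's V. Raw p-values are reported (no
#' multiple-testing adjustment).
#'
#' @param features A feature tibble such as from [build_feature_matrix()],
#'   with a label column.
#' @param label_col Name of the label column (default `"label"`).
#' @return Tibble with one row per predictor: `variable`, `type`,
#'   `statistic`, `df`, `p_value`, `effect`, `effect_type`.
#' @export
cohort_stats <- function(features, label_col = "label") {
  y <- as_case_indicator(features[[label_col]])
  numeric_vars <- intersect(c("z_score", "age", "cholesterol"),
                            names(features))
  categorical_vars <- intersect(c("apoe", "sex", "smoker", "diabetes"),
                                names(features))
  num <- purrr::map_dfr(numeric_vars, function(v) {
    x <- features[[v]]
    wt <- welch_test(x[y == 1], x[y == 0])
    tibble(variable = v, type = "numeric", statistic = wt$statistic,
           df = wt$df, p_value = wt$p_value,
           effect = hedges_g(x[y == 1], x[y == 0]),
           effect_type = "hedges_g")
  })
  cat_ <- purrr::map_dfr(categorical_vars, function(v) {
    x <- features[[v]]
    ct <- chi_square_independence(table(factor(y, levels = c(0, 1)), x))
    tibble(variable = v, type = "categorical", statistic = ct$statistic,
           df = as.numeric(ct$df), p_value = ct$p_value,
           effect = ct$cramers_v, effect_type = "cramers_v")
  })
  bind_rows(num, cat_)
}
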