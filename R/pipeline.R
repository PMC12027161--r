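#' Specification of a single predictive-model experiment
#'
#' One row of the experiment matrix: which feature set feeds the
#' classifier (`"snps_only"` = the per-SNP risk-oriented encoded matrix;
#' `"combined"` = the 7-column feature matrix of standardized score, APOE
#' code and encoded phenotypes), which rebalancing strategy and distance
#' metric are used, and the decision threshold.
#'
#' @param model_id Identifier for reporting.
#' @param feature_set `"snps_only"` or `"combined"`.
#' @param sampling `"none"`, `"oversample"` or `"subsample"`.
#' @param metric `"euclidean"`, `"manhattan"` or `"cosine"`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it via [stage_seed()].
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(model_id = 1,
                            feature_set = c("combined", "snps_only"),
                            sampling = c("subsample", "none", "oversample"),
                            metric = c("euclidean", "manhattan", "cosine"),
                            threshold = 0.5, seed = 1) {
  feature_set <- match.arg(feature_set)
  sampling <- match.arg(sampling)
  metric <- match.arg(metric)
  check_fraction(threshold, "threshold")
  structure(list(model_id = model_id, feature_set = feature_set,
                 sampling = sampling, metric = metric,
                 threshold = threshold, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' The seven-model experiment grid
#'
#' Models 1-3 compare rebalancing strategies on the SNP-only features with
#' Euclidean distance; models 3-5 compare the three distance metrics under
#' subsampling; models 6-7 use the combined genetic + phenotypic features,
#' with model 7 lowering the decision threshold from 0.50 to 0.42 to
#' favour sensitivity.
#'
#' @return Tibble with one row per model.
#' @export
default_model_grid <- function() {
  tibble(
    model_id = 1:7,
    feature_set = c(rep("snps_only", 5), "combined", "combined"),
    sampling = c("none", "oversample", "subsample", "subsample",
                 "subsample", "subsample", "subsample"),
    metric = c("euclidean", "euclidean", "euclidean", "manhattan",
               "cosine", "euclidean", "euclidean"),
    threshold = c(rep(0.50, 6), 0.42)
  )
}

#' Run one experiment end-to-end on a cohort
#'
#' Stages: genotype QC; feature construction (with genotype-missingness
#' imputation from training-control means, control standardization of the
#' polygenic score on training controls only, complete-case dropping of
#' phenotype-missing rows in combined mode, and column scaling fitted on
#' the training partition); stratified 70/30 split; training-set
#' rebalancing; cross-validated selection of k; KNN prediction; evaluation
#' at the spec's threshold plus a full threshold sweep. Each stochastic
#' stage consumes a sub-seed derived from the spec's master seed, so the
#' split is identical across specs sharing a seed.
#'
#' @param cohort A `load_cohort` (or a list with elements `genotypes`,
#'   `apoe`, `phenotypes`, `sumstats` in the package's table formats).
#' @param spec An [experiment_spec()].
#' @param qc Apply [apply_qc()] to the genotypes first (default `TRUE`).
#' @param k `"auto"` (cross-validated selection) or a fixed integer.
#' @param k_grid Candidate k values for selection.
#' @param test_fraction Test-set fraction (default 0.30).
#' @param min_specificity Specificity floor used when reporting the
#'   constrained-optimal threshold from the sweep.
#' @return An object of class `load_run`: `eval` (a `knn_eval`), `sweep`,
#'   `optimal_threshold` (`NA` if the floor is infeasible), `spec`,
#'   `manifest` (stage-by-stage counts, seeds and fitted parameters).
#' @export
run_experiment <- function(cohort, spec, qc = TRUE, k = "auto",
                           k_grid = seq(1, 119, by = 2),
                           test_fraction = 0.30, min_specificity = 0.61) {
  stopifnot(inherits(spec, "experiment_spec"))
  seeds <- list(split = stage_seed(spec$seed, "split"),
                rebalance = stage_seed(spec$seed, "rebalance"),
                cv = stage_seed(spec$seed, "cv"))

  geno <- cohort$genotypes
  n_geno_before <- list(snps = ncol(geno) - 1L, individuals = nrow(geno))
  qc_report <- NULL
  if (qc) {
    qr <- apply_qc(geno)
    geno <- qr$genotypes
    qc_report <- qr$report
  }

  pheno <- encode_phenotypes(cohort$phenotypes) %>%
    filter(.data$individual_id %in% geno$individual_id)

  # modelling ids: combined mode needs complete phenotypes + APOE
  if (spec$feature_set == "combined") {
    apoe <- cohort$apoe %>%
      filter(.data$individual_id %in% geno$individual_id)
    apoe_codes <- call_apoe_diplotype(apoe$rs429358, apoe$rs7412)
    apoe <- apoe %>% mutate(apoe_code = apoe_codes$apoe_code)
    base <- pheno %>%
      left_join(apoe %>% select(all_of(c("individual_id", "apoe_code"))),
                by = "individual_id")
    complete <- stats::complete.cases(base)
    dropped <- base$individual_id[!complete]
    base <- base[complete, , drop = FALSE]
  } else {
    base <- pheno %>% filter(!is.na(.data$label))
    dropped <- character(0)
  }

  split <- split_cohort(base, test_fraction = test_fraction,
                        seed = seeds$split)
  train_ids <- split$train_ids
  test_ids <- split$test_ids
  labels <- setNames(base$label, base$individual_id)
  train_controls <- train_ids[labels[train_ids] == "control"]

  # oriented, imputed per-SNP matrix restricted to the modelling ids
  m <- geno_matrix(geno)[base$individual_id, , drop = FALSE]
  st <- cohort$sumstats %>% filter(.data$snp_id %in% colnames(m))
  o <- orient_dosages(m, st)
  d <- impute_oriented(o$dosage, "control_mean", ref_rows = train_controls)

  if (spec$feature_set == "snps_only") {
    feat <- geno_tibble(d + 1) %>%
      mutate(label = unname(labels[.data$individual_id]))
    standardization <- NULL
  } else {
    raw <- tibble(individual_id = rownames(d),
                  raw_score = as.vector((d + 1) %*% o$beta))
    scored <- standardize_scores(raw, train_controls)
    standardization <- attr(scored, "standardization")
    feat <- build_feature_matrix(
      scored,
      base %>% select(all_of(c("individual_id", "apoe_code"))),
      base %>% select(-all_of("apoe_code"))
    )
  }

  train <- feat %>% filter(.data$individual_id %in% train_ids)
  test <- feat %>% filter(.data$individual_id %in% test_ids)
  scaler <- fit_scaler(train)
  train <- apply_scaler(train, scaler)
  test <- apply_scaler(test, scaler)

  n_train_before <- nrow(train)
  train <- rebalance(train, spec$sampling, seed = seeds$rebalance)

  if (identical(k, "auto")) {
    sel <- select_k(train, train$label, metric = spec$metric,
                    k_grid = k_grid, seed = seeds$cv)
    k_used <- sel$best_k
    cv_table <- sel$cv_table
  } else {
    k_used <- check_count(k, "k")
    cv_table <- NULL
  }

  probs <- knn_probability(train, train$label, test, k = k_used,
                           metric = spec$metric)
  eval <- evaluate_predictions(test$label, probs, threshold = spec$threshold)
  sweep <- threshold_sweep(test$label, probs)
  opt <- tryCatch(
    optimal_threshold(sweep, "max_sensitivity",
                      min_specificity = min_specificity),
    loadrisk_no_threshold = function(e) NA_real_
  )

  manifest <- list(
    spec = unclass(spec),
    seeds = seeds,
    counts = list(
      genotypes_in = n_geno_before,
      post_qc = list(snps = ncol(geno) - 1L, individuals = nrow(geno)),
      dropped_missing_phenotype = length(dropped),
      modelled = nrow(base),
      n_train = n_train_before,
      n_train_rebalanced = nrow(train),
      n_test = nrow(test),
      train_cases = sum(labels[train_ids] == "case"),
      train_controls = length(train_controls),
      test_cases = sum(labels[test_ids] == "case"),
      test_controls = sum(labels[test_ids] == "control")
    ),
    qc = qc_report,
    dropped_ids = dropped,
    k = k_used,
    standardization = standardization,
    scaler = as.data.frame(scaler)
  )

  structure(list(eval = eval, sweep = sweep, optimal_threshold = opt,
                 cv_table = cv_table, spec = spec, manifest = manifest),
            class = "load_run")
}

#' @export
print.load_run <- function(x, ...) {
  cat(sprintf("<load_run> model %s: %s features, %s, %s, threshold %.2f, k = %d\n",
              x$spec$model_id, x$spec$feature_set, x$spec$sampling,
              x$spec$metric, x$spec$threshold, x$manifest$k))
  print(x$eval)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `load_run`.
#' @param ... Unused.
#' @return One-row tibble with the spec fields, the stage counts and the
#'   evaluation metrics.
#' @method glance load_run
#' @export
glance.load_run <- function(x, ...) {
  cn <- x$manifest$counts
  dplyr::bind_cols(
    tibble(model_id = x$spec$model_id, feature_set = x$spec$feature_set,
           sampling = x$spec$sampling, metric = x$spec$metric,
           threshold = x$spec$threshold, k = x$manifest$k,
           n_train = cn$n_train_rebalanced, n_test = cn$n_test,
           train_cases = cn$train_cases, train_controls = cn$train_controls),
    x$eval$metrics,
    tibble(auc = x$eval$auc)
  )
}

#' @describeIn glance.load_run the run's threshold sweep table.
#' @method tidy load_run
#' @export
tidy.load_run <- function(x, ...) as_tibble(x$sweep)

#' Run a grid of experiments on one cohort
#'
#' Every row of `grid` is run with the same master seed, so all models
#' share the identical train/test split (rebalancing changes only the
#' training partition).
#'
#' @param cohort A `load_cohort`.
#' @param grid Experiment grid, as from [default_model_grid()].
#' @param seed Master seed.
#' @param ... Passed to [run_experiment()].
#' @return List of `load_run` objects, named by model id.
#' @export
run_model_grid <- function(cohort, grid = default_model_grid(), seed = 1, ...) {
  runs <- purrr::pmap(grid, function(model_id, feature_set, sampling,
                                     metric, threshold) {
    run_experiment(cohort,
                   experiment_spec(model_id, feature_set, sampling, metric,
                                   threshold, seed = seed),
                   ...)
  })
  names(runs) <- as.character(grid$model_id)
  runs
}

#' Summarise a list of runs as a model-comparison table
#'
#' @param runs List of `load_run` objects.
#' @return Tibble with one row per run.
#' @export
summarise_runs <- function(runs) {
  purrr::map_dfr(runs, glance)
}

#' Write evaluation reports and the run manifest to a directory
#'
#' Emits a model-comparison `summary.tsv` (model, sampling, distance,
#' observations, threshold, train/test sizes, class counts, sensitivity,
#' specificity, AUC), one `model_<id>.json` per run (metrics, ROC points,
#' manifest) and `manifest.json`. Reports contain no timestamps, so a
#' rerun with the same configuration and seed is byte-identical.
#'
#' @param runs List of `load_run` objects.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory (default
#'   `FALSE`: refuse).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(runs, out_dir, force = FALSE) {
  if (dir.exists(out_dir) &&
      length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) > 0 &&
      !force) {
    abort(sprintf("`%s` exists and is not empty; use force = TRUE", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- purrr::map_dfr(runs, function(r) {
    g <- glance(r)
    tibble(model = g$model_id,
           sampling = g$sampling,
           distance = g$metric,
           observations = ifelse(g$feature_set == "snps_only",
                                 "SNPs", "Z-score, APOE, phenotypes"),
           threshold = g$threshold,
           test = g$n_test, train = g$n_train,
           cases = g$train_cases, controls = g$train_controls,
           sensitivity = g$sensitivity, specificity = g$specificity,
           auc = g$auc)
  })
  readr::write_tsv(summary, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  for (r in runs) {
    payload <- list(
      metrics = glance(r),
      roc = r$eval$roc,
      sweep = as_tibble(r$sweep),
      optimal_threshold = r$optimal_threshold,
      manifest = r$manifest
    )
    jsonlite::write_json(
      payload, file.path(out_dir, sprintf("model_%s.json", r$spec$model_id)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }
  manifest <- purrr::map(runs, "manifest")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
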