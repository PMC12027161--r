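knn_metrics <- c("euclidean", "manhattan", "cosine")

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control"))) {
    abort("labels must be \"case\"/\"control\" or 0/1")
  }
  as.integer(labels == "case")
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), c("individual_id", "label"))]
    x <- as.matrix(x)
  }
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

#' Distance between two feature vectors
#'
#' Euclidean: `sqrt(sum((a - b)^2))`; Manhattan: `sum(|a - b|)`; cosine:
#' `1 - (a . b) / (|a| |b|)` (an angular dissimilarity, 0 for collinear
#' vectors of the same sign, undefined when either vector has zero norm).
#'
#' @param a,b Numeric vectors of equal length.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"cosine"`.
#' @return A non-negative number.
#' @export
#' @examples
#' knn_distance(c(0, 0), c(3, 4))            # 5
#' knn_distance(c(1, 0), c(0, 1), "cosine")  # 1
knn_distance <- function(a, b, metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  if (length(a) != length(b) || length(a) < 1) {
    abort("vectors must have equal positive length")
  }
  switch(metric,
    euclidean = sqrt(sum((a - b)^2)),
    manhattan = sum(abs(a - b)),
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) {
        abort("cosine distance undefined for a zero vector",
              class = "loadrisk_undefined_distance")
      }
      1 - sum(a * b) / (na * nb)
    }
  )
}

# full query x train distance matrix
pairwise_distances <- function(query, train, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(query^2), rep(1, nrow(train))) +
        outer(rep(1, nrow(query)), rowSums(train^2)) -
        2 * tcrossprod(query, train)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      d <- matrix(0, nrow(query), nrow(train))
      for (j in seq_len(ncol(query))) {
        d <- d + abs(outer(query[, j], train[, j], "-"))
      }
      d
    },
    cosine = {
      nq <- sqrt(rowSums(query^2)); nt <- sqrt(rowSums(train^2))
      if (any(nq == 0) || any(nt == 0)) {
        abort("cosine distance undefined for a zero vector",
              class = "loadrisk_undefined_distance")
      }
      1 - tcrossprod(query / nq, train / nt)
    },
    abort("unknown metric")
  )
}

# probabilities for every k in k_values at once: per query, neighbors are
# ranked once and the case fraction read off the cumulative vote count
knn_prob_grid <- function(train_x, train_y, query_x, metric, k_values) {
  d <- pairwise_distances(query_x, train_x, metric)
  ks <- as.integer(k_values)
  out <- matrix(NA_real_, nrow(query_x), length(ks))
  for (i in seq_len(nrow(query_x))) {
    ord <- order(d[i, ], method = "radix")  # stable: ties by training order
    cum <- cumsum(train_y[ord])
    out[i, ] <- cum[ks] / ks
  }
  colnames(out) <- as.character(ks)
  out
}

#' Case probability of a query point under k-nearest-neighbours
#'
#' The probability is the fraction of case-labelled rows among the `k`
#' training rows nearest to the query under the chosen metric. Distance
#' ties are broken by training-row order (stable sort).
#'
#' @param train Training features: numeric matrix or data frame
#'   (`individual_id` / `label` columns are ignored if present).
#' @param labels Training labels: `"case"`/`"control"`, 0/1 or logical.
#' @param query A single feature vector or a matrix / data frame of queries.
#' @param k Number of neighbours, `1 <= k <=` number of training rows.
#' @param metric Distance metric.
#' @return Numeric vector of case probabilities, one per query row.
#' @export
knn_probability <- function(train, labels, query, k,
                            metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  train_x <- as_feature_matrix(train)
  y <- as_case_indicator(labels)
  stopifnot(length(y) == nrow(train_x))
  k <- check_count(k, "k")
  if (k > nrow(train_x)) abort("`k` exceeds the number of training rows")
  query_x <- as_feature_matrix(query)
  if (ncol(query_x) != ncol(train_x)) {
    abort("query and training features have different dimension")
  }
  as.vector(knn_prob_grid(train_x, y, query_x, metric, k))
}

#' Threshold a case probability into a class label
#'
#' An individual is called a case exactly when `prob >= threshold`
#' (boundary inclusive, which favours sensitivity at a tuned cut-off).
#'
#' @param prob Numeric probabilities in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return Character vector of `"case"` / `"control"`.
#' @export
#' @examples
#' classify(c(0.42, 0.41), threshold = 0.42)
classify <- function(prob, threshold = 0.5) {
  check_fraction(threshold, "threshold")
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("probabilities must be in [0, 1]")
  }
  ifelse(prob >= threshold, "case", "control")
}

# stratified fold ids, deterministic given seed
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Select k by stratified cross-validated accuracy
#'
#' Stratified `folds`-fold cross-validation over a grid of candidate `k`
#' values; for each `k` the mean validation accuracy at threshold 0.5 is
#' recorded and the best `k` is the argmax, ties resolved toward the
#' smallest `k`. The default grid is the 60 odd values 1, 3, ..., 119
#' (odd `k` avoids 50:50 neighbour votes); values exceeding the smallest
#' fold's training size are dropped.
#'
#' @param features Training features (matrix or data frame).
#' @param labels Training labels.
#' @param metric Distance metric.
#' @param k_grid Candidate `k` values.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List with `best_k` and `cv_table` (tibble of `k`, `accuracy`).
#' @export
select_k <- function(features, labels,
                     metric = c("euclidean", "manhattan", "cosine"),
                     k_grid = seq(1, 119, by = 2), folds = 5, seed = 1) {
  metric <- match.arg(metric)
  x <- as_feature_matrix(features)
  y <- as_case_indicator(labels)
  check_count(folds, "folds")
  if (folds < 2) abort("`folds` must be >= 2")
  fold <- stratified_folds(y, folds, seed)
  min_train <- min(vapply(seq_len(folds),
                          function(f) sum(fold != f), integer(1)))
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid >= 1 & k_grid <= min_train]
  if (!length(k_grid)) abort("no feasible k in `k_grid`")

  acc <- matrix(NA_real_, folds, length(k_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      abort("a cross-validation fold lost one class; use fewer folds",
            class = "loadrisk_stratification_error")
    }
    probs <- knn_prob_grid(x[tr, , drop = FALSE], y[tr],
                           x[!tr, , drop = FALSE], metric, k_grid)
    pred <- probs >= 0.5
    acc[f, ] <- colMeans(pred == (y[!tr] == 1))
  }
  cv <- tibble(k = k_grid, accuracy = colMeans(acc))
  best <- cv$k[which.max(cv$accuracy)]  # which.max takes the first maximum
  list(best_k = as.integer(best), cv_table = cv)
}

#' Rebalance a labelled training set
#'
#' `"oversample"` duplicates minority-class rows uniformly at random with
#' replacement until the class counts are equal (every original row is
#' retained); `"subsample"` samples majority-class rows without replacement
#' down to the minority count; `"none"` returns the data unchanged.
#' Rebalancing is meant for the training partition only.
#'
#' @param data Data frame with a label column.
#' @param strategy One of `"none"`, `"oversample"`, `"subsample"`.
#' @param seed Integer seed.
#' @param label_col Name of the label column (default `"label"`).
#' @return The rebalanced tibble.
#' @export
rebalance <- function(data, strategy = c("none", "oversample", "subsample"),
                      seed = 1, label_col = "label") {
  strategy <- match.arg(strategy)
  y <- as_case_indicator(data[[label_col]])
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (strategy == "none") return(as_tibble(data))
  counts <- table(y)
  minority <- as.integer(names(counts)[which.min(counts)])
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  withr::with_seed(seed, {
    idx <- switch(strategy,
      oversample = {
        extra <- sample(min_idx, length(maj_idx) - length(min_idx),
                        replace = TRUE)
        c(seq_along(y), extra)
      },
      subsample = sort(c(min_idx, sample(maj_idx, length(min_idx))))
    )
  })
  as_tibble(data[idx, , drop = FALSE])
}

#' Stratified train/test split
#'
#' Splits ids into training and test sets; with `stratified = TRUE`
#' (default) the class ratio is preserved to rounding by sampling
#' `round(n_class * test_fraction)` test rows within each class.
#'
#' @param data Data frame with id and label columns.
#' @param test_fraction Fraction of rows assigned to the test set
#'   (default 0.30).
#' @param seed Integer seed.
#' @param stratified Preserve the class ratio exactly (default `TRUE`).
#' @param id_col,label_col Column names (defaults `"individual_id"`,
#'   `"label"`).
#' @return List of class `split_index` with `train_ids` and `test_ids`.
#' @export
split_cohort <- function(data, test_fraction = 0.30, seed = 1,
                         stratified = TRUE, id_col = "individual_id",
                         label_col = "label") {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1)")
  }
  ids <- as.character(data[[id_col]])
  y <- as_case_indicator(data[[label_col]])
  test <- character(0)
  withr::with_seed(seed, {
    if (stratified) {
      for (cl in sort(unique(y))) {
        cl_ids <- ids[y == cl]
        n_test <- round(length(cl_ids) * test_fraction)
        n_test <- max(1L, min(n_test, length(cl_ids) - 1L))
        test <- c(test, sample(cl_ids, n_test))
      }
    } else {
      n_test <- max(1L, min(round(length(ids) * test_fraction),
                            length(ids) - 1L))
      test <- sample(ids, n_test)
    }
  })
  structure(list(train_ids = setdiff(ids, test),
                 test_ids = ids[ids %in% test],
                 test_fraction = test_fraction, seed = seed,
                 stratified = stratified),
            class = "split_index")
}
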