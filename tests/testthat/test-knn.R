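test_that("pairwise distances match their textbook definitions", {
  expect_equal(knn_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(knn_distance(c(1, 2), c(4, 6), "manhattan"), 7)
  expect_equal(knn_distance(c(1, 0), c(0, 1), "cosine"), 1)
  v <- c(0.3, -1.2, 4)
  expect_equal(knn_distance(v, 2 * v, "cosine"), 0, tolerance = 1e-12)
  expect_error(knn_distance(c(0, 0), c(1, 1), "cosine"),
               class = "loadrisk_undefined_distance")
})

test_that("euclidean and manhattan satisfy the metric axioms on random triples", {
  withr::with_seed(1, {
    for (i in 1:50) {
      a <- rnorm(5); b <- rnorm(5); cc <- rnorm(5)
      for (metric in c("euclidean", "manhattan")) {
        expect_equal(knn_distance(a, b, metric), knn_distance(b, a, metric))
        expect_equal(knn_distance(a, a, metric), 0)
        expect_lte(knn_distance(a, cc, metric),
                   knn_distance(a, b, metric) + knn_distance(b, cc, metric) +
                     1e-12)
      }
      expect_equal(knn_distance(a, b, "cosine"),
                   knn_distance(b, a, "cosine"))
    }
  })
})

test_that("neighbour votes match hand counts on a toy configuration", {
  # 5 integer points on a line; query at 0
  train <- matrix(c(1, 2, 3, 10, 11), ncol = 1)
  y <- c("case", "control", "case", "control", "control")
  expect_equal(knn_probability(train, y, 0, k = 3), 2 / 3)
  expect_equal(knn_probability(train, y, 1, k = 1), 1)       # self-match
  # equidistant query, k = n: the vote degenerates to prevalence
  sq <- matrix(c(1, 1, -1, -1, 1, -1, 1, -1), ncol = 2)
  ysq <- c(1, 1, 1, 0)
  expect_equal(knn_probability(sq, ysq, c(0, 0), k = 4), 3 / 4)
  expect_error(knn_probability(train, y, 0, k = 6), "exceeds")
})

test_that("neighbour probabilities agree with the exhaustive oracle", {
  withr::with_seed(42, {
    for (i in 1:60) {
      n <- sample(5:50, 1); d <- sample(1:7, 1)
      x <- matrix(rnorm(n * d), n, d)
      y <- rbinom(n, 1, 0.4)
      q <- rnorm(d)
      k <- sample(c(1, 3, 5, 7), 1)
      k <- min(k, n)
      metric <- sample(c("euclidean", "manhattan", "cosine"), 1)
      expect_identical(knn_probability(x, y, q, k, metric),
                       oracle_knn_prob(x, y, q, k, metric))
    }
  })
})

test_that("permuting training rows leaves tie-free predictions unchanged", {
  withr::with_seed(7, {
    x <- matrix(rnorm(40 * 3), 40, 3)
    y <- rbinom(40, 1, 0.3)
    q <- matrix(rnorm(10 * 3), 10, 3)
    perm <- sample(40)
    expect_equal(knn_probability(x, y, q, 5),
                 knn_probability(x[perm, ], y[perm], q, 5))
  })
})

test_that("classification threshold is boundary-inclusive", {
  expect_equal(classify(0.42, 0.42), "case")
  expect_equal(classify(0.41, 0.42), "control")
  expect_true(all(classify(c(0, 0.5, 1), 0) == "case"))
})

test_that("cross-validated k selection honours the grid, ties and determinism", {
  # two well-separated clusters: every small k is perfect, tie-break -> k = 1
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(20 * 2, mean = 0), ncol = 2),
               matrix(rnorm(20 * 2, mean = 8), ncol = 2))
  })
  y <- rep(c("control", "case"), each = 20)
  sel <- select_k(x, y, k_grid = c(1, 3, 5, 7), seed = 5)
  expect_equal(sel$best_k, 1L)
  expect_equal(max(sel$cv_table$accuracy), 1)

  # the default grid has 60 candidate values
  expect_length(seq(1, 119, by = 2), 60)
  withr::with_seed(9, {
    xl <- matrix(rnorm(200 * 3), 200, 3)
    yl <- rbinom(200, 1, 0.4)
  })
  sel2 <- select_k(xl, yl, seed = 11)
  expect_equal(nrow(sel2$cv_table), 60)
  sel3 <- select_k(xl, yl, seed = 11)
  expect_identical(sel2$cv_table, sel3$cv_table)
})

test_that("rebalancing reaches exact parity and respects multiset bounds", {
  df <- tibble::tibble(individual_id = sprintf("i%03d", 1:100),
                       x = rnorm(100),
                       label = rep(c("case", "control"), c(23, 77)))
  over <- rebalance(df, "oversample", seed = 1)
  expect_equal(unname(table(over$label)["case"]), 77)
  expect_equal(unname(table(over$label)["control"]), 77)
  expect_true(all(df$individual_id %in% over$individual_id))  # superset

  sub <- rebalance(df, "subsample", seed = 1)
  expect_equal(as.integer(table(sub$label)), c(23L, 23L))
  expect_true(all(sub$individual_id %in% df$individual_id))   # subset
  expect_equal(anyDuplicated(sub$individual_id), 0L)

  balanced <- dplyr::mutate(df, label = rep(c("case", "control"), 50))
  expect_equal(nrow(rebalance(balanced, "oversample", seed = 2)), 100)
  expect_equal(nrow(rebalance(balanced, "subsample", seed = 2)), 100)
  expect_identical(rebalance(df, "none"), df)

  single <- dplyr::mutate(df, label = "case")
  expect_error(rebalance(single, "oversample"), "both classes")
})

test_that("stratified splitting preserves the class ratio to rounding", {
  df <- tibble::tibble(individual_id = sprintf("i%04d", 1:1000),
                       label = rep(c("case", "control"), c(230, 770)))
  sp <- split_cohort(df, test_fraction = 0.30, seed = 4)
  expect_length(sp$test_ids, 300)
  expect_length(sp$train_ids, 700)
  expect_equal(sum(df$label[df$individual_id %in% sp$test_ids] == "case"), 69)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)

  sp2 <- split_cohort(df, test_fraction = 0.30, seed = 4)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_error(split_cohort(df, test_fraction = 1.2), "must be in")
})
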