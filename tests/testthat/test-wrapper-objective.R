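test_that("binarization thresholds at 0.5 with 0.5 selecting", {
  expect_identical(binarize(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
  expect_identical(binarize(rep(0, 4)), rep(0L, 4))
  expect_identical(binarize(rep(1, 4)), rep(1L, 4))
  expect_error(binarize(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("knn_predict handles the elementary cases", {
  train <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6, 5, 4), ncol = 2, byrow = TRUE)
  y <- c("A", "A", "B", "B", "B")
  # single-class training set
  expect_equal(knn_predict(train[1:2, ], c("A", "A"),
                           matrix(c(9, 9), 1), k = 2), "A")
  # query identical to a training row, k = 1
  expect_equal(knn_predict(train, y, train[2, , drop = FALSE], k = 1), "A")
  # 2-D toy: brute-force sort of the five distances puts B in the majority
  expect_equal(knn_predict(train, y, matrix(c(4, 5), 1), k = 3), "B")
  expect_error(knn_predict(train[0, , drop = FALSE], character(0),
                           matrix(0, 1, 2)), "empty")
  expect_warning(pred <- knn_predict(train, y, matrix(c(4, 5), 1), k = 9),
                 "clamping")
  expect_equal(pred, "B")
})

test_that("knn_predict agrees with an independent brute-force reference", {
  set.seed(31)
  for (k in c(1, 3, 5)) {
    train <- matrix(rnorm(40 * 3), 40, 3)
    y <- sample(0:2, 40, replace = TRUE)
    query <- matrix(rnorm(15 * 3), 15, 3)
    expect_equal(knn_predict(train, y, query, k),
                 knn_reference(train, y, query, k))
  }
})

test_that("classification accuracy is the matching fraction", {
  expect_equal(classification_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 1)), 0.75)
  expect_equal(classification_accuracy(1:5, 1:5), 1)
  expect_equal(classification_accuracy(rep(0, 3), rep(1, 3)), 0)
  expect_error(classification_accuracy(integer(0), integer(0)), "nonempty")
  expect_error(classification_accuracy(1:3, 1:4), "equal length")
})

test_that("subset fitness combines validation error and selection fraction", {
  split <- make_separable_split(n = 60, n_features = 10, informative = 1)
  cfg <- fitness_config(alpha = 0.99, k = 5)
  # the separating feature alone classifies perfectly: alpha*(1-1) + 0.01*0.1
  mask1 <- c(1L, rep(0L, 9))
  expect_equal(subset_fitness(mask1, split, cfg), 0.001)
  # empty mask is infeasible
  expect_equal(subset_fitness(rep(0L, 10), split, cfg), 1)
  # the combination matches a by-hand evaluation of the weighted sum
  mask <- c(0L, 1L, 1L, 0L, 1L, rep(0L, 5))
  xt <- split$x[split$train, c(2, 3, 5)]
  xv <- split$x[split$valid, c(2, 3, 5)]
  xv_s <- sweep(sweep(xv, 2, apply(xt, 2, min), "-"),
                2, apply(xt, 2, max) - apply(xt, 2, min), "/")
  xt_s <- sweep(sweep(xt, 2, apply(xt, 2, min), "-"),
                2, apply(xt, 2, max) - apply(xt, 2, min), "/")
  p <- classification_accuracy(
    knn_predict(xt_s, split$y[split$train], xv_s, 5), split$y[split$valid])
  expect_equal(subset_fitness(mask, split, cfg),
               0.99 * (1 - p) + 0.01 * 3 / 10)
  expect_error(subset_fitness(rep(1L, 4), split, cfg), "does not match")
})

test_that("alpha limits recover misclassification rate and reduction ratio", {
  split <- make_separable_split(n = 60, n_features = 8, informative = 2)
  mask <- c(1L, 1L, 1L, 1L, rep(0L, 4))
  f1 <- subset_fitness(mask, split, fitness_config(alpha = 1))
  f0 <- subset_fitness(mask, split, fitness_config(alpha = 0))
  expect_equal(f0, 0.5)                        # 4 of 8 features
  expect_gte(f1, 0); expect_lte(f1, 1)
  fa <- subset_fitness(mask, split, fitness_config(alpha = 0.6))
  expect_equal(fa, 0.6 * f1 + 0.4 * f0)        # linear in the two sub-goals
})

test_that("fitness stays in [0,1], decreasing in P and increasing in N_f", {
  split <- make_separable_split(n = 60, n_features = 10, informative = 1)
  cfg <- fitness_config()
  fits <- vapply(0:9, function(extra) {
    mask <- integer(10); mask[1] <- 1L
    if (extra > 0) mask[1 + seq_len(extra)] <- 1L
    subset_fitness(mask, split, cfg)
  }, numeric(1))
  expect_true(all(fits >= 0 & fits <= 1))
  # the weighted sum itself is decreasing in accuracy and increasing in
  # subset size (alpha fixed); the KNN accuracy feeding it is data-dependent
  combine <- function(p, nf) cfg$alpha * (1 - p) + (1 - cfg$alpha) * nf / 10
  p_grid <- seq(0, 1, by = 0.1)
  for (nf in c(1, 5, 10)) {
    expect_true(all(diff(combine(p_grid, nf)) < 0))
  }
  for (p in c(0, 0.5, 1)) {
    expect_true(all(diff(combine(p, 1:10)) > 0))
  }
})

test_that("the continuous objective caches by mask and matches subset_fitness", {
  split <- make_separable_split(n = 48, n_features = 6, informative = 1)
  cfg <- fitness_config()
  obj <- feature_objective(split, cfg)
  pos <- c(0.9, 0.1, 0.2, 0.8, 0.3, 0.4)
  expect_equal(obj(pos), subset_fitness(binarize(pos), split, cfg))
  # a different position with the same mask returns the identical value
  expect_identical(obj(pos), obj(c(0.51, 0.49, 0.0, 1.0, 0.2, 0.3)))
})
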