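# Aggregation of repeated optimizer applications into run statistics,
# test accuracy, selection size, and Fisher scores.

#' Assemble a collection of independent runs
#'
#' Bundles the per-run best masks and fitness values of `M` independent
#' optimizer applications on one split, and computes each run's test-split
#' predictions (KNN trained on the training split restricted to the run's
#' mask). All downstream evaluation metrics read from this collection.
#'
#' A run whose best mask is empty predicts the training majority class for
#' every test row (deterministic fallback; the forced full-feature agent
#' makes this practically unreachable).
#'
#' @param masks list (or matrix, runs x features) of per-run best 0/1
#'   masks.
#' @param fitness numeric vector of per-run best fitness values.
#' @param split the `split_dataset` the runs were performed on.
#' @param config the [fitness_config()] used.
#' @return an object of class `run_collection`.
#' @export
run_collection <- function(masks, fitness, split, config = fitness_config()) {
  if (is.list(masks)) masks <- do.call(rbind, masks)
  masks <- matrix(as.integer(masks), nrow = length(fitness))
  if (nrow(masks) < 1) stop("at least one run is required", call. = FALSE)
  if (ncol(masks) != ncol(split$x)) {
    stop("mask length does not match the dataset features", call. = FALSE)
  }
  train_y <- split$y[split$train]
  majority <- as.integer(names(which.max(table(train_y))))
  predictions <- lapply(seq_len(nrow(masks)), function(i) {
    cols <- which(masks[i, ] != 0)
    if (length(cols) == 0) {
      return(rep(majority, length(split$test)))
    }
    xt <- split$x[split$train, cols, drop = FALSE]
    xs <- split$x[split$test, cols, drop = FALSE]
    if (config$scale) {
      xs <- scale_minmax(xs, xt)
      xt <- scale_minmax(xt, xt)
    }
    knn_predict(xt, train_y, xs, config$k)
  })
  structure(list(masks = masks, fitness = fitness,
                 test_predictions = predictions, split = split,
                 config = config),
            class = "run_collection")
}

#' Run statistics over repeated applications
#'
#' Mean, best (minimum), worst (maximum) and standard deviation of the
#' per-run best fitness values. The standard deviation uses the sample
#' `1/(M-1)` divisor and is an indicator of optimizer stability: small
#' values mean the optimizer converges to the same solution across runs.
#' With a single run the standard deviation is reported as `NA`.
#'
#' @param runs a `run_collection` or a numeric vector of per-run best
#'   fitness values.
#' @return list with `mean`, `best`, `worst`, `std`.
#' @export
run_statistics <- function(runs) {
  g <- if (inherits(runs, "run_collection")) runs$fitness else as.numeric(runs)
  if (length(g) == 0) stop("empty run collection", call. = FALSE)
  list(mean = mean(g), best = min(g), worst = max(g),
       std = if (length(g) >= 2) stats::sd(g) else NA_real_)
}

#' Average test-set classification accuracy
#'
#' Mean over runs of the per-run accuracy of the run's selected features
#' on the held-out test split.
#'
#' @param runs a `run_collection`.
#' @return value in `[0, 1]`.
#' @export
average_accuracy <- function(runs) {
  stopifnot(inherits(runs, "run_collection"))
  test_y <- runs$split$y[runs$split$test]
  mean(vapply(runs$test_predictions,
              function(p) classification_accuracy(p, test_y), numeric(1)))
}

#' Average selection size
#'
#' Mean over runs of the fraction of features selected,
#' `size(mask) / N_t`.
#'
#' @param runs a `run_collection`.
#' @return value in `(0, 1]` (0 only if every run selected nothing).
#' @export
average_selection_size <- function(runs) {
  stopifnot(inherits(runs, "run_collection"))
  mean(rowSums(runs$masks) / ncol(runs$masks))
}

#' Fisher scores of individual features
#'
#' Class-separability score of each feature `j`:
#' \deqn{F_j = \sum_k n_k (\mu_{kj} - \mu_j)^2 / \sigma_j^2,}
#' where \eqn{\mu_{kj}} is the class-`k` mean, and \eqn{\mu_j} and
#' \eqn{\sigma_j} are the mean and standard deviation of feature `j` over
#' the entire dataset (population convention, divisor `N`). Features with
#' zero overall variance get score 0 with a warning. The score is
#' invariant to affine rescaling of a feature and scales linearly with
#' replication of the samples.
#'
#' @param x numeric feature matrix.
#' @param y label vector with at least 2 classes.
#' @return nonnegative numeric vector, one score per feature.
#' @export
fisher_scores <- function(x, y) {
  x <- as.matrix(x)
  classes <- unique(y)
  if (length(classes) < 2) stop("fisher scores need at least 2 classes",
                                call. = FALSE)
  mu <- colMeans(x)
  sig2 <- colMeans(x^2) - mu^2            # population variance
  num <- numeric(ncol(x))
  for (cls in classes) {
    rows <- y == cls
    num <- num + sum(rows) * (colMeans(x[rows, , drop = FALSE]) - mu)^2
  }
  out <- numeric(ncol(x))
  zero <- sig2 <= 0
  if (any(zero)) warning(sum(zero), " feature(s) have zero variance; ",
                         "their fisher score is reported as 0")
  out[!zero] <- num[!zero] / sig2[!zero]
  out
}

#' Average Fisher score of the selected subsets
#'
#' For each run, the Fisher scores of that run's selected features are
#' aggregated (summed by default; `aggregate = "mean"` averages them) and
#' the aggregate is then averaged over runs. Scores are computed on the
#' entire dataset. Runs with an empty mask contribute 0.
#'
#' @param runs a `run_collection`.
#' @param aggregate `"sum"` (default) or `"mean"` within a run.
#' @return nonnegative scalar.
#' @export
average_fisher <- function(runs, aggregate = c("sum", "mean")) {
  stopifnot(inherits(runs, "run_collection"))
  aggregate <- match.arg(aggregate)
  fs <- fisher_scores(runs$split$x, runs$split$y)
  per_run <- apply(runs$masks, 1L, function(mask) {
    sel <- fs[mask != 0]
    if (length(sel) == 0) return(0)
    if (aggregate == "sum") sum(sel) else mean(sel)
  })
  mean(per_run)
}

#' @export
print.run_collection <- function(x, ...) {
  st <- run_statistics(x)
  cat("<run_collection> ", length(x$fitness), " runs over ", ncol(x$masks),
      " features; fitness mean ", signif(st$mean, 4), " [",
      signif(st$best, 4), ", ", signif(st$worst, 4), "]\n", sep = "")
  invisible(x)
}
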