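# Wrapper fitness: continuous position -> feature mask -> KNN validation
# error combined with the selection-size penalty.

#' Threshold a continuous position into a feature mask
#'
#' Each dimension of the position corresponds to one feature; values below
#' the static threshold 0.5 deselect the feature, values at or above 0.5
#' select it.
#'
#' @param position numeric vector with entries in `[0, 1]`.
#' @return integer 0/1 vector of the same length.
#' @export
binarize <- function(position) {
  if (any(position < 0 | position > 1)) {
    stop("position entries must lie in [0, 1]", call. = FALSE)
  }
  as.integer(position >= 0.5)
}

#' Fitness configuration for the wrapper objective
#'
#' @param alpha weight in `[0, 1]` of the classification-error sub-goal;
#'   the complementary weight `1 - alpha` multiplies the fraction of
#'   features retained. Default 0.99 (accuracy-dominant).
#' @param k number of nearest neighbours for the KNN classifier; default 5.
#' @param scale logical; min-max scale each feature to `[0, 1]` using
#'   training-split statistics before computing distances (default `TRUE`),
#'   so features with different units contribute comparably.
#' @return an object of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.99, k = 5, scale = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (k < 1) stop("k must be a positive integer", call. = FALSE)
  structure(list(alpha = alpha, k = as.integer(k), scale = isTRUE(scale)),
            class = "fitness_config")
}

#' Deterministic k-nearest-neighbour classification
#'
#' Euclidean-distance KNN with majority vote. Ties are resolved
#' deterministically: equal distances prefer the lower training-row index,
#' and a tied vote falls back to the label of the single nearest
#' neighbour.
#'
#' @param train_x numeric training matrix (rows = samples).
#' @param train_y label vector, one per training row.
#' @param query_x numeric matrix of query samples with the same columns.
#' @param k number of neighbours; values above `nrow(train_x)` are clamped
#'   with a warning.
#' @return predicted labels, one per query row.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 5) {
  train_x <- as.matrix(train_x)
  query_x <- as.matrix(query_x)
  n <- nrow(train_x)
  if (n == 0) stop("training set is empty", call. = FALSE)
  if (length(train_y) != n) {
    stop("train_y length must match nrow(train_x)", call. = FALSE)
  }
  if (k > n) {
    warning("k = ", k, " exceeds the ", n,
            " training rows; clamping k to ", n)
    k <- n
  }
  # squared Euclidean distances, queries x training rows
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(query_x, train_x)
  labels <- unique(train_y)
  pred_idx <- vapply(seq_len(nrow(query_x)), function(i) {
    ord <- order(d2[i, ])                    # stable: distance ties by index
    nb <- train_y[ord[seq_len(k)]]
    counts <- tabulate(match(nb, labels), nbins = length(labels))
    winners <- which(counts == max(counts))
    if (length(winners) == 1L) winners else match(nb[1L], labels)
  }, integer(1))
  labels[pred_idx]
}

#' Classification performance
#'
#' Fraction of instances whose predicted label matches the reference
#' label.
#'
#' @param pred,ref label vectors of equal, positive length.
#' @return a value in `[0, 1]`.
#' @export
classification_accuracy <- function(pred, ref) {
  if (length(pred) == 0 || length(pred) != length(ref)) {
    stop("pred and ref must be nonempty vectors of equal length",
         call. = FALSE)
  }
  mean(pred == ref)
}

# min-max scale columns of `x` with statistics taken from `train`;
# zero-range columns map to 0
scale_minmax <- function(x, train) {
  mins <- apply(train, 2L, min)
  span <- apply(train, 2L, max) - mins
  span[span == 0] <- 1
  sweep(sweep(x, 2L, mins, "-"), 2L, span, "/")
}

#' Bi-objective fitness of a feature subset
#'
#' Trains the KNN classifier on the training split restricted to the
#' mask's features, measures its accuracy `P` on the validation split, and
#' returns the minimized fitness
#' \deqn{\alpha (1 - P) + (1 - \alpha)\, N_f / N_t,}
#' where `N_f` is the number of selected and `N_t` the total number of
#' features. The empty mask is infeasible and scores the worst possible
#' value, 1.
#'
#' The test split is never touched here; it is reserved for final
#' reporting.
#'
#' @param mask 0/1 vector of length `N_t` (one entry per feature).
#' @param split a `split_dataset` from [three_way_split()].
#' @param config a [fitness_config()].
#' @return fitness value in `[0, 1]`.
#' @export
subset_fitness <- function(mask, split, config = fitness_config()) {
  n_total <- ncol(split$x)
  if (length(mask) != n_total) {
    stop("mask length ", length(mask), " does not match the ", n_total,
         " dataset features", call. = FALSE)
  }
  n_sel <- sum(mask != 0)
  if (n_sel == 0) return(1)
  cols <- which(mask != 0)
  xt <- split$x[split$train, cols, drop = FALSE]
  xv <- split$x[split$valid, cols, drop = FALSE]
  if (config$scale) {
    xv <- scale_minmax(xv, xt)
    xt <- scale_minmax(xt, xt)
  }
  pred <- knn_predict(xt, split$y[split$train], xv, config$k)
  perf <- classification_accuracy(pred, split$y[split$valid])
  config$alpha * (1 - perf) + (1 - config$alpha) * n_sel / n_total
}

#' Build the continuous optimizer objective for a dataset
#'
#' Returns a function over `[0, 1]^N_t` that thresholds its argument with
#' [binarize()] and scores the mask with [subset_fitness()]. Fitness values
#' are cached per mask, so re-visiting a subset costs nothing; the cache
#' has no effect on the optimizer's random stream.
#'
#' @inheritParams subset_fitness
#' @return a function `position -> fitness`.
#' @export
feature_objective <- function(split, config = fitness_config()) {
  cache <- new.env(parent = emptyenv())
  force(split); force(config)
  function(position) {
    mask <- binarize(position)
    key <- paste(mask, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- subset_fitness(mask, split, config)
    assign(key, val, envir = cache)
    val
  }
}
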