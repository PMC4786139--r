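# Dataset ingestion, the three-way split protocol, the synthetic generator
# with planted informative features, and the exhaustive-search oracle.

#' Load a delimited classification dataset
#'
#' Reads a UCI-style delimited text file: one row per sample, numeric
#' feature columns and a single class-label column. The delimiter is
#' auto-detected from the extension (`.csv` comma, anything else tab).
#' Labels are mapped to integers `0..c-1` in order of first appearance.
#'
#' @param path path to the file.
#' @param label_column `"last"` (default) or the name of the label column.
#' @param header logical; does the file carry a header row (default `TRUE`).
#' @return list with numeric matrix `x` (samples x features), integer label
#'   vector `y`, and `labels`, the original label values in encoding order.
#' @export
load_dataset <- function(path, label_column = "last", header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("dataset needs at least one feature column and one ",
                         "label column", call. = FALSE)
  lab_idx <- if (identical(label_column, "last")) ncol(df) else {
    idx <- match(label_column, names(df))
    if (is.na(idx)) stop("label column '", label_column, "' not found",
                         call. = FALSE)
    idx
  }
  raw_y <- df[[lab_idx]]
  feat <- df[, -lab_idx, drop = FALSE]
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))[1]
      if (!is.na(bad) || anyNA(vn)) {
        row <- if (!is.na(bad)) bad else which(is.na(vn))[1]
        stop("non-numeric feature value at row ", row, ", column '",
             names(feat)[j], "'", call. = FALSE)
      }
      feat[[j]] <- vn
    }
    if (anyNA(feat[[j]])) {
      stop("missing feature value at row ", which(is.na(feat[[j]]))[1],
           ", column '", names(feat)[j], "'", call. = FALSE)
    }
  }
  if (anyNA(raw_y)) stop("missing class label at row ",
                         which(is.na(raw_y))[1], call. = FALSE)
  labels <- unique(raw_y)
  if (length(labels) < 2) stop("dataset must contain at least 2 classes",
                               call. = FALSE)
  x <- as.matrix(feat)
  dimnames(x) <- list(NULL, names(feat))
  message("loaded ", nrow(x), " samples x ", ncol(x), " features, ",
          length(labels), " classes")
  list(x = x, y = match(raw_y, labels) - 1L, labels = labels)
}

#' Stratified three-way split
#'
#' Partitions the samples into training, validation and test thirds:
#' within each class the (seeded) shuffled indices are dealt into three
#' sets of equal size (within one sample), so every class is represented
#' in every split. The validation third drives the wrapper fitness during
#' optimization; the test third is reserved for final reporting.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y label vector; every class needs at least 3 samples.
#' @param seed optional integer seed; the same seed reproduces the split.
#' @return an object of class `split_dataset`: list with `x`, `y` and
#'   disjoint index vectors `train`, `valid`, `test` covering all rows.
#' @export
three_way_split <- function(x, y, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  counts <- table(y)
  if (any(counts < 3)) {
    stop("every class needs at least 3 samples for a three-way split; class '",
         names(counts)[which(counts < 3)[1]], "' has ",
         min(counts), call. = FALSE)
  }
  with_seed(seed, {
    train <- integer(0); valid <- integer(0); test <- integer(0)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      n <- length(idx)
      base <- n %/% 3
      sizes <- rep(base, 3)
      extra <- n - 3 * base
      if (extra >= 1) sizes[1] <- sizes[1] + 1
      if (extra == 2) sizes[2] <- sizes[2] + 1
      train <- c(train, idx[seq_len(sizes[1])])
      valid <- c(valid, idx[sizes[1] + seq_len(sizes[2])])
      test <- c(test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
    structure(list(x = x, y = y, train = sort(train), valid = sort(valid),
                   test = sort(test)),
              class = "split_dataset")
  })
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> ", nrow(x$x), " samples x ", ncol(x$x), " features (",
      length(unique(x$y)), " classes); train/valid/test = ",
      length(x$train), "/", length(x$valid), "/", length(x$test), "\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic classification dataset with planted features
#'
#' Emulates the structure of small biomedical classification datasets:
#' balanced classes, a known subset of informative dimensions drawn from
#' class-conditional Gaussians whose means are `delta * sigma` apart
#' between consecutive classes, and pure-noise dimensions drawn
#' identically for every class. The informative columns are placed at
#' seeded random positions and their indices returned, so feature-recovery
#' rates can be measured against ground truth.
#'
#' @param n_samples total number of samples; classes are balanced to
#'   within one sample.
#' @param n_informative number of class-separated columns, at least 1.
#' @param n_noise number of pure-noise columns.
#' @param delta class-mean separation in units of `sigma`; `delta = 0`
#'   plants no signal.
#' @param sigma common within-class standard deviation; default 1.
#' @param n_classes number of classes; default 2.
#' @param seed optional integer seed.
#' @return list with matrix `x`, integer labels `y` (0-based), and
#'   `informative`, the sorted column indices carrying signal.
#' @export
generate_synthetic <- function(n_samples = 300, n_informative = 3,
                               n_noise = 7, delta = 3, sigma = 1,
                               n_classes = 2, seed = NULL) {
  stopifnot(n_informative >= 1, n_noise >= 0, delta >= 0, sigma > 0,
            n_classes >= 2, n_samples >= n_classes)
  with_seed(seed, {
    per <- n_samples %/% n_classes
    extra <- n_samples %% n_classes
    y <- rep(seq_len(n_classes) - 1L,
             times = per + (seq_len(n_classes) <= extra))
    n_total <- n_informative + n_noise
    informative <- sort(sample.int(n_total, n_informative))
    x <- matrix(stats::rnorm(n_samples * n_total, sd = sigma),
                n_samples, n_total)
    for (j in informative) {
      x[, j] <- x[, j] + y * delta * sigma
    }
    colnames(x) <- paste0("f", seq_len(n_total))
    list(x = x, y = y, informative = informative)
  })
}

#' Exhaustive feature-subset oracle
#'
#' Evaluates [subset_fitness()] for every nonempty mask over at most 15
#' features (2^15 - 1 subsets) and returns the global minimum; fitness
#' ties resolve to the lexicographically smallest mask. No population
#' optimizer can attain a lower fitness on the same split and
#' configuration, which makes the oracle the reference for convergence
#' checks on small feature spaces.
#'
#' @param split a `split_dataset`.
#' @param config a [fitness_config()].
#' @param max_features refusal threshold on the number of features
#'   (default 15).
#' @return list with the optimal `mask` (0/1 integer vector) and its
#'   `fitness`.
#' @export
exhaustive_oracle <- function(split, config = fitness_config(),
                              max_features = 15) {
  n_total <- ncol(split$x)
  if (n_total > max_features) {
    stop("exhaustive search over ", n_total, " features means 2^", n_total,
         " subsets; refusing above ", max_features,
         " — use alo_run() instead", call. = FALSE)
  }
  best_fit <- Inf
  best_mask <- NULL
  best_key <- NULL
  for (m in seq_len(2^n_total - 1)) {
    mask <- as.integer(intToBits(m))[seq_len(n_total)]
    fit <- subset_fitness(mask, split, config)
    key <- paste(mask, collapse = "")
    if (fit < best_fit || (fit == best_fit && key < best_key)) {
      best_fit <- fit
      best_mask <- mask
      best_key <- key
    }
  }
  list(mask = best_mask, fitness = best_fit)
}
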