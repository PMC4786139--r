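# Shared fixtures, built in code at test time.

# A small two-class dataset where the listed columns separate the classes
# perfectly (means +/- sep) and the rest are pure noise.
make_separable_split <- function(n = 60, n_features = 6, informative = 1,
                                 sep = 5, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * n_features), n, n_features)
  for (j in informative) x[, j] <- x[, j] + ifelse(y == 1, sep, -sep)
  three_way_split(x, y, seed = seed)
}

# Plain brute-force KNN reference, deliberately written differently from
# knn_predict(): per-query loop with repeated which.min extraction.
knn_reference <- function(train_x, train_y, query_x, k) {
  apply(query_x, 1L, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nb <- integer(0)
    dd <- d
    for (i in seq_len(k)) {
      j <- which.min(dd)       # which.min takes the first = lowest index
      nb <- c(nb, j)
      dd[j] <- Inf
    }
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      type.convert(top, as.is = TRUE)
    } else {
      train_y[nb[1]]
    }
  })
}

# Write a small CSV dataset and return its path.
write_toy_csv <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  path
}
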