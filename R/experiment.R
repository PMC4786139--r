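# Reproducible multi-run experiments: M independent optimizer applications
# per optimizer/map, metric aggregation, and report round-tripping.

# Parse an optimizer name ("alo", "calo-tent", "calo-logistic", ...) into
# an alo_schedule.
optimizer_schedule <- function(name) {
  if (identical(name, "alo")) return(alo_schedule("base"))
  if (grepl("^calo-", name)) {
    return(alo_schedule("chaotic", map = chaotic_map(sub("^calo-", "", name))))
  }
  stop("unknown optimizer '", name, "'; use 'alo' or 'calo-<map>'",
       call. = FALSE)
}

#' Single feature-selection run
#'
#' One application of the (chaotic) antlion optimizer to a split dataset:
#' the continuous search runs over `[0, 1]^{N_t}` against the wrapper
#' objective of [feature_objective()], with the all-ones (full-feature)
#' position forced into the initial populations so the returned subset is
#' never worse than using every feature.
#'
#' @param split a `split_dataset` from [three_way_split()].
#' @param optimizer `"alo"` or `"calo-<map>"` with `<map>` one of the
#'   [chaotic_map()] names, e.g. `"calo-tent"`.
#' @param agents,iterations population size and iteration count;
#'   defaults 8 and 70.
#' @param config a [fitness_config()].
#' @param seed optional integer seed.
#' @param force_full force the all-ones position into the initial
#'   populations (default `TRUE`).
#' @return list with the selected `mask`, its validation `fitness`, the
#'   elite-fitness `trace`, and the continuous best `position`.
#' @export
feature_selection_run <- function(split, optimizer = "calo-tent", agents = 8,
                                  iterations = 70,
                                  config = fitness_config(), seed = NULL,
                                  force_full = TRUE) {
  stopifnot(inherits(split, "split_dataset"))
  n_total <- ncol(split$x)
  objective <- feature_objective(split, config)
  res <- alo_run(objective, dim = n_total, lower = 0, upper = 1,
                 agents = agents, iterations = iterations,
                 schedule = optimizer_schedule(optimizer), seed = seed,
                 forced = if (force_full) rep(1, n_total) else NULL)
  list(mask = binarize(res$best_position), fitness = res$best_fitness,
       trace = res$trace, position = res$best_position)
}

#' Run a multi-optimizer feature-selection experiment
#'
#' For each requested optimizer, performs `runs` independent applications
#' on one stratified three-way split of the data (per-run seed =
#' `seed + run index`, so runs are independent yet reproducible), always
#' forcing the full-feature position into the initial populations.
#' Aggregates each optimizer's [run_collection()] into the full metric
#' suite: fitness mean/best/worst/std, average test accuracy, average
#' selection size, and average Fisher score of the selected subsets.
#'
#' A failing run is recorded and skipped; its optimizer's metrics are
#' computed from the remaining runs and the failure count is reported.
#'
#' @param x,y feature matrix and labels, or pass a ready-made `split`.
#' @param split optional `split_dataset`; overrides `x`/`y`.
#' @param optimizers character vector of optimizer names; default compares
#'   base ALO with the five chaotic variants.
#' @param runs number of independent applications per optimizer;
#'   default 20.
#' @param agents,iterations optimizer size; defaults 8 and 70.
#' @param alpha,k fitness weighting and KNN neighbours; defaults 0.99
#'   and 5.
#' @param seed base seed (also seeds the split when built here).
#' @return an object of class `calo_experiment`: list with the metric
#'   `report` data frame (one row per optimizer), per-optimizer
#'   `collections`, and the `config`.
#' @examples
#' \donttest{
#' d <- generate_synthetic(n_samples = 120, n_informative = 2, n_noise = 4,
#'                         delta = 3, seed = 7)
#' ex <- run_experiment(d$x, d$y, optimizers = c("alo", "calo-tent"),
#'                      runs = 2, iterations = 15, seed = 7)
#' ex$report
#' }
#' @export
run_experiment <- function(x = NULL, y = NULL, split = NULL,
                           optimizers = c("alo", "calo-logistic",
                                          "calo-piecewise", "calo-singer",
                                          "calo-sinusoidal", "calo-tent"),
                           runs = 20, agents = 8, iterations = 70,
                           alpha = 0.99, k = 5, seed = 1) {
  if (is.null(split)) {
    if (is.null(x) || is.null(y)) stop("provide x and y, or a split",
                                       call. = FALSE)
    split <- three_way_split(x, y, seed = seed)
  }
  config <- fitness_config(alpha = alpha, k = k)
  collections <- list()
  rows <- list()
  for (opt in optimizers) {
    masks <- list(); fits <- numeric(0); failures <- 0L
    for (r in seq_len(runs)) {
      run <- tryCatch(
        feature_selection_run(split, optimizer = opt, agents = agents,
                              iterations = iterations, config = config,
                              seed = seed + r),
        error = function(e) {
          warning("run ", r, " of ", opt, " failed: ", conditionMessage(e))
          NULL
        })
      if (is.null(run)) { failures <- failures + 1L; next }
      masks[[length(masks) + 1L]] <- run$mask
      fits <- c(fits, run$fitness)
    }
    if (length(fits) == 0) stop("all runs of ", opt, " failed", call. = FALSE)
    rc <- run_collection(masks, fits, split, config)
    collections[[opt]] <- rc
    st <- run_statistics(rc)
    rows[[opt]] <- data.frame(
      optimizer = opt, runs = length(fits), failed = failures,
      mean_fitness = st$mean, best_fitness = st$best,
      worst_fitness = st$worst, std_fitness = st$std,
      avg_accuracy = average_accuracy(rc),
      avg_selection_size = average_selection_size(rc),
      avg_fisher = average_fisher(rc),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, collections = collections,
                 config = list(optimizers = optimizers, runs = runs,
                               agents = agents, iterations = iterations,
                               alpha = alpha, k = k, seed = seed)),
            class = "calo_experiment")
}

#' @export
print.calo_experiment <- function(x, ...) {
  cat("<calo_experiment> ", x$config$runs, " runs x ",
      nrow(x$report), " optimizers (", x$config$agents, " agents, ",
      x$config$iterations, " iterations, seed ", x$config$seed, ")\n",
      sep = "")
  print(x$report, digits = 4)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes the metric table as CSV and a structured YAML sidecar
#' (`<path>.meta.yml`) carrying the configuration, per-run seeds, per-run
#' masks as bitstrings, and package/R versions for provenance. The pair
#' round-trips through [read_report()].
#'
#' @param experiment a `calo_experiment` from [run_experiment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(experiment, path) {
  stopifnot(inherits(experiment, "calo_experiment"))
  if (nrow(experiment$report) == 0) stop("report is empty", call. = FALSE)
  utils::write.csv(experiment$report, path, row.names = FALSE)
  cfg <- experiment$config
  meta <- list(
    config = cfg,
    run_seeds = cfg$seed + seq_len(cfg$runs),
    masks = lapply(experiment$collections, function(rc) {
      apply(rc$masks, 1L, paste, collapse = "")
    }),
    versions = list(package = as.character(utils::packageVersion("caloFS")),
                    r = paste(R.version$major, R.version$minor, sep = "."))
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' Read back a written report
#'
#' @param path the CSV path given to [write_report()].
#' @return list with the `report` data frame and the `meta` list from the
#'   YAML sidecar (if present).
#' @export
read_report <- function(path) {
  report <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.yml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  list(report = report, meta = meta)
}
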