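#' Control parameters for benchmark comparisons
#'
#' Per-method settings shared by [run_comparison()] and
#' [reproduce_simulation_table()].
#'
#' @param B ensemble size for the bagged / random-subspace / MFS kNN
#'   comparators, default 1001 (mirroring the ensemble's own m).
#' @param m stage-one model count for the subset-kNN ensemble.
#' @param subset_size features per member; \code{NULL} means
#'   \code{max(2, floor(d / 3))}.
#' @param k_grid candidate neighbour counts for cross-validated k.
#' @param reselect_fraction,validation_fraction,combine_rule passed to
#'   [esknn_config()].
#' @return A list of class \code{"comparison_control"}.
#' @export
comparison_control <- function(B = 1001L, m = 1001L, subset_size = NULL,
                               k_grid = 1:10, reselect_fraction = 0.4,
                               validation_fraction = 0.3,
                               combine_rule = "mean_prob") {
  structure(list(B = as.integer(B), m = as.integer(m),
                 subset_size = subset_size, k_grid = as.integer(k_grid),
                 reselect_fraction = reselect_fraction,
                 validation_fraction = validation_fraction,
                 combine_rule = combine_rule),
            class = "comparison_control")
}

knn_family <- c("knn", "bknn", "rknn", "mfs")

apply_method <- function(method, train, test_x, control, k_shared) {
  switch(method,
    knn = classify_from_probability(
      knn_class1_probability(train, test_x, k_shared)),
    bknn = bagged_knn_predict(train, test_x, B = control$B, k = k_shared),
    rknn = random_knn_predict(train, test_x, B = control$B,
                              subset_size = control$subset_size,
                              k = k_shared),
    mfs = mfs_knn_predict(train, test_x, B = control$B,
                          subset_size = control$subset_size, k = k_shared),
    esknn = {
      cfg <- esknn_config(m = control$m, subset_size = control$subset_size,
                          reselect_fraction = control$reselect_fraction,
                          validation_fraction = control$validation_fraction,
                          k_grid = control$k_grid,
                          combine_rule = control$combine_rule)
      predict(fit_esknn(train, cfg), test_x)
    },
    rf = external_comparator_predict("rf", train, test_x),
    svm = external_comparator_predict("svm", train, test_x),
    stop(sprintf("unknown method '%s'", method))
  )
}

#' Benchmark several methods on repeated train/test splits
#'
#' For each of \code{n_splits} stratified 90/10 (by default) partitions,
#' every method is trained on the same training part and evaluated on the
#' same test part; per-split misclassification rates are retained so any
#' aggregate can be audited. For the kNN-family methods the neighbour count
#' is selected once per split by stratified 10-fold cross-validation on the
#' training part and shared (the subset-kNN ensemble performs its own
#' selection on its construction part).
#'
#' @param data a [knn_dataset()].
#' @param methods character vector from \code{knn, bknn, rknn, mfs, esknn,
#'   rf, svm}.
#' @param n_splits number of random splits, default 1000.
#' @param test_fraction test share per split, default 0.1.
#' @param control a [comparison_control()].
#' @param seed optional integer seed governing all splits and methods.
#' @param verbose if \code{TRUE}, one message per split and method with the
#'   observed rate.
#' @return A data frame of class \code{"esknn_results"} with columns
#'   \code{method}, \code{mean_mr}, \code{se} (standard error of the mean
#'   over splits) and \code{n_splits}; the per-split rate matrix is in
#'   \code{attr(x, "per_split")} and the per-split test indices in
#'   \code{attr(x, "split_indices")}.
#' @export
run_comparison <- function(data, methods = c("knn", "esknn"),
                           n_splits = 1000L, test_fraction = 0.1,
                           control = comparison_control(), seed = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(data, "knn_dataset"),
            inherits(control, "comparison_control"))
  if (length(methods) == 0L) stop("`methods` is empty")
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop("`n_splits` must be positive")
  if (!is.null(seed)) set.seed(seed)
  rates <- matrix(NA_real_, n_splits, length(methods),
                  dimnames = list(NULL, methods))
  split_indices <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- train_test_split(data, test_fraction)
    split_indices[[s]] <- sp$second_indices
    k_shared <- if (any(methods %in% knn_family))
      select_k_cv(sp$first, control$k_grid) else NA_integer_
    for (j in seq_along(methods)) {
      pred <- apply_method(methods[j], sp$first, sp$second$x, control, k_shared)
      rates[s, j] <- misclassification_rate(sp$second$y, pred)
      if (verbose)
        message(sprintf("split %d method %s rate %.4f", s, methods[j],
                        rates[s, j]))
    }
  }
  out <- data.frame(method = methods,
                    mean_mr = colMeans(rates),
                    se = apply(rates, 2L, stats::sd) / sqrt(n_splits),
                    n_splits = n_splits, row.names = NULL)
  class(out) <- c("esknn_results", "data.frame")
  attr(out, "per_split") <- rates
  attr(out, "split_indices") <- split_indices
  out
}

#' Reproduce the simulation benchmark tables
#'
#' For each scenario (a count of appended non-informative features, at a
#' fixed variance multiplier \code{w} for the Gaussian model), generates
#' \code{reps} independent datasets, evaluates every method on one
#' stratified 90/10 split of each dataset, and averages the
#' misclassification rates across datasets.
#'
#' @param model 1 (correlated-Gaussian classes) or 2 (distance-band
#'   Bernoulli).
#' @param noise vector of appended noise-feature counts defining the
#'   scenarios, default \code{c(0, 50, 100, 200, 500)}.
#' @param w variance multiplier for model 1 (ignored for model 2).
#' @param reps independent datasets per scenario, default 100.
#' @param methods methods to compare, as in [run_comparison()].
#' @param control a [comparison_control()].
#' @param seed optional integer seed.
#' @param verbose forwarded to [run_comparison()].
#' @return A data frame of class \code{"esknn_table"} with one row per
#'   (scenario, method): columns \code{model}, \code{noise}, \code{w},
#'   \code{method}, \code{mean_mr}, \code{se}, \code{reps}. Per-replicate
#'   rates are kept in \code{attr(x, "per_rep")}.
#' @export
reproduce_simulation_table <- function(model = 2L,
                                       noise = c(0L, 50L, 100L, 200L, 500L),
                                       w = 1, reps = 100L,
                                       methods = c("knn", "bknn", "rknn",
                                                   "mfs", "esknn"),
                                       control = comparison_control(),
                                       seed = NULL, verbose = FALSE) {
  if (!model %in% c(1L, 2L)) stop("`model` must be 1 or 2")
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be positive")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  per_rep <- list()
  for (nz in noise) {
    rates <- matrix(NA_real_, reps, length(methods),
                    dimnames = list(NULL, methods))
    for (r in seq_len(reps)) {
      data <- if (model == 1L)
        simulate_model1(model1_spec(w = w, n_noise = nz))
      else
        simulate_model2(model2_spec(n_noise = nz))
      res <- run_comparison(data, methods, n_splits = 1L,
                            control = control, verbose = verbose)
      rates[r, ] <- attr(res, "per_split")[1L, ]
    }
    per_rep[[as.character(nz)]] <- rates
    rows[[as.character(nz)]] <- data.frame(
      model = model, noise = nz, w = if (model == 1L) w else NA_real_,
      method = methods, mean_mr = colMeans(rates),
      se = apply(rates, 2L, stats::sd) / sqrt(reps), reps = reps,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("esknn_table", "data.frame")
  attr(out, "per_rep") <- per_rep
  out
}

#' Write a results table as TSV with a metadata header
#'
#' @param table an \code{"esknn_results"} or \code{"esknn_table"} data
#'   frame.
#' @param path output path.
#' @param meta named list written as \code{# key: value} header lines
#'   (seed, reps, package version and similar provenance).
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(table, path, meta = list()) {
  meta <- c(list(package = paste0("esknn ",
                                  as.character(utils::packageVersion("esknn"))),
                 date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, meta[[key]]), con)
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
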