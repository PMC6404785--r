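#' Construct a binary-class dataset
#'
#' Bundles a numeric feature matrix with a 0/1 label vector. All model
#' fitting and prediction functions in the package operate on this
#' container.
#'
#' @param x numeric matrix (or data frame coercible to one), one row per
#'   observation, one column per feature.
#' @param y label vector of the same length as \code{nrow(x)} with entries
#'   in \code{\{0, 1\}}.
#' @param feature_names optional character vector of feature identifiers;
#'   defaults to the column names of \code{x}.
#' @return An object of class \code{"knn_dataset"}: a list with elements
#'   \code{x} (matrix), \code{y} (integer vector) and \code{feature_names}.
#' @examples
#' d <- knn_dataset(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' d
#' @export
knn_dataset <- function(x, y, feature_names = colnames(x)) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("`x` needs at least one row and one column")
  if (anyNA(x)) stop("`x` contains missing values")
  y <- as.integer(y)
  if (length(y) != nrow(x))
    stop("`y` must have one label per row of `x`")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(ncol(x)))
  if (length(feature_names) != ncol(x))
    stop("`feature_names` must have one entry per column")
  colnames(x) <- feature_names
  structure(list(x = x, y = y, feature_names = feature_names),
            class = "knn_dataset")
}

#' @export
print.knn_dataset <- function(x, ...) {
  cat(sprintf("<knn_dataset> %d observations x %d features; class 1: %d, class 0: %d\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' @export
dim.knn_dataset <- function(x) dim(x$x)

as_query_matrix <- function(queries) {
  if (inherits(queries, "knn_dataset")) return(queries$x)
  if (is.data.frame(queries)) queries <- as.matrix(queries)
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1L)
  storage.mode(queries) <- "double"
  queries
}

#' Read a delimited dataset with a binary label column
#'
#' Reads a header-ed delimited text file, takes one column as the class
#' label and all remaining numeric columns as features. Labels may be coded
#' \code{0}/\code{1} directly or as two arbitrary strings, which are mapped
#' to 0/1 alphabetically (the mapping is reported via \code{message()}).
#' Rows containing missing values are dropped with a message stating the
#' count.
#'
#' @param file path to the delimited file.
#' @param label_col name of the label column.
#' @param sep field separator, default comma.
#' @return A [knn_dataset()].
#' @export
read_dataset <- function(file, label_col, sep = ",") {
  df <- read.csv(file, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df))
    stop(sprintf("label column '%s' not found (columns: %s)",
                 label_col, paste(names(df), collapse = ", ")))
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  ylab <- df[[label_col]]
  xdf <- df[setdiff(names(df), label_col)]
  if (!all(vapply(xdf, is.numeric, logical(1L))))
    stop("all feature columns must be numeric")
  lev <- sort(unique(as.character(ylab)))
  if (length(lev) != 2L)
    stop(sprintf("label column must have exactly two distinct values, found %d",
                 length(lev)))
  if (setequal(lev, c("0", "1"))) {
    y <- as.integer(as.character(ylab))
  } else {
    y <- as.integer(as.character(ylab) == lev[2L])
    message(sprintf("label mapping: '%s' -> 0, '%s' -> 1", lev[1L], lev[2L]))
  }
  knn_dataset(as.matrix(xdf), y)
}

# Stratified sampling of `fraction` of the data into the second part.
# The overall second-part size is round(n * fraction); per-class counts are
# apportioned by largest remainder and clamped so that both parts retain
# both classes.
stratified_second_indices <- function(y, fraction) {
  n <- length(y)
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(cl) sum(y == cl), integer(1L))
  if (any(sizes < 2L))
    stop("each class needs at least 2 observations to split")
  total <- round(n * fraction)
  ideal <- sizes * fraction
  take <- floor(ideal)
  rem <- total - sum(take)
  if (rem > 0L) {
    ord <- order(-(ideal - take), seq_along(classes))
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(pmax(take, 1L), sizes - 1L)
  idx <- integer(0L)
  for (j in seq_along(classes)) {
    members <- which(y == classes[j])
    idx <- c(idx, sample(members, take[j]))
  }
  sort(idx)
}

split_pair <- function(data, second_idx) {
  first_idx <- setdiff(seq_along(data$y), second_idx)
  structure(list(
    first = knn_dataset(data$x[first_idx, , drop = FALSE], data$y[first_idx],
                        data$feature_names),
    second = knn_dataset(data$x[second_idx, , drop = FALSE], data$y[second_idx],
                         data$feature_names),
    first_indices = first_idx,
    second_indices = second_idx
  ), class = "knn_split")
}

#' Stratified train/test split
#'
#' Partitions a dataset into a training part and a test part of size
#' \code{round(n * test_fraction)}, stratified by class label. The two index
#' sets are disjoint and jointly exhaustive, and each part contains both
#' classes.
#'
#' @param data a [knn_dataset()].
#' @param test_fraction fraction of observations assigned to the test part,
#'   strictly between 0 and 1. Default 0.1 (a 90/10 split).
#' @param seed optional integer seed for reproducible splits.
#' @return A list of class \code{"knn_split"} with elements \code{first}
#'   (training data), \code{second} (test data), \code{first_indices} and
#'   \code{second_indices}.
#' @export
train_test_split <- function(data, test_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(data, "knn_dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  split_pair(data, stratified_second_indices(data$y, test_fraction))
}

#' Split training data into construction and validation parts
#'
#' The ensemble builder uses the construction part to train and rank base
#' models and the validation part only for the greedy Brier-score growth of
#' the ensemble. Stratified by class, like [train_test_split()].
#'
#' @inheritParams train_test_split
#' @param validation_fraction fraction held out for validation, default 0.3.
#' @return A \code{"knn_split"}; \code{first} is the construction part,
#'   \code{second} the validation part.
#' @export
split_construction_validation <- function(data, validation_fraction = 0.3,
                                          seed = NULL) {
  stopifnot(inherits(data, "knn_dataset"))
  if (!is.numeric(validation_fraction) || validation_fraction <= 0 ||
      validation_fraction >= 1)
    stop("`validation_fraction` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  split_pair(data, stratified_second_indices(data$y, validation_fraction))
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of \code{nfolds} folds so that class
#' proportions are preserved as closely as possible within each fold.
#'
#' @param y 0/1 label vector.
#' @param nfolds number of folds, default 10.
#' @param seed optional integer seed.
#' @return Integer vector of fold ids in \code{1:nfolds}, one per
#'   observation.
#' @export
stratified_folds <- function(y, nfolds = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(y) < nfolds)
    stop("need at least `nfolds` observations")
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    members <- which(y == cl)
    fold[members] <- sample(rep_len(seq_len(nfolds), length(members)))
  }
  fold
}
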