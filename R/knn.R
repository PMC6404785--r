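#' Pairwise Euclidean distances
#'
#' Distance matrix between two point sets sharing a column count. Computed
#' in compiled code; used by every kNN routine in the package.
#'
#' @param a,b numeric matrices with the same number of columns.
#' @return A \code{nrow(a) x nrow(b)} matrix of Euclidean distances.
#' @examples
#' pairwise_distances(rbind(c(0, 0)), rbind(c(3, 4)))  # 5
#' @export
pairwise_distances <- function(a, b) {
  a <- as_query_matrix(a)
  b <- as_query_matrix(b)
  if (ncol(a) != ncol(b))
    stop("`a` and `b` must have the same number of columns")
  cpp_pairwise_dist(a, b)
}

#' kNN class-1 probability estimates
#'
#' For each query point, the fraction of class-1 labels among its \code{k}
#' nearest training points under Euclidean distance. Distance ties at the
#' k-th rank are resolved deterministically in favour of the lowest
#' training-row index, so results are reproducible.
#'
#' @param train a [knn_dataset()] of training points.
#' @param queries matrix of query points (or a \code{knn_dataset}).
#' @param k neighbour count, \code{1 <= k <=} number of training points.
#' @param scale if \code{TRUE}, z-score the training features and apply the
#'   same transform to the queries before computing distances. Off by
#'   default: distances are taken on the raw feature scale.
#' @return Numeric vector of class-1 probabilities, each an integer
#'   multiple of \code{1/k}.
#' @export
knn_class1_probability <- function(train, queries, k, scale = FALSE) {
  stopifnot(inherits(train, "knn_dataset"))
  q <- as_query_matrix(queries)
  if (ncol(q) != ncol(train$x))
    stop("query width does not match training feature count")
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("`k` must be a positive integer")
  if (k > nrow(train$x))
    stop("`k` exceeds the number of training points")
  tx <- train$x
  if (scale) {
    mu <- colMeans(tx)
    sd <- apply(tx, 2L, stats::sd)
    sd[sd == 0] <- 1
    tx <- sweep(sweep(tx, 2L, mu), 2L, sd, "/")
    q <- sweep(sweep(q, 2L, mu), 2L, sd, "/")
  }
  drop(cpp_knn_prob_multik(tx, train$y, q, k))
}

#' Threshold class probabilities into 0/1 labels
#'
#' A point is assigned class 1 iff its class-1 probability strictly exceeds
#' the threshold; a probability exactly at the threshold yields class 0.
#'
#' @param probs numeric vector of class-1 probabilities.
#' @param threshold cut-off in (0, 1), default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
classify_from_probability <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  as.integer(probs > threshold)
}

#' Choose k by stratified cross-validation
#'
#' Selects the neighbour count minimising the mean fold misclassification
#' rate over a stratified v-fold cross-validation; ties go to the smallest
#' k. One distance ranking per held-out point is shared across the whole k
#' grid, so the search costs little more than a single kNN evaluation.
#'
#' @param train a [knn_dataset()].
#' @param k_grid candidate neighbour counts, default \code{1:10}.
#' @param nfolds number of folds, default 10.
#' @param seed optional seed for the fold assignment.
#' @return The selected k (integer scalar).
#' @export
select_k_cv <- function(train, k_grid = 1:10, nfolds = 10L, seed = NULL) {
  stopifnot(inherits(train, "knn_dataset"))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0L) stop("`k_grid` is empty")
  if (any(k_grid < 1L)) stop("`k_grid` entries must be positive")
  n <- nrow(train$x)
  if (n < nfolds) stop("fewer observations than folds")
  fold <- stratified_folds(train$y, nfolds, seed)
  min_train <- n - max(tabulate(fold, nfolds))
  if (max(k_grid) > min_train)
    stop("max(k_grid) exceeds the smallest fold-training size")
  err <- matrix(NA_real_, nfolds, length(k_grid))
  for (v in seq_len(nfolds)) {
    hold <- fold == v
    probs <- cpp_knn_prob_multik(train$x[!hold, , drop = FALSE],
                                 train$y[!hold],
                                 train$x[hold, , drop = FALSE], k_grid)
    pred <- probs > 0.5
    err[v, ] <- colMeans(pred != (train$y[hold] == 1L))
  }
  k_grid[which.min(colMeans(err))]
}
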