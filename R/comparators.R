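#' Plain kNN prediction with cross-validated k
#'
#' Chooses k on the training data by [select_k_cv()], then classifies the
#' test points by thresholding the kNN class-1 probability at 0.5.
#'
#' @param train a [knn_dataset()].
#' @param test matrix of test points (or a \code{knn_dataset}).
#' @param k_grid candidate neighbour counts, default \code{1:10}.
#' @param seed optional seed (fold assignment).
#' @return Integer 0/1 labels with the selected k attached as attribute
#'   \code{"k"}.
#' @export
knn_predict <- function(train, test, k_grid = 1:10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- select_k_cv(train, k_grid)
  pred <- classify_from_probability(
    knn_class1_probability(train, as_query_matrix(test), k))
  attr(pred, "k") <- k
  pred
}

force_odd <- function(B) {
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be positive")
  if (B %% 2L == 0L) {
    warning(sprintf("`B` = %d is even; using %d to avoid voting ties", B, B + 1L))
    B <- B + 1L
  }
  B
}

resolve_k <- function(train, k, k_grid) {
  if (is.null(k)) select_k_cv(train, k_grid) else as.integer(k)
}

#' Bagged kNN prediction
#'
#' B kNN classifiers, each trained on a bootstrap sample of the training
#' data with the full feature set; each member votes the thresholded label
#' of its class-1 probability and the majority label wins (B is forced odd,
#' so votes cannot tie). Bootstrap samples are drawn one per member, in
#' member order, with \code{sample.int(n, n, replace = TRUE)}.
#'
#' @inheritParams knn_predict
#' @param B ensemble size, default 1001 (forced odd).
#' @param k neighbour count; \code{NULL} (default) selects it by
#'   [select_k_cv()] on the training data.
#' @return Integer 0/1 labels.
#' @export
bagged_knn_predict <- function(train, test, B = 1001L, k = NULL,
                               k_grid = 1:10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- force_odd(B)
  k <- resolve_k(train, k, k_grid)
  n <- nrow(train$x)
  W <- matrix(0L, B, n)
  for (b in seq_len(B))
    W[b, ] <- tabulate(sample.int(n, n, replace = TRUE), n)
  probs <- cpp_members_bagged(train$x, train$y, as_query_matrix(test), W, k)
  vote_labels(probs, colMeans(probs))
}

subset_member_labels <- function(train, test, B, subset_size, k, replace) {
  d <- ncol(train$x)
  l <- if (is.null(subset_size)) default_subset_size(d) else as.integer(subset_size)
  if (l > d) stop("`subset_size` exceeds the feature count")
  subsets <- lapply(seq_len(B), function(b)
    if (replace) sample.int(d, l, replace = TRUE) else sort(sample.int(d, l)))
  probs <- cpp_members_subset(train$x, train$y, as_query_matrix(test),
                              subsets, matrix(0L, 0L, 0L), k)
  vote_labels(probs, colMeans(probs))
}

#' Random-subspace kNN prediction (random kNN)
#'
#' B kNN classifiers, each seeing a random feature subset drawn without
#' replacement but all training observations; members vote their
#' thresholded labels and the majority wins. Feature subsets are drawn one
#' per member, in member order.
#'
#' @inheritParams bagged_knn_predict
#' @param subset_size features per member; \code{NULL} resolves to
#'   \code{max(2, floor(d / 3))}.
#' @return Integer 0/1 labels.
#' @export
random_knn_predict <- function(train, test, B = 1001L, subset_size = NULL,
                               k = NULL, k_grid = 1:10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- force_odd(B)
  k <- resolve_k(train, k, k_grid)
  subset_member_labels(train, test, B, subset_size, k, replace = FALSE)
}

#' Multiple-feature-subset kNN prediction (MFS)
#'
#' Like [random_knn_predict()], but each member's feature subset is drawn
#' with replacement, so a feature may enter a member's distance twice (and
#' is then weighted accordingly). This sampling scheme is what
#' distinguishes the multiple-feature-subset method from the
#' random-subspace one.
#'
#' @inheritParams random_knn_predict
#' @return Integer 0/1 labels.
#' @export
mfs_knn_predict <- function(train, test, B = 1001L, subset_size = NULL,
                            k = NULL, k_grid = 1:10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- force_odd(B)
  k <- resolve_k(train, k, k_grid)
  subset_member_labels(train, test, B, subset_size, k, replace = TRUE)
}

#' Random-forest / SVM reference predictions
#'
#' Thin adapters delegating to the \pkg{randomForest} and \pkg{kernlab}
#' packages (optional dependencies) so the established reference methods
#' can be benchmarked alongside the kNN family. SVM uses a Gaussian kernel
#' with kernlab's automatic sigma selection.
#'
#' @param method \code{"rf"} or \code{"svm"}.
#' @param train a [knn_dataset()].
#' @param test matrix of test points.
#' @param ... passed through to the backing implementation.
#' @return Integer 0/1 labels.
#' @export
external_comparator_predict <- function(method, train, test, ...) {
  test <- as_query_matrix(test)
  yf <- factor(train$y, levels = c(0L, 1L))
  if (method == "rf") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("optional dependency 'randomForest' is not installed; ",
           "install it to use method = \"rf\"")
    fit <- randomForest::randomForest(train$x, yf, ...)
    as.integer(as.character(predict(fit, test)))
  } else if (method == "svm") {
    if (!requireNamespace("kernlab", quietly = TRUE))
      stop("optional dependency 'kernlab' is not installed; ",
           "install it to use method = \"svm\"")
    fit <- kernlab::ksvm(train$x, yf, kernel = "rbfdot",
                         kpar = "automatic", ...)
    as.integer(as.character(kernlab::predict(fit, test)))
  } else {
    stop(sprintf("unknown external method '%s' (use \"rf\" or \"svm\")", method))
  }
}
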