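#' Ensemble configuration
#'
#' Collects the tuning parameters of the subset-kNN ensemble.
#'
#' @param m number of base models generated in stage one, default 1001. An
#'   odd count is required so that member votes cannot tie; an even value
#'   is bumped to the next odd number with a warning.
#' @param subset_size number of features drawn (without replacement) for
#'   each base model. \code{NULL} (default) resolves at fit time to
#'   \code{max(2, floor(d / 3))} — one third of the input features, but
#'   never fewer than two.
#' @param reselect_fraction fraction of the \code{m} models kept after
#'   ranking by out-of-bag accuracy, default 0.4 (so \code{h =
#'   max(1, floor(0.4 m))}).
#' @param validation_fraction fraction of the training data held out for
#'   the greedy Brier-score stage, default 0.3.
#' @param k_grid candidate neighbour counts for cross-validated selection
#'   of k, default \code{1:10}.
#' @param combine_rule how accepted members are combined at prediction
#'   time: \code{"mean_prob"} (average the members' class-1 probabilities,
#'   then threshold at 0.5 — the rule the greedy selection itself uses) or
#'   \code{"majority_vote"} (each member votes its thresholded label).
#' @param seed optional integer seed making the whole fit reproducible.
#' @return A list of class \code{"esknn_config"}.
#' @export
esknn_config <- function(m = 1001L, subset_size = NULL,
                         reselect_fraction = 0.4, validation_fraction = 0.3,
                         k_grid = 1:10,
                         combine_rule = c("mean_prob", "majority_vote"),
                         seed = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer")
  if (m %% 2L == 0L) {
    warning(sprintf("`m` = %d is even; using %d to avoid voting ties", m, m + 1L))
    m <- m + 1L
  }
  if (reselect_fraction <= 0 || reselect_fraction > 1)
    stop("`reselect_fraction` must be in (0, 1]")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("`validation_fraction` must be in (0, 1)")
  if (!is.null(subset_size)) {
    subset_size <- as.integer(subset_size)
    if (subset_size < 2L) stop("`subset_size` must be at least 2")
  }
  combine_rule <- match.arg(combine_rule)
  structure(list(m = m, subset_size = subset_size,
                 reselect_fraction = reselect_fraction,
                 validation_fraction = validation_fraction,
                 k_grid = as.integer(k_grid), combine_rule = combine_rule,
                 seed = seed),
            class = "esknn_config")
}

default_subset_size <- function(d) max(2L, as.integer(floor(d / 3)))

#' Draw a random feature subset
#'
#' \code{l} distinct feature indices drawn uniformly from \code{1:d}
#' without replacement. Subsets of size 1 are disallowed: a single feature
#' cannot express the joint structure the ensemble relies on, and the
#' smallest subset used anywhere in the package is 2.
#'
#' @param d total feature count.
#' @param l subset size, \code{2 <= l <= d}.
#' @return Sorted integer vector of \code{l} distinct indices.
#' @export
draw_feature_subset <- function(d, l) {
  d <- as.integer(d); l <- as.integer(l)
  if (l < 2L) stop("`l` must be at least 2")
  if (l > d) stop("`l` cannot exceed `d`")
  sort(sample.int(d, l))
}

#' Draw a bootstrap sample and its out-of-bag complement
#'
#' Samples \code{n} observation indices with replacement; the indices never
#' drawn form the out-of-bag (OOB) set, on average a fraction
#' \eqn{(1 - 1/n)^n \approx 0.368} of the data.
#'
#' @param n number of observations.
#' @return List with \code{inbag} (length-n integer multiset) and
#'   \code{oob} (sorted integer vector, possibly empty).
#' @export
draw_bootstrap <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be positive")
  inbag <- sample.int(n, n, replace = TRUE)
  list(inbag = inbag, oob = setdiff(seq_len(n), inbag))
}

#' Build the stage-one base models
#'
#' Generates \code{m} subset-kNN models on the construction data: each
#' draws a feature subset of size \code{l}, a bootstrap sample of size n,
#' and is scored by its accuracy on its own out-of-bag points, predicted
#' from the in-bag points restricted to the model's feature subset. A model
#' whose bootstrap happens to cover every observation has no OOB points; it
#' receives accuracy 0 and a warning is raised.
#'
#' @param construction a [knn_dataset()] containing both classes.
#' @param config an [esknn_config()].
#' @param k shared neighbour count (chosen once, typically by
#'   [select_k_cv()] on the construction data).
#' @return List of \code{m} base models; each is a list with
#'   \code{feature_indices}, \code{inbag}, \code{oob}, \code{k} and
#'   \code{oob_accuracy}.
#' @export
build_base_models <- function(construction, config, k) {
  stopifnot(inherits(construction, "knn_dataset"),
            inherits(config, "esknn_config"))
  if (length(unique(construction$y)) < 2L)
    stop("construction data must contain both classes")
  n <- nrow(construction$x)
  d <- ncol(construction$x)
  l <- if (is.null(config$subset_size)) default_subset_size(d) else config$subset_size
  if (l > d) stop("`subset_size` exceeds the feature count")
  m <- config$m
  subsets <- vector("list", m)
  W <- matrix(0L, m, n)
  oob_list <- vector("list", m)
  for (b in seq_len(m)) {
    subsets[[b]] <- draw_feature_subset(d, l)
    boot <- draw_bootstrap(n)
    W[b, ] <- tabulate(boot$inbag, n)
    oob_list[[b]] <- boot$oob
  }
  # one compiled pass scores every member on its own OOB rows only
  acc <- cpp_oob_accuracy(construction$x, construction$y, subsets, W,
                          as.integer(k), oob_list, 0.5)
  empty_oob <- sum(is.na(acc))
  acc[is.na(acc)] <- 0
  models <- vector("list", m)
  for (b in seq_len(m)) {
    models[[b]] <- list(feature_indices = subsets[[b]],
                        inbag = which(W[b, ] > 0L),
                        inbag_counts = W[b, ],
                        oob = oob_list[[b]], k = as.integer(k),
                        oob_accuracy = acc[b])
  }
  if (empty_oob > 0L)
    warning(sprintf("%d model(s) had an empty out-of-bag sample; accuracy set to 0",
                    empty_oob))
  models
}

#' Rank base models and keep the best fraction
#'
#' Sorts models by decreasing out-of-bag accuracy (ties keep the original
#' generation order) and returns the first \code{h = max(1,
#' floor(reselect_fraction * m))}.
#'
#' @param models list of base models from [build_base_models()].
#' @param reselect_fraction fraction retained, default 0.4.
#' @return The top-h models, best first.
#' @export
rank_and_select <- function(models, reselect_fraction = 0.4) {
  if (length(models) == 0L) stop("no models to rank")
  acc <- vapply(models, `[[`, numeric(1L), "oob_accuracy")
  h <- max(1L, as.integer(floor(reselect_fraction * length(models))))
  models[order(-acc, seq_along(acc))[seq_len(h)]]
}

#' Greedy Brier-score member selection on a probability matrix
#'
#' Core of the stage-two selection, operating directly on the matrix of
#' member class-1 probabilities for the validation points (rows in rank
#' order, best model first). The best model is always accepted. Candidates
#' are then scanned in rank order through the whole list: candidate r joins
#' iff the validation Brier score of the averaged-probability ensemble
#' including it is strictly lower than that of the currently accepted
#' ensemble. Rejected candidates are discarded and scanning continues; a
#' Brier tie counts as a rejection, keeping the ensemble minimal.
#'
#' @param member_probs h x n_valid matrix of class-1 probabilities, rows
#'   ordered best model first.
#' @param y_valid 0/1 validation labels.
#' @return List with \code{accepted} (row indices of accepted members, in
#'   acceptance order, always starting with 1) and \code{brier_trace} (the
#'   strictly decreasing validation Brier scores of the accepted ensemble
#'   states, starting with the best single model's score).
#' @export
greedy_select_probs <- function(member_probs, y_valid) {
  member_probs <- rbind(member_probs)
  if (ncol(member_probs) != length(y_valid))
    stop("probability columns must match validation labels")
  if (nrow(member_probs) < 1L) stop("need at least one member")
  accepted <- 1L
  prob_sum <- member_probs[1L, ]
  bs <- brier_score(y_valid, prob_sum)
  trace <- bs
  h <- nrow(member_probs)
  if (h >= 2L) {
    for (r in 2L:h) {
      cand_sum <- prob_sum + member_probs[r, ]
      cand_bs <- brier_score(y_valid, cand_sum / (length(accepted) + 1L))
      if (cand_bs < bs) {
        accepted <- c(accepted, r)
        prob_sum <- cand_sum
        bs <- cand_bs
        trace <- c(trace, bs)
      }
    }
  }
  list(accepted = accepted, brier_trace = trace)
}

new_esknn <- function(members, construction, brier_trace, k, config,
                      subset_size) {
  structure(list(members = members, construction = construction,
                 brier_trace = brier_trace, k = k, config = config,
                 subset_size = subset_size),
            class = "esknn")
}

member_prob_matrix <- function(members, construction, queries) {
  subsets <- lapply(members, `[[`, "feature_indices")
  W <- do.call(rbind, lapply(members, `[[`, "inbag_counts"))
  storage.mode(W) <- "integer"
  cpp_members_subset(construction$x, construction$y, queries, subsets, W,
                     members[[1L]]$k)
}

#' Grow the ensemble by greedy Brier-score selection
#'
#' Evaluates the ranked models' class-1 probabilities on the validation
#' set and applies [greedy_select_probs()]. See there for the acceptance
#' rule.
#'
#' @param ranked list of base models, best first (from
#'   [rank_and_select()]).
#' @param construction the construction [knn_dataset()] the models were
#'   built on.
#' @param validation the validation [knn_dataset()].
#' @param config an [esknn_config()] (stored with the result).
#' @return An object of class \code{"esknn"}.
#' @export
greedy_brier_selection <- function(ranked, construction, validation,
                                   config = esknn_config()) {
  if (length(ranked) == 0L) stop("`ranked` is empty")
  if (nrow(validation$x) == 0L) stop("validation set is empty")
  if (length(unique(validation$y)) < 2L)
    message("validation set contains a single class")
  probs <- member_prob_matrix(ranked, construction, validation$x)
  sel <- greedy_select_probs(probs, validation$y)
  new_esknn(ranked[sel$accepted], construction, sel$brier_trace,
            ranked[[1L]]$k, config,
            length(ranked[[1L]]$feature_indices))
}

#' Fit an ensemble of subset kNN classifiers
#'
#' Full two-stage fit: the training data is split (stratified) into a
#' construction part and a validation part; k is chosen once on the
#' construction part by stratified 10-fold cross-validation and shared by
#' all members; \code{m} subset-kNN base models are built and ranked by
#' out-of-bag accuracy; the top fraction enters the greedy Brier-score
#' selection on the validation part.
#'
#' @param train a [knn_dataset()] with both classes present.
#' @param config an [esknn_config()].
#' @return An \code{"esknn"} object with elements \code{members} (accepted
#'   base models, best-ranked first), \code{brier_trace} (strictly
#'   decreasing validation Brier scores), \code{k}, \code{construction} and
#'   \code{config}. Use [predict.esknn()] on new data.
#' @examples
#' d <- simulate_model2(model2_spec(n = 200, seed = 1))
#' fit <- fit_esknn(d, esknn_config(m = 25, seed = 2))
#' fit
#' @export
fit_esknn <- function(train, config = esknn_config()) {
  stopifnot(inherits(train, "knn_dataset"),
            inherits(config, "esknn_config"))
  if (length(unique(train$y)) < 2L) stop("training data must contain both classes")
  if (!is.null(config$seed)) set.seed(config$seed)
  sp <- split_construction_validation(train, config$validation_fraction)
  k <- select_k_cv(sp$first, config$k_grid)
  models <- build_base_models(sp$first, config, k)
  ranked <- rank_and_select(models, config$reselect_fraction)
  greedy_brier_selection(ranked, sp$first, sp$second, config)
}

#' @export
print.esknn <- function(x, ...) {
  cat(sprintf("Ensemble of subset kNN classifiers\n  members: %d (of m = %d generated), k = %d, subset size = %d\n  validation Brier trace: %s\n",
              length(x$members), x$config$m, x$k, x$subset_size,
              paste(formatC(x$brier_trace, digits = 4, format = "f"),
                    collapse = " -> ")))
  invisible(x)
}

#' Ensemble class-1 probabilities
#'
#' Unweighted mean over the accepted members of each member's kNN class-1
#' probability, every member using its own bootstrap sample and feature
#' subset of the construction data.
#'
#' @param ensemble an \code{"esknn"} object.
#' @param queries matrix of query points (construction feature width).
#' @return Numeric vector of averaged class-1 probabilities.
#' @export
ensemble_predict_proba <- function(ensemble, queries) {
  stopifnot(inherits(ensemble, "esknn"))
  q <- as_query_matrix(queries)
  if (ncol(q) != ncol(ensemble$construction$x))
    stop("query width does not match the training feature count")
  colMeans(member_prob_matrix(ensemble$members, ensemble$construction, q))
}

vote_labels <- function(member_probs, mean_probs) {
  votes <- colMeans(member_probs > 0.5)
  out <- as.integer(votes > 0.5)
  tie <- votes == 0.5
  if (any(tie)) out[tie] <- classify_from_probability(mean_probs[tie])
  out
}

#' Ensemble label predictions
#'
#' \code{"mean_prob"} thresholds the averaged member probability at 0.5
#' (strictly); \code{"majority_vote"} lets each member vote its own
#' thresholded label, with an exact vote tie falling back to the
#' mean-probability rule.
#'
#' @inheritParams ensemble_predict_proba
#' @param rule combining rule, see [esknn_config()].
#' @return Integer vector of 0/1 labels.
#' @export
ensemble_predict <- function(ensemble, queries,
                             rule = c("mean_prob", "majority_vote")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ensemble, "esknn"))
  q <- as_query_matrix(queries)
  if (ncol(q) != ncol(ensemble$construction$x))
    stop("query width does not match the training feature count")
  probs <- member_prob_matrix(ensemble$members, ensemble$construction, q)
  mean_probs <- colMeans(probs)
  if (rule == "mean_prob") classify_from_probability(mean_probs)
  else vote_labels(probs, mean_probs)
}

#' Predict method for esknn ensembles
#'
#' @param object an \code{"esknn"} object.
#' @param newdata matrix or [knn_dataset()] of query points.
#' @param type \code{"class"} for 0/1 labels, \code{"prob"} for averaged
#'   class-1 probabilities.
#' @param rule combining rule for \code{type = "class"}; defaults to the
#'   rule stored in the fit's configuration.
#' @param ... unused.
#' @export
predict.esknn <- function(object, newdata, type = c("class", "prob"),
                          rule = object$config$combine_rule, ...) {
  type <- match.arg(type)
  if (type == "prob") ensemble_predict_proba(object, newdata)
  else ensemble_predict(object, newdata, rule)
}

#' Serialize a fitted ensemble to JSON
#'
#' Writes the configuration, shared k, member feature subsets and bootstrap
#' samples, the Brier trace and the construction data to a plain-text JSON
#' file, so that predictions can be made in a later R process via
#' [read_esknn()].
#'
#' @param ensemble an \code{"esknn"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_esknn <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "esknn"))
  payload <- list(
    format = "esknn-1",
    config = unclass(ensemble$config),
    k = ensemble$k,
    subset_size = ensemble$subset_size,
    brier_trace = ensemble$brier_trace,
    members = lapply(ensemble$members, function(m)
      list(feature_indices = m$feature_indices,
           inbag_counts = m$inbag_counts,
           oob = m$oob, oob_accuracy = m$oob_accuracy)),
    construction = list(x = ensemble$construction$x,
                        y = ensemble$construction$y,
                        feature_names = ensemble$construction$feature_names)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a serialized ensemble
#'
#' @param path JSON file written by [write_esknn()].
#' @return An \code{"esknn"} object equivalent to the one written.
#' @export
read_esknn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "esknn-1")
    stop("not an esknn model file")
  cfg <- p$config
  config <- esknn_config(m = cfg$m, subset_size = cfg$subset_size,
                         reselect_fraction = cfg$reselect_fraction,
                         validation_fraction = cfg$validation_fraction,
                         k_grid = cfg$k_grid, combine_rule = cfg$combine_rule,
                         seed = cfg$seed)
  construction <- knn_dataset(p$construction$x, p$construction$y,
                              p$construction$feature_names)
  members <- if (is.data.frame(p$members)) {
    lapply(seq_len(nrow(p$members)), function(i) as.list(p$members[i, ]))
  } else p$members
  members <- lapply(members, function(m) {
    counts <- as.integer(unlist(m$inbag_counts))
    list(feature_indices = as.integer(unlist(m$feature_indices)),
         inbag = which(counts > 0L), inbag_counts = counts,
         oob = as.integer(unlist(m$oob)), k = as.integer(p$k),
         oob_accuracy = as.numeric(m$oob_accuracy))
  })
  new_esknn(members, construction, as.numeric(p$brier_trace),
            as.integer(p$k), config, as.integer(p$subset_size))
}
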