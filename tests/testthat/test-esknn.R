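fake_models <- function(accs) {
  lapply(seq_along(accs), function(i)
    list(feature_indices = c(1L, 2L), inbag = 1L, inbag_counts = 1L,
         oob = integer(0), k = 1L, oob_accuracy = accs[i], id = i))
}

test_that("configuration is validated and even m is bumped to odd", {
  cfg <- esknn_config()
  expect_equal(cfg$m, 1001L)
  expect_equal(cfg$reselect_fraction, 0.4)
  expect_warning(cfg2 <- esknn_config(m = 10), "even")
  expect_equal(cfg2$m, 11L)
  expect_error(esknn_config(reselect_fraction = 0), "reselect_fraction")
  expect_error(esknn_config(subset_size = 1), "at least 2")
})

test_that("feature subsets are distinct, bounded and uniform over pairs", {
  expect_identical(draw_feature_subset(4, 4), 1:4)
  expect_error(draw_feature_subset(5, 1), "at least 2")
  expect_error(draw_feature_subset(3, 4), "exceed")

  set.seed(21)
  draws <- vapply(seq_len(1e5), function(i)
    paste(draw_feature_subset(5, 2), collapse = "-"), character(1))
  freq <- table(draws) / 1e5
  expect_length(freq, 10)
  sigma <- sqrt(0.1 * 0.9 / 1e5)
  expect_true(all(abs(freq - 0.1) < 4 * sigma))
})

test_that("bootstraps partition into in-bag and out-of-bag", {
  set.seed(22)
  expect_identical(draw_bootstrap(1), list(inbag = 1L, oob = integer(0)))
  for (i in 1:20) {
    b <- draw_bootstrap(50)
    expect_length(b$inbag, 50)
    expect_setequal(c(b$oob, unique(b$inbag)), 1:50)
    expect_length(intersect(b$oob, b$inbag), 0)
  }
})

test_that("base models satisfy their invariants and OOB accuracy is recomputable", {
  set.seed(23)
  data <- make_random_dataset(40, 6)
  cfg <- esknn_config(m = 3, subset_size = 2)
  models <- build_base_models(data, cfg, k = 3)
  expect_length(models, 3)
  for (mo in models) {
    expect_length(unique(mo$feature_indices), 2)
    expect_length(intersect(mo$oob, mo$inbag), 0)
    expect_equal(sum(mo$inbag_counts), 40)
    # recompute the accuracy from the stored indices with the brute-force
    # weighted oracle
    p <- oracle_knn_prob_weighted(data$x[, mo$feature_indices, drop = FALSE],
                                  data$y, mo$inbag_counts,
                                  data$x[mo$oob, mo$feature_indices, drop = FALSE],
                                  mo$k)
    expect_equal(mo$oob_accuracy,
                 1 - misclassification_rate(data$y[mo$oob], as.integer(p > 0.5)),
                 tolerance = 1e-12)
  }
})

test_that("models whose bootstrap covers everything get accuracy 0 and a warning", {
  # with n = 2 roughly half of all bootstraps contain both rows, so some of
  # 15 models are certain (under this seed) to have an empty OOB set
  set.seed(24)
  data <- knn_dataset(rbind(c(0, 0), c(1, 1)), c(0L, 1L))
  expect_warning(models <- build_base_models(data, esknn_config(m = 15), 1),
                 "empty out-of-bag")
  empties <- Filter(function(mo) length(mo$oob) == 0, models)
  expect_gt(length(empties), 0)
  expect_true(all(vapply(empties, `[[`, numeric(1), "oob_accuracy") == 0))
})

test_that("ranking keeps the top fraction, stably", {
  sel <- rank_and_select(fake_models(c(0.6, 0.9, 0.7)), 0.4)
  expect_length(sel, 1)
  expect_equal(sel[[1]]$id, 2)

  sel <- rank_and_select(fake_models(rep(0.5, 10)), 0.4)
  expect_equal(vapply(sel, `[[`, integer(1), "id"), 1:4)

  sel <- rank_and_select(fake_models(runif(1001)), 0.4)
  expect_length(sel, 400)
  expect_error(rank_and_select(list(), 0.4), "no models")
})

test_that("greedy selection accepts only strict Brier improvements", {
  # three candidates in rank order on a single class-1 validation point
  sel <- greedy_select_probs(rbind(0.56, 0.68, 0.88), 1)
  expect_identical(sel$accepted, 1:3)
  expect_equal(sel$brier_trace,
               c(0.1936, 0.1444, (1 - mean(c(0.56, 0.68, 0.88)))^2),
               tolerance = 1e-12)

  # a poor third candidate drags the mean down and is rejected
  sel <- greedy_select_probs(rbind(0.56, 0.68, 0.10), 1)
  expect_identical(sel$accepted, 1:2)
  expect_length(sel$brier_trace, 2)

  # a single candidate is the whole ensemble
  sel <- greedy_select_probs(rbind(c(0.7, 0.3)), c(1, 0))
  expect_identical(sel$accepted, 1L)

  # an exact Brier tie is a rejection
  sel <- greedy_select_probs(rbind(0.6, 0.6), 1)
  expect_identical(sel$accepted, 1L)

  # scanning continues past rejections: candidate 2 hurts, candidate 3 helps
  sel <- greedy_select_probs(rbind(0.6, 0.2, 0.9), 1)
  expect_identical(sel$accepted, c(1L, 3L))
})

test_that("ensemble probabilities are the unweighted member mean", {
  set.seed(25)
  data <- make_random_dataset(60, 5)
  fit <- fit_esknn(data, esknn_config(m = 21, seed = 5))
  q <- matrix(rnorm(4 * 5), 4, 5)
  by_hand <- rowMeans(vapply(fit$members, function(mo)
    oracle_knn_prob_weighted(fit$construction$x[, mo$feature_indices, drop = FALSE],
                             fit$construction$y, mo$inbag_counts,
                             q[, mo$feature_indices, drop = FALSE], mo$k),
    numeric(4)))
  expect_equal(ensemble_predict_proba(fit, q), by_hand, tolerance = 1e-12)

  single <- fit
  single$members <- fit$members[1]
  mo <- fit$members[[1]]
  expect_equal(ensemble_predict_proba(single, q),
               oracle_knn_prob_weighted(
                 fit$construction$x[, mo$feature_indices, drop = FALSE],
                 fit$construction$y, mo$inbag_counts,
                 q[, mo$feature_indices, drop = FALSE], mo$k),
               tolerance = 1e-12)
  expect_error(ensemble_predict_proba(fit, matrix(0, 1, 2)), "width")
})

test_that("vote ties fall back to the mean-probability rule", {
  # two members voting 1 and 0 with mean probability 0.45 -> class 0
  expect_identical(esknn:::vote_labels(rbind(0.6, 0.3), 0.45), 0L)
  expect_identical(esknn:::vote_labels(rbind(0.6, 0.3), 0.55), 1L)
  expect_identical(esknn:::vote_labels(rbind(0.2, 0.3, 0.4), 0.3), 0L)
})

test_that("the full fit is deterministic, bounded by h, and separates separable data", {
  set.seed(26)
  train <- make_separable(40, 6)
  test <- make_separable(15, 6)

  fit1 <- fit_esknn(train, esknn_config(m = 51, seed = 9))
  fit2 <- fit_esknn(train, esknn_config(m = 51, seed = 9))
  expect_identical(lapply(fit1$members, `[[`, "feature_indices"),
                   lapply(fit2$members, `[[`, "feature_indices"))
  expect_identical(fit1$brier_trace, fit2$brier_trace)

  expect_lte(length(fit1$members), max(1, floor(0.4 * 51)))
  expect_true(all(diff(fit1$brier_trace) < 0))
  # the top-ranked model opens the ensemble
  expect_equal(fit1$members[[1]]$oob_accuracy,
               max(vapply(fit1$members, `[[`, numeric(1), "oob_accuracy")))
  expect_equal(misclassification_rate(test$y, predict(fit1, test$x)), 0)

  fit3 <- fit_esknn(train, esknn_config(m = 5, seed = 10))
  expect_lte(length(fit3$members), 2)
})

test_that("serialized ensembles reload and predict identically", {
  set.seed(27)
  data <- make_random_dataset(50, 4)
  fit <- fit_esknn(data, esknn_config(m = 11, seed = 3))
  path <- tempfile(fileext = ".json")
  write_esknn(fit, path)
  back <- read_esknn(path)
  q <- matrix(rnorm(20), 5, 4)
  expect_equal(ensemble_predict_proba(back, q),
               ensemble_predict_proba(fit, q), tolerance = 1e-12)
  expect_identical(ensemble_predict(back, q), ensemble_predict(fit, q))
  expect_equal(back$brier_trace, fit$brier_trace, tolerance = 1e-12)
  expect_equal(back$k, fit$k)
  unlink(path)
})
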