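#' AR(1)-style correlation matrix for simulation model 1
#'
#' The d x d matrix with entries \eqn{(1/2)^{|i-j|}}: unit diagonal and
#' geometrically decaying off-diagonal correlation, so adjacent features
#' correlate at 0.5, features two apart at 0.25, and so on.
#'
#' @param d dimension.
#' @return A symmetric positive-definite d x d matrix.
#' @export
make_psi <- function(d) {
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be positive")
  idx <- seq_len(d)
  0.5^abs(outer(idx, idx, "-"))
}

#' Specification of simulation model 1
#'
#' Two Gaussian classes in d informative dimensions. Class 1 (label 1) is
#' drawn from a multivariate normal with mean 2 in every coordinate and
#' covariance \code{w * make_psi(d)} — correlated features whose variance
#' scales with \code{w}. Class 2 (label 0) has independent N(1, 1)
#' features. Optional non-informative standard-normal features are appended
#' to both classes.
#'
#' @param n1,n2 per-class sample counts; default 500 each (a total of 1000
#'   observations, the same scale as model 2).
#' @param d informative feature count, default 20.
#' @param w variance multiplier for class 1, default 1.
#' @param n_noise number of appended non-informative features, default 0.
#' @param seed optional integer seed.
#' @return A list of class \code{"model1_spec"}.
#' @export
model1_spec <- function(n1 = 500L, n2 = 500L, d = 20L, w = 1, n_noise = 0L,
                        seed = NULL) {
  if (w <= 0) stop("`w` must be positive")
  if (d < 1L || n1 < 1L || n2 < 1L) stop("`d`, `n1`, `n2` must be positive")
  if (n_noise < 0L) stop("`n_noise` cannot be negative")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), d = as.integer(d),
                 w = w, n_noise = as.integer(n_noise), seed = seed),
            class = "model1_spec")
}

#' Specification of simulation model 2
#'
#' Four features uniform on \code{[0, 100]}; the class-1 probability is a
#' deterministic band function of the Euclidean distance r of a point from
#' a central point: 1 for r < 110, \code{(150 - r) / 140} for 110 <= r <=
#' 140, and 0 beyond. Labels are Bernoulli draws from that probability.
#' Optional non-informative uniform(0, 100) features are appended.
#'
#' The default central point is the origin: distances from the origin have
#' a root-mean-square of about 115, so the three probability branches are
#' all populated and the classes come out roughly balanced. (From the
#' hypercube centre every point would be closer than 110, collapsing all
#' labels to 1.)
#'
#' @param n observation count, default 1000.
#' @param central_point numeric length-4 vector, default \code{c(0,0,0,0)}.
#' @param n_noise number of appended non-informative features, default 0.
#' @param seed optional integer seed.
#' @return A list of class \code{"model2_spec"}.
#' @export
model2_spec <- function(n = 1000L, central_point = c(0, 0, 0, 0),
                        n_noise = 0L, seed = NULL) {
  if (n < 1L) stop("`n` must be positive")
  if (length(central_point) != 4L) stop("`central_point` must have length 4")
  if (n_noise < 0L) stop("`n_noise` cannot be negative")
  structure(list(n = as.integer(n), central_point = as.numeric(central_point),
                 n_noise = as.integer(n_noise), seed = seed),
            class = "model2_spec")
}

#' Generate a dataset from simulation model 1
#'
#' @param spec a [model1_spec()].
#' @return A [knn_dataset()] with \code{n1 + n2} rows (class 1 first) and
#'   \code{d + n_noise} columns. Informative features are named
#'   \code{V1..Vd}, appended ones \code{noise1..}.
#' @export
simulate_model1 <- function(spec = model1_spec()) {
  stopifnot(inherits(spec, "model1_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$d
  # class 1: MVN(mean 2, w * Psi) via the Cholesky factor
  R <- chol(spec$w * make_psi(d))
  x1 <- matrix(rnorm(spec$n1 * d), spec$n1, d) %*% R + 2
  # class 2: independent N(1, 1)
  x2 <- matrix(rnorm(spec$n2 * d, mean = 1, sd = 1), spec$n2, d)
  x <- rbind(x1, x2)
  colnames(x) <- paste0("V", seq_len(d))
  y <- rep(c(1L, 0L), c(spec$n1, spec$n2))
  data <- knn_dataset(x, y)
  if (spec$n_noise > 0L)
    data <- add_noise_features(data, spec$n_noise, "standard_normal")
  data
}

#' Class-1 probability of simulation model 2
#'
#' The band function of the distance r from the central point: 1 below
#' 110, linearly decreasing \code{(150 - r)/140} on \code{[110, 140]},
#' 0 above 140.
#'
#' @param r nonnegative distances.
#' @return Probabilities in \code{[0, 1]}.
#' @export
model2_class_probability <- function(r) {
  ifelse(r < 110, 1, ifelse(r <= 140, (150 - r) / 140, 0))
}

#' Generate a dataset from simulation model 2
#'
#' @param spec a [model2_spec()].
#' @return A [knn_dataset()] with n rows and \code{4 + n_noise} columns.
#' @export
simulate_model2 <- function(spec = model2_spec()) {
  stopifnot(inherits(spec, "model2_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  x <- matrix(runif(spec$n * 4L, 0, 100), spec$n, 4L)
  colnames(x) <- paste0("V", 1:4)
  r <- sqrt(colSums((t(x) - spec$central_point)^2))
  y <- rbinom(spec$n, 1L, model2_class_probability(r))
  data <- knn_dataset(x, y)
  if (spec$n_noise > 0L)
    data <- add_noise_features(data, spec$n_noise, "uniform_0_100")
  data
}

#' Append non-informative features
#'
#' Adds \code{count} columns drawn independently of the class label, either
#' standard normal (the convention for the Gaussian model) or uniform on
#' \code{[0, 100]} (the convention for the distance-band model). Labels are
#' untouched.
#'
#' @param data a [knn_dataset()].
#' @param count number of columns to append.
#' @param family \code{"standard_normal"} or \code{"uniform_0_100"}.
#' @param seed optional integer seed.
#' @return A [knn_dataset()] with \code{count} extra columns named
#'   \code{noise1..}.
#' @export
add_noise_features <- function(data, count,
                               family = c("standard_normal", "uniform_0_100"),
                               seed = NULL) {
  stopifnot(inherits(data, "knn_dataset"))
  count <- as.integer(count)
  if (count < 0L) stop("`count` cannot be negative")
  if (count == 0L) return(data)
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$x)
  noise <- switch(family,
                  standard_normal = matrix(rnorm(n * count), n, count),
                  uniform_0_100 = matrix(runif(n * count, 0, 100), n, count))
  colnames(noise) <- paste0("noise", seq_len(count))
  knn_dataset(cbind(data$x, noise), data$y)
}

#' Write a dataset as CSV
#'
#' Writes features plus a \code{label} column in the dialect
#' [read_dataset()] consumes.
#'
#' @param data a [knn_dataset()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "knn_dataset"))
  df <- as.data.frame(data$x)
  df$label <- data$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
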