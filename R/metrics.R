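#' Misclassification rate
#'
#' Fraction of positions where predicted and true labels differ.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return A number in \code{[0, 1]}.
#' @export
misclassification_rate <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  if (length(y_true) < 1L) stop("need at least one observation")
  mean(y_true != y_pred)
}

#' Brier score for binary outcomes
#'
#' Mean squared difference between the observed 0/1 outcomes and the
#' predicted class-1 probabilities,
#' \deqn{\widehat{BS} = \frac{1}{n_t}\sum_{i=1}^{n_t} (y_i - \hat p_i)^2,}
#' the two-class form. Lower is better; a perfectly calibrated and sharp
#' predictor scores 0, the constant 0.5 predictor scores 0.25.
#'
#' @param y_true 0/1 outcome vector.
#' @param probs predicted class-1 probabilities in \code{[0, 1]}.
#' @return A number in \code{[0, 1]}.
#' @examples
#' brier_score(1, 0.56)  # 0.1936
#' @export
brier_score <- function(y_true, probs) {
  if (length(y_true) != length(probs))
    stop("`y_true` and `probs` must have equal length")
  if (length(y_true) < 1L) stop("need at least one observation")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(y_true %in% c(0, 1))) stop("outcomes must be 0 or 1")
  mean((y_true - probs)^2)
}

#' Evaluate predictions with both scores
#'
#' @param y_true 0/1 outcomes.
#' @param probs class-1 probabilities.
#' @param threshold classification cut-off, default 0.5 (strict).
#' @return List with \code{misclassification_rate}, \code{brier_score} and
#'   \code{n_points}.
#' @export
evaluate_predictions <- function(y_true, probs, threshold = 0.5) {
  list(misclassification_rate =
         misclassification_rate(y_true, classify_from_probability(probs, threshold)),
       brier_score = brier_score(y_true, probs),
       n_points = length(y_true))
}
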