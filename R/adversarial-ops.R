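#' Gradient reversal layer: forward pass
#'
#' The gradient reversal layer is the identity during forward propagation;
#' its effect exists only in the backward pass, where the gradient of any
#' downstream loss is multiplied by `-lambda` before flowing into the
#' feature extractor (see [grlBackward()]). This turns minimization of the
#' domain-discriminator loss into maximization at the feature level, pushing
#' the extractor toward domain-indistinguishable representations.
#'
#' @param x numeric vector or matrix of features.
#' @param lambda reversal strength, `>= 0` (unused in the forward pass).
#' @return `x`, unchanged.
#' @seealso [grlBackward()], [lambdaSchedule()]
#' @export
grlForward <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  x
}

#' Gradient reversal layer: backward pass
#'
#' Implements the reversed-gradient contract: the gradient with respect to
#' the layer input equals `-lambda` times the gradient with respect to its
#' output.
#'
#' @param grad gradient of a downstream scalar loss w.r.t. the layer output.
#' @param lambda reversal strength, `>= 0`.
#' @return `-lambda * grad`.
#' @export
grlBackward <- function(grad, lambda = 1) {
  stopifnot(lambda >= 0)
  -lambda * grad
}

#' Gradient-reversal strength schedule
#'
#' `lambda = 2 / (1 + exp(-gamma * p)) - 1`, where `p` is the ratio of the
#' current iteration to the total planned iterations. Starts at exactly 0
#' (the adversary is ignored while features are still random) and rises
#' towards 1.
#'
#' @param p training progress in `[0, 1]`.
#' @param gamma steepness constant (default 10).
#' @return `lambda` in `[0, 1)`, strictly increasing in `p`.
#' @export
lambdaSchedule <- function(p, gamma = 10) {
  if (any(p < 0 | p > 1)) stopf("training progress p must be in [0, 1]")
  stopifnot(gamma > 0)
  2 / (1 + exp(-gamma * p)) - 1
}

#' Domain-discriminator loss (mean binary cross-entropy)
#'
#' Mean binary cross-entropy between true domain labels and predicted
#' probabilities, with probabilities clamped to `[1e-7, 1 - 1e-7]`. The
#' discriminator minimizes this; the gradient reversal layer converts that
#' into feature-level maximization. At the adversarial optimum (chance-level
#' predictions on a balanced batch) the loss is `log(2)`.
#'
#' @param yTrue domain labels in `{0, 1}`.
#' @param yProb predicted probability of domain 1, in `(0, 1)`.
#' @return scalar mean BCE.
#' @export
domainLoss <- function(yTrue, yProb) {
  if (length(yTrue) != length(yProb)) {
    stopf("domain labels (%d) and probabilities (%d) differ in length",
          length(yTrue), length(yProb))
  }
  stopifnot(all(yTrue %in% c(0, 1)))
  p <- clampProb(yProb)
  -mean(yTrue * log(p) + (1 - yTrue) * log(1 - p))
}
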