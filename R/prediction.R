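# Probability predictions from degrees of confirmation ----------------------

star_value <- function(x) {
  if (is.data.frame(x)) x$value else x
}

prediction_result <- function(p_h1) {
  structure(list(p_h1 = p_h1, p_h0 = 1 - p_h1), class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat("P(h1|theta) = ", format(x$p_h1), ", P(h0|theta) = ",
      format(x$p_h0), "\n", sep = "")
  invisible(x)
}

#' Predict P(h1) from a prior and a channel confirmation degree
#'
#' Transports a degree of confirmation `b*` for the rule `e1 -> h1` to a
#' (possibly new) prior prevalence:
#' for `b* >= 0`, `P(h1|theta) = prior / (1 - b* (1 - prior))`; for
#' `b* < 0`, Consequent Symmetry gives the believable part to `h0` and
#' `P(h0|theta) = (1 - prior) / (1 - |b*| prior)`, the returned `p_h1` being
#' its complement. With `b* = 0` the prior is returned unchanged; with
#' `b* = 1` the prediction is exactly 1.
#'
#' @param prior prior probability P(h1), in (0, 1).
#' @param bstar a channel confirmation degree in \[-1, 1\] (a number or a
#'   [b_star()] result row).
#' @return a `prediction` object with `p_h1` and `p_h0`.
#' @examples
#' predict_from_b(0.25, 0.9)$p_h1   # 0.7692...
#' @export
predict_from_b <- function(prior, bstar) {
  bstar <- star_value(bstar)
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop("prior must be strictly between 0 and 1")
  if (is.na(bstar) || abs(bstar) > 1) stop("bstar must lie in [-1, 1]")
  if (bstar >= 0) {
    p1 <- prior / (1 - bstar * (1 - prior))
  } else {
    b10 <- abs(bstar)
    p0 <- (1 - prior) / (1 - b10 * prior)
    p1 <- 1 - p0
  }
  prediction_result(p1)
}

#' Correct rate from a prediction confirmation degree
#'
#' Inverts `c* = (2 CR - 1)/max(CR, 1 - CR)`: for `c* >= 0` the correct
#' rate of `e1 -> h1` is `CR = 1/(2 - c*)`; for `c* < 0` the believable part
#' supports `h0`, `P(h0|theta) = 1/(2 - |c*|)` and
#' `p_h1 = (1 - |c*|)/(2 - |c*|)`.
#'
#' @param cstar a prediction confirmation degree in \[-1, 1\].
#' @return a `prediction` object; for `c* >= 0`, `p_h1` is the correct rate.
#' @examples
#' predict_from_c(0.701)$p_h1   # 0.7698...
#' @export
predict_from_c <- function(cstar) {
  cstar <- star_value(cstar)
  if (is.na(cstar) || abs(cstar) > 1) stop("cstar must lie in [-1, 1]")
  if (cstar >= 0) {
    p1 <- 1 / (2 - cstar)
  } else {
    c10 <- abs(cstar)
    p1 <- (1 - c10) / (2 - c10)
  }
  prediction_result(p1)
}

#' Correct rate from a cF* degree
#'
#' `P(h1|theta) = CR = (1 + cF*)/2`.
#'
#' @param cf a cF* degree in \[-1, 1\].
#' @return a `prediction` object.
#' @export
predict_from_cf <- function(cf) {
  cf <- star_value(cf)
  if (is.na(cf) || abs(cf) > 1) stop("cf must lie in [-1, 1]")
  prediction_result((1 + cf) / 2)
}

#' Semantic Bayes prediction
#'
#' Updates a prior distribution with a truth function instead of a
#' likelihood: `posterior_i = prior_i * truth_i / sum_k prior_k * truth_k`,
#' the denominator being the logical probability of the label. For the
#' two-point mixture truth function (1 on h1, b' on h0) this reproduces
#' [predict_from_b()] exactly.
#'
#' @param prior a probability vector over a finite outcome set (sums to 1).
#' @param truth truth values in \[0, 1\] per outcome (a numeric vector or a
#'   [truth_function()] evaluated by the caller).
#' @return a normalized posterior vector (named like `prior`).
#' @examples
#' semantic_bayes(c(h0 = 0.75, h1 = 0.25), c(h0 = 0.1, h1 = 1))
#' @export
semantic_bayes <- function(prior, truth) {
  if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
  if (any(truth < 0 | truth > 1)) stop("truth values must lie in [0, 1]")
  w <- prior * truth
  tot <- sum(w)
  if (tot <= 0) stop("all-zero weighted truth: posterior undefined")
  w / tot
}
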