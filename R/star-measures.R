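# Channel and prediction confirmation measures ------------------------------
#
# b* scores a rule by the conditionals *given the consequent variable*
# (channel direction): b* = (pos - neg) / max(pos, neg) with
# pos = P(ant | cons), neg = P(ant | !cons). It is a monotone transform of
# the likelihood ratio, b* = (LR - 1)/max(LR, 1), and indicates the quality
# of the testing means.
#
# c* scores a rule by the two counts sharing the rule's antecedent condition
# (prediction direction): c* = (pos - neg) / max(pos, neg) with
# pos = P(cons | ant), neg = P(!cons | ant); on counts c*(e1->h1) =
# (a - c)/max(a, c). It is a transform of the correct rate and indicates the
# quality of a probability prediction.
#
# Both shapes carry Consequent Symmetry structurally: negating the
# consequent swaps pos and neg, flipping the sign. The same pairs with "+"
# instead of "max" give bF* (identical to F) and cF*.

star_report <- function(name, rl, value) {
  out <- measure_report(name, rl, value)
  out
}

#' Channel confirmation measure b*
#'
#' `b* = (pos - neg)/max(pos, neg)` where `pos`/`neg` are the rule's
#' positive-example and counterexample conditionals in the channel direction
#' (conditioned on the consequent variable for `e -> h` rules, on the
#' antecedent's opposite variable for `h -> e` rules). Equivalently
#' `b* = (LR - 1)/max(LR, 1)` for the rule's likelihood ratio. Values lie in
#' \[-1, 1\]; `+1` without counterexamples, `-1` without positive examples,
#' `NaN` when both conditionals are zero.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @param rule a [rule()] or string; any of the 16 forms.
#' @return a one-row data.frame with `measure`, `rule`, `value`, `defined`.
#' @examples
#' nat <- test_profile(0.5, 0.95, prior = 0.25)
#' b_star(nat, "e1->h1")$value   # 0.9
#' b_star(nat, "e0->h0")$value   # 0.4736...
#' @export
b_star <- function(table, rule = "e1->h1") {
  classic_measure("b*", table, rule)
}

#' Prediction confirmation measure c*
#'
#' `c* = (pos - neg)/max(pos, neg)` on the two counts sharing the rule's
#' antecedent condition; on counts `c*(e1->h1) = (a - c)/max(a, c)`,
#' `c*(e0->h0) = (d - b)/max(d, b)`, `c*(h1->e1) = (a - b)/max(a, b)`,
#' `c*(h0->e0) = (d - c)/max(d, c)`, with negative-consequent forms by
#' Consequent Symmetry.
#'
#' @inheritParams b_star
#' @return a one-row data.frame with `measure`, `rule`, `value`, `defined`.
#' @examples
#' c_star(contingency_table(200, 0, 720, 80))$value  # -0.7222...
#' @export
c_star <- function(table, rule = "e1->h1") {
  classic_measure("c*", table, rule)
}

#' Prediction confirmation measure cF* (difference over sum)
#'
#' Same conditional pair as [c_star()] but normalized by the sum instead of
#' the max: on counts `cF*(e1->h1) = (a - c)/(a + c)`.
#'
#' @inheritParams b_star
#' @return a one-row data.frame with `measure`, `rule`, `value`, `defined`.
#' @export
cf_star <- function(table, rule = "e1->h1") {
  classic_measure("cF*", table, rule)
}

#' b* as a function of a likelihood ratio
#'
#' `b* = (LR - 1)/max(LR, 1)`; the matching disconfirmation proportion is
#' `b' = min(LR, 1/LR)`.
#'
#' @param LR a non-negative likelihood ratio (may be `Inf`).
#' @return a list with `b_star` and `b_prime`.
#' @examples
#' b_star_from_lr(10)   # b* = 0.9, b' = 0.1
#' @export
b_star_from_lr <- function(LR) {
  if (is.nan(LR)) return(list(b_star = NaN, b_prime = NaN))
  if (LR < 0) stop("LR must be non-negative")
  if (is.infinite(LR)) return(list(b_star = 1, b_prime = 0))
  list(b_star = (LR - 1) / max(LR, 1),
       b_prime = min(LR, if (LR > 0) 1 / LR else Inf))
}

#' Disconfirmation proportions b'* and c'*
#'
#' The unbelievable-part proportions dual to [b_star()] and [c_star()]:
#' `b'* = min(LR, 1/LR)` on the rule's channel likelihood ratio, and
#' `c'* = min(pos/neg, neg/pos)` on the prediction conditionals. Both lie in
#' \[0, 1\] and satisfy `m* = 1 - m'*` when `m* >= 0` and `m* = m'* - 1`
#' otherwise.
#'
#' @inheritParams b_star
#' @param type `"b"` for the channel proportion, `"c"` for the prediction
#'   proportion.
#' @return a one-row data.frame with `measure`, `rule`, `value`, `defined`.
#' @export
disconfirmation <- function(table, rule = "e1->h1", type = c("b", "c")) {
  type <- match.arg(type)
  if (inherits(table, "test_profile")) table <- as_contingency_table(table)
  rl <- parse_rule(rule)
  pair <- if (type == "b") channel_pair(rl, table$a, table$b, table$c, table$d)
          else prediction_pair(rl, table$a, table$b, table$c, table$d)
  ratio <- pair$pos / pair$neg
  v <- if (is.nan(ratio)) NaN else min(ratio, 1 / ratio)
  star_report(paste0(type, "'*"), rl, v)
}
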