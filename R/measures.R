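# Vectorized measure kernel -------------------------------------------------
#
# All confirmation measures are functions f(a, b, c, d) once a rule fixes the
# antecedent/consequent events. The kernel below evaluates each measure on
# vectors of counts so the property lab can sweep grids cheaply; the
# user-facing wrappers operate on single tables.
#
# Conventions:
#  * logs are base 2 throughout (R, L and all information quantities);
#  * a conditional with zero denominator is NaN (undefined marker);
#  * log of zero is -Inf, never clamped.

MEASURE_NAMES <- c("D", "M", "R", "C", "Z", "S", "N", "L", "F",
                   "b*", "c*", "bF*", "cF*", "CF", "LR+")

# channel-direction conditional pair for a rule: P(ant|cons), P(ant|!cons)
channel_pair <- function(rl, a, b, c, d) {
  A <- rl$antecedent; H <- rl$consequent
  list(pos = cond_prob(A, H, a, b, c, d),
       neg = cond_prob(A, negate_event(H), a, b, c, d))
}

# prediction-direction pair for a rule: P(cons|ant), P(!cons|ant)
prediction_pair <- function(rl, a, b, c, d) {
  A <- rl$antecedent; H <- rl$consequent
  list(pos = cond_prob(H, A, a, b, c, d),
       neg = cond_prob(negate_event(H), A, a, b, c, d))
}

is_e_side <- function(rl) substr(rl$antecedent, 1, 1) == "e"

# Z shape shared by Z and the certainty-factor alias: piecewise-normalized
# posterior increment for a rule with antecedent A and consequent H.
z_kernel <- function(rl, a, b, c, d) {
  A <- rl$antecedent; H <- rl$consequent
  n <- a + b + c + d
  pH <- event_count(H, a, b, c, d) / n
  pHA <- cond_prob(H, A, a, b, c, d)
  ifelse(pHA >= pH, (pHA - pH) / (1 - pH), (pHA - pH) / pH)
}

# Evaluate one measure on count vectors for a given rule. Classic measures
# other than F require an e-side antecedent (the canonical formula shapes);
# b*, c*, bF*, cF* and F are defined for all 16 rule forms, CF for h-side
# antecedents via the Z alias.
measure_kernel <- function(name, a, b, c, d, rl) {
  name <- match.arg(name, MEASURE_NAMES)
  A <- rl$antecedent; H <- rl$consequent
  n <- a + b + c + d
  if (name %in% c("D", "M", "R", "C", "Z", "S", "N", "L", "LR+") &&
      !is_e_side(rl))
    stop("measure ", name, " uses the canonical e->h formula shape; ",
         "rule must have a test-result antecedent")
  switch(name,
    "D" = cond_prob(H, A, a, b, c, d) - event_count(H, a, b, c, d) / n,
    "M" = cond_prob(A, H, a, b, c, d) - event_count(A, a, b, c, d) / n,
    "R" = log2(cond_prob(H, A, a, b, c, d) / (event_count(H, a, b, c, d) / n)),
    "C" = joint_count(A, H, a, b, c, d) / n -
          (event_count(A, a, b, c, d) / n) * (event_count(H, a, b, c, d) / n),
    "Z" = z_kernel(rl, a, b, c, d),
    "S" = cond_prob(H, A, a, b, c, d) -
          cond_prob(H, negate_event(A), a, b, c, d),
    "N" = cond_prob(A, H, a, b, c, d) -
          cond_prob(A, negate_event(H), a, b, c, d),
    "L" = log2(cond_prob(A, H, a, b, c, d) /
               cond_prob(A, negate_event(H), a, b, c, d)),
    "LR+" = cond_prob(A, H, a, b, c, d) /
            cond_prob(A, negate_event(H), a, b, c, d),
    "F" = ,
    "bF*" = {
      p <- channel_pair(rl, a, b, c, d)
      (p$pos - p$neg) / (p$pos + p$neg)
    },
    "b*" = {
      p <- channel_pair(rl, a, b, c, d)
      (p$pos - p$neg) / pmax(p$pos, p$neg)
    },
    "c*" = {
      p <- prediction_pair(rl, a, b, c, d)
      (p$pos - p$neg) / pmax(p$pos, p$neg)
    },
    "cF*" = {
      p <- prediction_pair(rl, a, b, c, d)
      (p$pos - p$neg) / (p$pos + p$neg)
    },
    "CF" = {
      if (is_e_side(rl))
        stop("the certainty factor scores an h -> e inference")
      z_kernel(mirror_rule(rl), a, b, c, d)
    })
}

# CF(h->e) = Z(e->h): mirror swaps antecedent and consequent
mirror_rule <- function(rl) rule(rl$consequent, rl$antecedent)

measure_report <- function(name, rl, value) {
  data.frame(measure = name,
             rule = paste0(rl$antecedent, "->", rl$consequent),
             value = value,
             defined = !is.nan(value),
             stringsAsFactors = FALSE)
}

#' Evaluate a confirmation measure on a contingency table
#'
#' A single dispatcher over the measure registry: the classical measures
#' `D`, `M`, `R`, `C`, `Z`, `S`, `N`, `L`, `F`, the channel and prediction
#' measures `b*`, `c*`, `bF*` (identical to `F`), `cF*`, the certainty
#' factor `CF`, and the positive likelihood ratio `LR+`.
#'
#' Classical measures use the canonical conditional-probability formulas for
#' rules with a test-result antecedent (`e1` or `e0`); the test-negative rule
#' `e0 -> h0` is handled by substituting e0/h0 into the same formula shapes.
#' `b*`, `c*`, `cF*` and `F` are defined for all sixteen rule forms, with
#' Consequent Symmetry (`m(e -> h0) = -m(e -> h1)`) built into the shared
#' difference-over-max and difference-over-sum shapes. `CF` requires an
#' h-side antecedent and equals `Z` of the mirrored rule.
#'
#' Logs (for `R` and `L`) are base 2. Undefined conditionals propagate as
#' `NaN` with `defined = FALSE`; a log of zero yields `-Inf`.
#'
#' @param name measure name; one of `r paste(MEASURE_NAMES, collapse = ", ")`.
#' @param table a [contingency_table()] or [test_profile()].
#' @param rule a [rule()] or string such as `"e1->h1"` (the default).
#' @return a one-row data.frame with columns `measure`, `rule`, `value`,
#'   `defined`.
#' @examples
#' tab <- contingency_table(20, 180, 8, 792)
#' classic_measure("D", tab)          # 0.514...
#' classic_measure("b*", tab)         # 0.9
#' @export
classic_measure <- function(name, table, rule = "e1->h1") {
  if (inherits(table, "test_profile")) table <- as_contingency_table(table)
  stopifnot(inherits(table, "contingency_table"))
  rl <- parse_rule(rule)
  v <- measure_kernel(name, table$a, table$b, table$c, table$d, rl)
  out <- measure_report(name, rl, v)
  out$defined <- !is.nan(v)
  out
}

#' Scalar value of a confirmation measure
#'
#' Convenience wrapper around [classic_measure()] returning just the value.
#'
#' @inheritParams classic_measure
#' @return a numeric scalar (`NaN` if undefined).
#' @export
measure_value <- function(name, table, rule = "e1->h1") {
  classic_measure(name, table, rule)$value
}

#' Measure grid over tables or rules
#'
#' Evaluates a set of measures on a set of tables (rows = tables, columns =
#' measures), the layout used to compare measures side by side.
#'
#' @param tables a list of [contingency_table()] objects (or a single one).
#' @param measures character vector of measure names.
#' @param rule rule applied to every cell.
#' @param digits if non-NULL, round the grid half-up to this many decimals.
#' @return a data.frame with a `label` column and one column per measure.
#' @export
measure_grid <- function(tables, measures = c("D", "M", "R", "C", "Z", "S",
                                              "N", "L", "F", "b*", "c*"),
                         rule = "e1->h1", digits = NULL) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  rl <- parse_rule(rule)
  rows <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    vals <- vapply(measures, function(m)
      measure_kernel(m, tab$a, tab$b, tab$c, tab$d, rl), numeric(1))
    if (!is.null(digits)) vals <- round_half_up(vals, digits)
    df <- as.data.frame(as.list(vals), check.names = FALSE)
    lbl <- if (!is.null(tab$label)) tab$label else paste0("table", i)
    cbind(data.frame(label = lbl, stringsAsFactors = FALSE), df)
  })
  do.call(rbind, rows)
}

#' Export a measure grid as TSV
#'
#' @param grid a data.frame from [measure_grid()] or [evaluate_test()].
#' @param path output file path.
#' @export
write_measure_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The four directional forms of measure F
#'
#' Measure F (difference over sum of the channel conditionals) has four
#' distinct confirmation formulas for the four positive-consequent rules;
#' on counts they are `F(e1->h1) = (ad-bc)/(ad+bc+2ac)`,
#' `F(h1->e1) = (ad-bc)/(ad+bc+2ab)`, `F(e0->h0) = (ad-bc)/(ad+bc+2bd)` and
#' `F(h0->e0) = (ad-bc)/(ad+bc+2cd)`. The conditional-probability form and
#' the count identity agree exactly; this function evaluates the count
#' identity.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @param rule one of the four rules above (object or string); negative
#'   consequents are resolved by Consequent Symmetry.
#' @return a one-row data.frame as in [classic_measure()].
#' @export
f_directional <- function(table, rule = "e1->h1") {
  if (inherits(table, "test_profile")) table <- as_contingency_table(table)
  rl <- parse_rule(rule)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  key <- paste0(rl$antecedent, "->", rl$consequent)
  sgn <- 1
  flip <- c("e1->h0" = "e1->h1", "h1->e0" = "h1->e1",
            "e0->h1" = "e0->h0", "h0->e1" = "h0->e0")
  if (key %in% names(flip)) { sgn <- -1; key <- flip[[key]] }
  cross <- switch(key,
                  "e1->h1" = 2 * a * c,
                  "h1->e1" = 2 * a * b,
                  "e0->h0" = 2 * b * d,
                  "h0->e0" = 2 * c * d)
  v <- sgn * (a * d - b * c) / (a * d + b * c + cross)
  out <- measure_report("F", rl, v)
  out$defined <- !is.nan(v)
  out
}

#' Certainty factor of an uncertain inference h -> e
#'
#' The certainty factor of rule-based expert systems scores how true an
#' uncertain inference `h -> e` is; it equals measure `Z` of the mirrored
#' rule `e -> h`.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @param rule a rule with an h-side antecedent, default `"h1->e1"`.
#' @return a one-row data.frame as in [classic_measure()].
#' @export
certainty_factor <- function(table, rule = "h1->e1") {
  classic_measure("CF", table, rule)
}
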