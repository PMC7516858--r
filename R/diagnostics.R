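# Medical-test evaluation and two-test decision engine ----------------------

#' Degrees of confirmation of a test's positive and negative results
#'
#' For each measure, `c(test+)` scores the rule `e1 -> h1` and `c(test-)`
#' scores `e0 -> h0` on the contingency structure implied by the profile
#' (sensitivity, specificity, prior).
#'
#' @param profile a [test_profile()].
#' @param measures character vector of measure names.
#' @param digits optional half-up rounding.
#' @return a data.frame with columns `measure`, `positive`, `negative`.
#' @examples
#' evaluate_test(test_profile(0.5, 0.95, 0.25), measures = c("F", "b*"))
#' @export
evaluate_test <- function(profile,
                          measures = c("D", "M", "Z", "S", "C", "N", "F",
                                       "b*", "c*"),
                          digits = NULL) {
  stopifnot(inherits(profile, "test_profile"))
  tab <- as_contingency_table(profile)
  pos <- vapply(measures, function(m) measure_value(m, tab, "e1->h1"),
                numeric(1))
  neg <- vapply(measures, function(m) measure_value(m, tab, "e0->h0"),
                numeric(1))
  if (!is.null(digits)) {
    pos <- round_half_up(pos, digits); neg <- round_half_up(neg, digits)
  }
  data.frame(measure = measures, positive = pos, negative = neg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-test decision grid
#'
#' When two tests disagree, the final diagnosis follows the result whose
#' supporting rule carries the strictly larger degree of confirmation: in
#' the (A-negative, B-positive) cell, `c(B+)` is compared with `c(A-)`.
#' Concordant cells keep the shared result; exact ties are reported as
#' `"undecided"`. With a belief `threshold`, a result whose degree of
#' confirmation does not exceed the threshold is not believed at all: if
#' only one side of a discordant cell is believable it wins, and if
#' neither is, the cell is `"undecided"`.
#'
#' @param profile_a,profile_b two [test_profile()] objects (shared prior
#'   taken from `profile_a`).
#' @param measure measure name used for the comparison.
#' @param threshold optional belief threshold (default `NULL`, plain
#'   comparison).
#' @return a list with `decision` (2x2 character matrix, rows = test A
#'   result, columns = test B result), `degrees` (the four degrees of
#'   confirmation) and `measure`.
#' @examples
#' nat <- test_profile(0.5, 0.95, 0.25, label = "NAT")
#' ct  <- test_profile(0.8, 0.75, 0.25, label = "CT")
#' two_test_decision(nat, ct, "b*")$decision
#' @export
two_test_decision <- function(profile_a, profile_b, measure = "b*",
                              threshold = NULL) {
  stopifnot(inherits(profile_a, "test_profile"),
            inherits(profile_b, "test_profile"))
  pb <- test_profile(profile_b$sensitivity, profile_b$specificity,
                     prior = profile_a$prior, label = profile_b$label)
  ea <- evaluate_test(profile_a, measures = measure)
  eb <- evaluate_test(pb, measures = measure)
  deg <- c(a_pos = ea$positive, a_neg = ea$negative,
           b_pos = eb$positive, b_neg = eb$negative)
  believable <- function(v) is.null(threshold) || v > threshold
  contest <- function(pos_deg, neg_deg) {
    # one test says positive (degree pos_deg), the other negative (neg_deg)
    bp <- believable(pos_deg); bn <- believable(neg_deg)
    if (bp && !bn) return("positive")
    if (bn && !bp) return("negative")
    if (!bp && !bn) return("undecided")
    if (pos_deg > neg_deg) "positive"
    else if (pos_deg < neg_deg) "negative"
    else "undecided"
  }
  dec <- matrix(NA_character_, 2, 2,
                dimnames = list(A = c("negative", "positive"),
                                B = c("negative", "positive")))
  dec["positive", "positive"] <- "positive"
  dec["negative", "negative"] <- "negative"
  dec["negative", "positive"] <- contest(deg[["b_pos"]], deg[["a_neg"]])
  dec["positive", "negative"] <- contest(deg[["a_pos"]], deg[["b_neg"]])
  list(decision = dec, degrees = deg, measure = measure,
       threshold = threshold)
}

# Bundled worked examples ----------------------------------------------------

#' Bundled worked examples and their expected values
#'
#' A machine-readable set of the package's reference inputs and the values
#' they are expected to reproduce, used by the test suite and by
#' [reproduce()]:
#'
#' * `extreme_examples`: three contingency tables contrasting a
#'   low-sensitivity/low-counterexample test, a high-sensitivity/many-
#'   counterexample test, and a rare-condition variant, with the full
#'   expected measure grid (3-decimal values; logs base 2). Two cells carry
#'   `erratum` flags where the printed source values are inconsistent with
#'   the defining formulas: the first example's `c*` (formula gives 0.6)
#'   and the third example's `N` (formula gives 0.909).
#' * `test_profiles`: the NAT and CT profiles (sensitivity 0.5/0.95 and
#'   0.8/0.75) with shared prior 0.25.
#' * `assessment_grid`: expected 2-decimal degrees of confirmation of the
#'   four test results under nine measures.
#' * `decision_grid`: the improved two-test diagnosis with `b*`, including
#'   the discordant cell that changes from negative to positive.
#' * `raven_base`: the base table `a = d = 20`, `b = c = 10` with expected
#'   increment rows; the `S` and `N` `delta_a` cells are flagged as errata
#'   (formulas give 0.344, not the printed 0.334).
#' * `prevalence_sweep`: priors with the posteriors predicted from
#'   `b* = 0.9`; the two low-prior printed posteriors are flagged as errata
#'   (the prediction formula gives 0.0099 and 0.526).
#'
#' @return a named list of fixtures.
#' @export
worked_examples <- function() {
  extreme <- list(
    tables = list(
      ex1 = contingency_table(20, 180, 8, 792, label = "ex1"),
      ex2 = contingency_table(200, 0, 720, 80, label = "ex2"),
      ex3 = contingency_table(10, 0, 90, 900, label = "ex3")),
    measures = c("D", "M", "R", "C", "Z", "S", "N", "L", "F", "b*", "c*"),
    expected = rbind(
      ex1 = c(D = 0.514, M = 0.072, R = 1.84, C = 0.014, Z = 0.643,
              S = 0.529, N = 0.09, L = 3.32, F = 0.818, "b*" = 0.9,
              "c*" = 0.8),
      ex2 = c(D = 0.017, M = 0.08, R = 0.12, C = 0.016, Z = 0.022,
              S = 0.217, N = 0.1, L = 0.152, F = 0.053, "b*" = 0.1,
              "c*" = -0.722),
      ex3 = c(D = 0.09, M = 0.9, R = 3.32, C = 0.009, Z = 0.091,
              S = 0.1, N = 0.091, L = 3.46, F = 0.833, "b*" = 0.91,
              "c*" = -0.9)),
    # cells whose printed values contradict the defining formulas
    errata = list(c("ex1", "c*"), c("ex3", "N")))

  profiles <- list(
    NAT = test_profile(0.5, 0.95, prior = 0.25, label = "NAT"),
    CT = test_profile(0.8, 0.75, prior = 0.25, label = "CT"))

  assessment <- rbind(
    "NAT-" = c(D = 0.10, M = 0.11, Z = 0.40, S = 0.62, C = 0.08, N = 0.45,
               F = 0.31, "b*" = 0.47, "c*" = 0.83),
    "NAT+" = c(D = 0.52, M = 0.34, Z = 0.69, S = 0.62, C = 0.08, N = 0.45,
               F = 0.82, "b*" = 0.90, "c*" = 0.70),
    "CT-" = c(D = 0.17, M = 0.14, Z = 0.67, S = 0.43, C = 0.10, N = 0.55,
              F = 0.58, "b*" = 0.73, "c*" = 0.91),
    "CT+" = c(D = 0.27, M = 0.41, Z = 0.36, S = 0.43, C = 0.10, N = 0.55,
              F = 0.52, "b*" = 0.69, "c*" = 0.06))

  decision <- matrix(c("negative", "positive", "positive", "positive"),
                     2, 2, dimnames = list(A = c("negative", "positive"),
                                           B = c("negative", "positive")))
  # rows: NAT result; columns: CT result; the (NAT-, CT+) cell is the one
  # the two-test rule changes from negative to positive.

  raven <- list(
    base = contingency_table(20, 10, 10, 20, label = "raven_base"),
    measures = c("D", "M", "C", "Z", "S", "N", "F", "LR+", "c*"),
    expected = rbind(
      D = c(base = 0.167, delta_a = 0.169, delta_d = 0.175),
      M = c(base = 0.167, delta_a = 0.169, delta_d = 0.175),
      C = c(base = 0.083, delta_a = 0.086, delta_d = 0.086),
      Z = c(base = 0.333, delta_a = 0.344, delta_d = 0.344),
      S = c(base = 0.333, delta_a = 0.334, delta_d = 0.344),
      N = c(base = 0.333, delta_a = 0.334, delta_d = 0.344),
      F = c(base = 0.333, delta_a = 0.340, delta_d = 0.348),
      "LR+" = c(base = 2, delta_a = 2.03, delta_d = 2.07),
      "c*" = c(base = 0.5, delta_a = 0.524, delta_d = 0.5)),
    errata = list(c("S", "delta_a"), c("N", "delta_a")))

  sweep <- list(
    priors = c(0.001, 0.1, 0.25),
    b_star = 0.9,
    printed_posterior = c(0.002, 0.19, 0.77),
    errata = c(TRUE, TRUE, FALSE))

  list(extreme_examples = extreme,
       test_profiles = profiles,
       assessment_grid = assessment,
       decision_grid = decision,
       raven_base = raven,
       prevalence_sweep = sweep)
}

#' Recompute a bundled worked example
#'
#' Recomputes the quantities of one fixture from [worked_examples()] with
#' the package's own functions, rounded half-up to the fixture's printed
#' precision (3 decimals for the measure grids, 2 for the test-assessment
#' values).
#'
#' @param id one of `"extreme_examples"`, `"assessment_grid"`,
#'   `"decision_grid"`, `"raven_base"`, `"prevalence_sweep"`.
#' @return a data.frame or matrix mirroring the fixture's layout.
#' @export
reproduce <- function(id = c("extreme_examples", "assessment_grid",
                             "decision_grid", "raven_base",
                             "prevalence_sweep")) {
  id <- match.arg(id)
  wx <- worked_examples()
  switch(id,
    extreme_examples = {
      fx <- wx$extreme_examples
      measure_grid(fx$tables, measures = fx$measures, digits = 3)
    },
    assessment_grid = {
      pr <- wx$test_profiles
      nat <- evaluate_test(pr$NAT, digits = 2)
      ct <- evaluate_test(pr$CT, digits = 2)
      out <- rbind("NAT-" = stats::setNames(nat$negative, nat$measure),
                   "NAT+" = stats::setNames(nat$positive, nat$measure),
                   "CT-" = stats::setNames(ct$negative, ct$measure),
                   "CT+" = stats::setNames(ct$positive, ct$measure))
      out
    },
    decision_grid = {
      pr <- wx$test_profiles
      two_test_decision(pr$NAT, pr$CT, "b*")$decision
    },
    raven_base = {
      fx <- wx$raven_base
      raven_experiment(fx$base, measures = fx$measures, digits = 3)
    },
    prevalence_sweep = {
      fx <- wx$prevalence_sweep
      data.frame(prior = fx$priors,
                 posterior = vapply(fx$priors, function(p)
                   predict_from_b(p, fx$b_star)$p_h1, numeric(1)))
    })
}
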