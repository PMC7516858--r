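#' 2x2 contingency table of rule evidence
#'
#' The evidential object consumed by every confirmation measure: the counts of
#' the four example types for a rule `e -> h`, where `a` counts positive
#' examples (e1, h1), `b` counts (e0, h1), `c` counts counterexamples (e1, h0)
#' and `d` counts (e0, h0).
#'
#' Counts are stored as non-negative reals so that expected tables derived
#' from a [test_profile()] are exact; use `round_counts()` (half-up) when an
#' integer table is wanted for export.
#'
#' @param a,b,c,d non-negative counts of the four example types.
#' @param label optional character label for the table.
#' @return an object of class `contingency_table`.
#' @examples
#' tab <- contingency_table(20, 180, 8, 792)
#' rates(tab)$PPV
#' @export
contingency_table <- function(a, b, c, d, label = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts a, b, c, d must be finite and non-negative")
  if (sum(counts) <= 0)
    stop("total count must be positive")
  structure(list(a = a, b = b, c = c, d = d, label = label),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 contingency table",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  m <- matrix(c(x$b, x$d, x$a, x$c), 2, 2,
              dimnames = list(c("h1", "h0"), c("e0", "e1")))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.contingency_table <- function(x, ...) {
  data.frame(a = x$a, b = x$b, c = x$c, d = x$d,
             label = if (is.null(x$label)) NA_character_ else x$label,
             stringsAsFactors = FALSE)
}

#' Round a table's counts to integers (half-up)
#'
#' @param table a [contingency_table()].
#' @return a `contingency_table` with integer counts.
#' @export
round_counts <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  contingency_table(round_half_up(table$a), round_half_up(table$b),
                    round_half_up(table$c), round_half_up(table$d),
                    label = table$label)
}

#' Diagnostic test profile
#'
#' The medical-test parameterization of a contingency structure: sensitivity
#' P(e1|h1), specificity P(e0|h0) and the prior prevalence P(h1).
#'
#' @param sensitivity probability of a positive result given infection, in
#'   \[0, 1\].
#' @param specificity probability of a negative result given non-infection,
#'   in \[0, 1\].
#' @param prior prior probability of infection P(h1), strictly inside (0, 1).
#' @param label optional test name.
#' @return an object of class `test_profile`.
#' @examples
#' nat <- test_profile(0.5, 0.95, prior = 0.25, label = "NAT")
#' as_contingency_table(nat, n = 400)
#' @export
test_profile <- function(sensitivity, specificity, prior, label = NULL) {
  if (!is.finite(sensitivity) || sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must be in [0, 1]")
  if (!is.finite(specificity) || specificity < 0 || specificity > 1)
    stop("specificity must be in [0, 1]")
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop("prior must be strictly between 0 and 1")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prior = prior, label = label),
            class = "test_profile")
}

#' @export
print.test_profile <- function(x, ...) {
  cat("test profile", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      ": sensitivity ", x$sensitivity,
      ", specificity ", x$specificity,
      ", prior P(h1) ", x$prior, "\n", sep = "")
  invisible(x)
}

#' Expected contingency table implied by a test profile
#'
#' Expands a (sensitivity, specificity, prior) triple into the expected
#' counts for a sample of size `n`:
#' `a = n * prior * sensitivity`, `b = n * prior * (1 - sensitivity)`,
#' `c = n * (1 - prior) * (1 - specificity)`,
#' `d = n * (1 - prior) * specificity`.
#' Counts are exact reals; pass `round = TRUE` for half-up integers.
#'
#' @param profile a [test_profile()].
#' @param n positive sample size.
#' @param round round the counts half-up to integers.
#' @return a [contingency_table()].
#' @export
as_contingency_table <- function(profile, n = 1, round = FALSE) {
  stopifnot(inherits(profile, "test_profile"))
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  tab <- contingency_table(
    a = n * profile$prior * profile$sensitivity,
    b = n * profile$prior * (1 - profile$sensitivity),
    c = n * (1 - profile$prior) * (1 - profile$specificity),
    d = n * (1 - profile$prior) * profile$specificity,
    label = profile$label)
  if (round) round_counts(tab) else tab
}

#' Directed rule between test-result and state events
#'
#' A rule is a directed implication `antecedent -> consequent` where one side
#' is a test-result event (`e1` positive, `e0` negative) and the other a
#' state event (`h1` infected, `h0` uninfected). It selects which of the 16
#' confirmation formula shapes applies.
#'
#' @param antecedent,consequent event names among `"e1"`, `"e0"`, `"h1"`,
#'   `"h0"`; the two must come from different variables.
#' @return an object of class `rule`.
#' @examples
#' rule("e1", "h1")
#' parse_rule("h0->e0")
#' @export
rule <- function(antecedent, consequent) {
  ev <- c("e1", "e0", "h1", "h0")
  if (!(antecedent %in% ev) || !(consequent %in% ev))
    stop("events must be one of e1, e0, h1, h0")
  side <- function(x) substr(x, 1, 1)
  if (side(antecedent) == side(consequent))
    stop("antecedent and consequent must belong to different variables")
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "rule")
}

#' @rdname rule
#' @param x a string like `"e1->h1"`, or an existing `rule`.
#' @export
parse_rule <- function(x) {
  if (inherits(x, "rule")) return(x)
  parts <- strsplit(gsub("\\s", "", x), "->", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("rule string must look like 'e1->h1'")
  rule(parts[1], parts[2])
}

#' @export
print.rule <- function(x, ...) {
  cat("rule ", x$antecedent, " -> ", x$consequent, "\n", sep = "")
  invisible(x)
}

# negation of an event name
negate_event <- function(ev) {
  c(e1 = "e0", e0 = "e1", h1 = "h0", h0 = "h1")[[ev]]
}

# marginal count of an event, vectorized over count vectors
event_count <- function(ev, a, b, c, d) {
  switch(ev,
         e1 = a + c, e0 = b + d,
         h1 = a + b, h0 = c + d,
         stop("unknown event ", ev))
}

# joint count of an e-event and an h-event (order free)
joint_count <- function(ev1, ev2, a, b, c, d) {
  key <- paste(sort(c(ev1, ev2)), collapse = ",")
  switch(key,
         "e1,h1" = a, "e0,h1" = b, "e1,h0" = c, "e0,h0" = d,
         stop("events must come from different variables"))
}

# conditional probability P(x | y) as a plug-in count ratio; 0/0 -> NaN
cond_prob <- function(x, y, a, b, c, d) {
  joint_count(x, y, a, b, c, d) / event_count(y, a, b, c, d)
}

#' All conditional probabilities and named rates of a table
#'
#' Returns the eight plug-in conditionals (the two channel directions) and
#' the standard named rates. A conditional with a zero denominator is
#' returned as `NaN` (an explicit undefined marker) rather than raising an
#' error, so that measure functions can apply their own limit conventions.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @return a list of class `rate_set` with components `P_e1_h1`, `P_e0_h1`,
#'   `P_e1_h0`, `P_e0_h0`, `P_h1_e1`, `P_h0_e1`, `P_h1_e0`, `P_h0_e0`
#'   (`P_x_y` is P(x|y)), the marginals `P_h1`, `P_e1`, and named rates
#'   `TPR`, `TNR`, `FNR`, `FPR`, `PPV`, `NPV`, `FDR`, `FOR`.
#' @export
rates <- function(table) {
  if (inherits(table, "test_profile")) table <- as_contingency_table(table)
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  r <- list(
    P_e1_h1 = cond_prob("e1", "h1", a, b, c, d),
    P_e0_h1 = cond_prob("e0", "h1", a, b, c, d),
    P_e1_h0 = cond_prob("e1", "h0", a, b, c, d),
    P_e0_h0 = cond_prob("e0", "h0", a, b, c, d),
    P_h1_e1 = cond_prob("h1", "e1", a, b, c, d),
    P_h0_e1 = cond_prob("h0", "e1", a, b, c, d),
    P_h1_e0 = cond_prob("h1", "e0", a, b, c, d),
    P_h0_e0 = cond_prob("h0", "e0", a, b, c, d),
    P_h1 = (a + b) / n,
    P_e1 = (a + c) / n)
  r$TPR <- r$P_e1_h1; r$FNR <- r$P_e0_h1
  r$TNR <- r$P_e0_h0; r$FPR <- r$P_e1_h0
  r$PPV <- r$P_h1_e1; r$FDR <- r$P_h0_e1
  r$NPV <- r$P_h0_e0; r$FOR <- r$P_h1_e0
  class(r) <- "rate_set"
  r
}

#' @export
print.rate_set <- function(x, ...) {
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Likelihood ratios of a table or profile
#'
#' `LR_plus = P(e1|h1)/P(e1|h0)` is the usual positive likelihood ratio.
#' `LR_minus = P(e0|h0)/P(e0|h1)` follows the convention used throughout
#' this package for the test-negative rule `e0 -> h0`; note that it is the
#' *reciprocal* of the clinical negative likelihood ratio
#' P(e0|h1)/P(e0|h0). A zero denominator yields `Inf`; 0/0 yields `NaN`.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @return a list with `LR_plus` and `LR_minus`.
#' @export
likelihood_ratios <- function(table) {
  r <- rates(table)
  list(LR_plus = r$P_e1_h1 / r$P_e1_h0,
       LR_minus = r$P_e0_h0 / r$P_e0_h1)
}

#' Read and write contingency tables as CSV
#'
#' The format is one row per table with header `a,b,c,d` and an optional
#' `label` column.
#'
#' @param path file path.
#' @return `read_tables()` returns a list of [contingency_table()] objects.
#' @export
read_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(df)))
    stop("CSV must have columns a, b, c, d")
  lapply(seq_len(nrow(df)), function(i) {
    contingency_table(df$a[i], df$b[i], df$c[i], df$d[i],
                      label = if ("label" %in% names(df)) df$label[i] else NULL)
  })
}

#' @rdname read_tables
#' @param tables a list of `contingency_table` objects (or a single one).
#' @export
write_tables <- function(tables, path) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  if (all(is.na(df$label))) df$label <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a test profile from JSON
#'
#' Expects keys `sensitivity`, `specificity`, `prior` (and optionally
#' `label`).
#'
#' @param path file path to a JSON object.
#' @return a [test_profile()].
#' @export
read_test_profile <- function(path) {
  x <- jsonlite::fromJSON(path)
  test_profile(x$sensitivity, x$specificity, x$prior,
               label = if (!is.null(x$label)) x$label else NULL)
}

#' Multinomial sampling of a contingency table
#'
#' Draws `n` examples from the joint distribution over the four example
#' types, either from an explicit joint (probabilities in the order a, b, c,
#' d) or from the joint implied by a [test_profile()]. With `exact = TRUE`
#' the expected (real-valued) counts `n * p` are returned instead.
#'
#' @param joint a [test_profile()] or a numeric vector of four probabilities
#'   (order a, b, c, d) summing to 1.
#' @param n sample size.
#' @param seed integer seed; the draw is deterministic per seed and the
#'   caller's random state is left untouched.
#' @param exact return expected counts instead of a random draw.
#' @return a [contingency_table()].
#' @export
simulate_sample <- function(joint, n, seed = NULL, exact = FALSE) {
  if (inherits(joint, "test_profile")) {
    p <- as_contingency_table(joint, n = 1)
    joint <- c(p$a, p$b, p$c, p$d)
  }
  if (length(joint) != 4 || any(joint < 0) || abs(sum(joint) - 1) > 1e-9)
    stop("joint must be four non-negative probabilities summing to 1")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  if (exact) {
    cnt <- n * joint
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(seed)
    }
    cnt <- as.vector(stats::rmultinom(1, size = n, prob = joint))
  }
  contingency_table(cnt[1], cnt[2], cnt[3], cnt[4])
}

# half-up rounding (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
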