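# Property lab: symmetries, monotonicity, logicality, Nicod-Fisher ----------
#
# The desiderata are algebraic claims; the lab verifies them empirically on
# seeded random tables and exhaustive count grids, returning a concrete
# witness table on every failure.

#' Seeded random contingency tables
#'
#' Uniform integer counts in `1..max_count` (strictly positive so that every
#' conditional is defined); use explicit zero-count tables for logicality
#' edge cases.
#'
#' @param n number of tables.
#' @param seed integer seed.
#' @param max_count largest count.
#' @return a list of [contingency_table()] objects.
#' @export
random_tables <- function(n, seed = 1, max_count = 50) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cnt <- matrix(sample.int(max_count, 4 * n, replace = TRUE), ncol = 4)
  lapply(seq_len(n), function(i)
    contingency_table(cnt[i, 1], cnt[i, 2], cnt[i, 3], cnt[i, 4]))
}

symmetry_rules <- function(kind) {
  switch(kind,
         HS = list(lhs = "e1->h1", rhs = "e1->h0", sign = -1),
         ES = list(lhs = "e1->h1", rhs = "e0->h1", sign = -1),
         CS = list(lhs = "e1->h1", rhs = "h1->e1", sign = 1),
         TS = list(lhs = "e1->h1", rhs = "e0->h0", sign = 1),
         stop("kind must be HS, ES, CS or TS"))
}

#' Check a symmetry identity for a measure
#'
#' The four candidate symmetries over rule `e1 -> h1`:
#' * `HS` (Hypothesis / Consequent Symmetry): `m(e1->h1) = -m(e1->h0)`;
#' * `ES` (Evidence / Antecedent Symmetry):  `m(e1->h1) = -m(e0->h1)`;
#' * `CS` (Commutativity Symmetry):          `m(e1->h1) =  m(h1->e1)`;
#' * `TS` (Total Symmetry):                  `m(e1->h1) =  m(e0->h0)`.
#' Despite the historical names, HS constrains the *consequent* and ES the
#' *antecedent* of the rule. Only HS is desirable.
#'
#' @param measure a measure name understood by [classic_measure()].
#' @param kind one of `"HS"`, `"ES"`, `"CS"`, `"TS"`.
#' @param tables a list of tables (default: 200 seeded random tables).
#' @param tol numerical tolerance for the identity.
#' @return a list with `holds` (flag), `witness` (first violating table or
#'   `NULL`), `skipped` (tables where a side was undefined).
#' @export
check_symmetry <- function(measure, kind, tables = random_tables(200),
                           tol = 1e-9) {
  sr <- symmetry_rules(kind)
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  c <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  lhs <- measure_kernel(measure, a, b, c, d, parse_rule(sr$lhs))
  rhs <- measure_kernel(measure, a, b, c, d, parse_rule(sr$rhs))
  skip <- is.nan(lhs) | is.nan(rhs)
  ok <- ifelse(is.infinite(lhs) | is.infinite(rhs),
               lhs == sr$sign * rhs,
               abs(lhs - sr$sign * rhs) <= tol)
  bad <- which(!skip & !ok)
  if (length(bad)) {
    i <- bad[1]
    return(list(holds = FALSE,
                witness = contingency_table(a[i], b[i], c[i], d[i]),
                skipped = sum(skip)))
  }
  list(holds = TRUE, witness = NULL, skipped = sum(skip))
}

#' Check count monotonicity of a measure
#'
#' A measure `f(a, b, c, d)` is monotone when it does not decrease with `a`
#' or `d` and does not increase with `b` or `c`. The check is exhaustive
#' over unit increments on the grid `grid^4` (vectorized).
#'
#' @param measure a measure name.
#' @param grid integer vector of count values, default `1:10`.
#' @param rule rule under which the measure is evaluated.
#' @param tol slack for comparisons.
#' @return a list with `holds`, and on failure `witness` (the base table)
#'   and `direction` (which count's increment violated monotonicity).
#' @export
check_monotonicity <- function(measure, grid = 1:10, rule = "e1->h1",
                               tol = 1e-12) {
  rl <- parse_rule(rule)
  g <- expand.grid(a = grid, b = grid, c = grid, d = grid)
  base <- measure_kernel(measure, g$a, g$b, g$c, g$d, rl)
  dirs <- list(a = +1, b = -1, c = -1, d = +1)  # required sign of change
  for (nm in names(dirs)) {
    g2 <- g; g2[[nm]] <- g2[[nm]] + 1
    new <- measure_kernel(measure, g2$a, g2$b, g2$c, g2$d, rl)
    delta <- (new - base) * dirs[[nm]]
    # Inf - Inf etc. -> NaN: treat unchanged infinities as monotone
    delta[is.nan(delta) & is.infinite(base) & new == base] <- 0
    bad <- which(delta < -tol)
    if (length(bad)) {
      i <- bad[1]
      return(list(holds = FALSE,
                  witness = contingency_table(g$a[i], g$b[i], g$c[i], g$d[i]),
                  direction = nm))
    }
  }
  list(holds = TRUE, witness = NULL, direction = NULL)
}

#' Increment experiment: which example type moves a measure?
#'
#' For each measure, evaluates the base table, the table with one extra
#' positive example (`a + 1`) and the table with one extra irrelevant
#' example (`d + 1`), together with the difference of the two increments.
#' This is the raven-paradox question in computable form: does a black
#' raven (`a + 1`) confirm "ravens are black" more than a piece of white
#' chalk (`d + 1`)? The Nicod-Fisher flag requires that for rule
#' `e1 -> h1` the measure strictly increases under `a + 1`, is unchanged
#' under `b + 1` and `d + 1`, and strictly decreases under `c + 1`.
#'
#' @param base a [contingency_table()].
#' @param measures character vector of measure names.
#' @param digits optional half-up rounding of the reported values.
#' @return a data.frame with columns `measure`, `base`, `delta_a`,
#'   `delta_d`, `diff` (increment under `a+1` minus increment under `d+1`)
#'   and `nicod_fisher`.
#' @examples
#' raven_experiment(contingency_table(20, 10, 10, 20),
#'                  measures = c("F", "c*"))
#' @export
raven_experiment <- function(base,
                             measures = c("D", "M", "C", "Z", "S", "N", "F",
                                          "LR+", "c*"),
                             digits = NULL) {
  stopifnot(inherits(base, "contingency_table"))
  rl <- parse_rule("e1->h1")
  a <- base$a; b <- base$b; c <- base$c; d <- base$d
  rows <- lapply(measures, function(m) {
    v0 <- measure_kernel(m, a, b, c, d, rl)
    va <- measure_kernel(m, a + 1, b, c, d, rl)
    vb <- measure_kernel(m, a, b + 1, c, d, rl)
    vc <- measure_kernel(m, a, b, c + 1, d, rl)
    vd <- measure_kernel(m, a, b, c, d + 1, rl)
    nf <- (va > v0) && (vb == v0) && (vd == v0) && (vc < v0)
    if (!is.null(digits)) {
      v0 <- round_half_up(v0, digits); va <- round_half_up(va, digits)
      vd <- round_half_up(vd, digits)
    }
    data.frame(measure = m, base = v0, delta_a = va, delta_d = vd,
               diff = (va - v0) - (vd - v0), nicod_fisher = nf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check logicality and normalization of a measure
#'
#' Logicality: the measure is `+1` on tables without counterexamples
#' (`c = 0`, `a > 0`) and `-1` on tables without positive examples
#' (`a = 0`, `c > 0`), for rule `e1 -> h1`. Normalization: every defined
#' value on the supplied tables lies within \[-1, 1\].
#'
#' @param measure a measure name.
#' @param tables tables to scan; zero-count edge tables are always added.
#' @return a list with `logicality`, `normalization` and witnesses on
#'   failure.
#' @export
check_logicality_normalization <- function(measure,
                                           tables = random_tables(200)) {
  edge_pos <- list(contingency_table(5, 3, 0, 7),
                   contingency_table(1, 0, 0, 1),
                   contingency_table(10, 0, 0, 90))
  edge_neg <- list(contingency_table(0, 3, 5, 7),
                   contingency_table(0, 1, 1, 0))
  logicality <- TRUE; log_witness <- NULL
  for (tab in edge_pos) {
    v <- measure_value(measure, tab, "e1->h1")
    if (is.nan(v) || abs(v - 1) > 1e-9) {
      logicality <- FALSE; log_witness <- tab; break
    }
  }
  if (logicality) for (tab in edge_neg) {
    v <- measure_value(measure, tab, "e1->h1")
    if (is.nan(v) || abs(v + 1) > 1e-9) {
      logicality <- FALSE; log_witness <- tab; break
    }
  }
  normalization <- TRUE; norm_witness <- NULL
  for (tab in c(tables, edge_pos, edge_neg)) {
    v <- measure_value(measure, tab, "e1->h1")
    if (is.nan(v)) next
    if (!is.finite(v) || abs(v) > 1 + 1e-9) {
      normalization <- FALSE; norm_witness <- tab; break
    }
  }
  list(logicality = logicality, logicality_witness = log_witness,
       normalization = normalization, normalization_witness = norm_witness)
}

#' Full desiderata report for a set of measures
#'
#' Runs [check_symmetry()] (HS, ES, CS, TS), [check_monotonicity()] and
#' [check_logicality_normalization()] for each measure and collects the
#' flags.
#'
#' @param measures character vector of measure names.
#' @param tables tables for the sampling-based checks.
#' @param grid count grid for the monotonicity check.
#' @return a data.frame with one row per measure and logical columns `HS`,
#'   `ES`, `CS`, `TS`, `monotone`, `logicality`, `normalization`.
#' @export
desiderata_report <- function(measures = c("D", "M", "Z", "S", "C", "N",
                                           "L", "F", "b*", "c*", "cF*"),
                              tables = random_tables(200),
                              grid = 1:6) {
  rows <- lapply(measures, function(m) {
    sym <- vapply(c("HS", "ES", "CS", "TS"), function(k) {
      res <- tryCatch(check_symmetry(m, k, tables),
                      error = function(e) list(holds = NA))
      isTRUE(res$holds)
    }, logical(1))
    mono <- check_monotonicity(m, grid = grid)$holds
    ln <- check_logicality_normalization(m, tables)
    data.frame(measure = m, HS = sym[["HS"]], ES = sym[["ES"]],
               CS = sym[["CS"]], TS = sym[["TS"]], monotone = mono,
               logicality = ln$logicality,
               normalization = ln$normalization,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
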