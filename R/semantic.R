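# Truth functions, logical probability, semantic information ----------------
#
# A truth function T(theta|x) maps outcomes to [0,1] and represents the
# semantic meaning of a label; it need not normalize across outcomes. The
# logical probability of the label is the prior-weighted average of its
# truth function; semantic information is the log-ratio of truth value to
# logical probability (base 2, so all quantities are in bits).

#' Truth function constructors
#'
#' Four families are supported:
#' * `gaussian`: `exp(-(x - center)^2 / (2 sigma^2))`, peaking at 1 at its
#'   center (hypotheses such as "x is about 20");
#' * `logistic`: `1/(1 + exp(-k (x - x0)))`, monotone (hypotheses such as
#'   "x is elderly");
#' * `mixture`: over a finite outcome set, a crisp believable part plus a
#'   tautological part of proportion `bprime`:
#'   `bprime + (1 - bprime) * believable`;
#' * `tabular`: explicit truth values per outcome.
#'
#' @param family one of `"gaussian"`, `"logistic"`, `"mixture"`, `"tabular"`.
#' @param ... family parameters: `center` and `sigma` (gaussian); `k` and
#'   `x0` (logistic); `believable` (0/1 vector) and `bprime` (mixture);
#'   `values` (tabular).
#' @return an object of class `truth_function`.
#' @examples
#' tf <- truth_function("mixture", believable = c(h0 = 0, h1 = 1), bprime = 0.1)
#' truth_values(tf)
#' @export
truth_function <- function(family = c("gaussian", "logistic", "mixture",
                                      "tabular"), ...) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
                 gaussian = c("center", "sigma"),
                 logistic = c("k", "x0"),
                 mixture = c("believable", "bprime"),
                 tabular = "values")
  if (!all(need %in% names(params)))
    stop("family '", family, "' needs parameters: ",
         paste(need, collapse = ", "))
  if (family == "mixture") {
    if (!all(params$believable %in% c(0, 1)))
      stop("believable must be a 0/1 indicator vector")
    if (params$bprime < 0 || params$bprime > 1)
      stop("bprime must lie in [0, 1]")
  }
  if (family == "tabular" && any(params$values < 0 | params$values > 1))
    stop("tabular truth values must lie in [0, 1]")
  structure(list(family = family, params = params), class = "truth_function")
}

#' @export
print.truth_function <- function(x, ...) {
  cat("truth function (", x$family, ")\n", sep = "")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Evaluate a truth function
#'
#' @param tf a [truth_function()].
#' @param x outcomes: numeric values for `gaussian`/`logistic`; indices or
#'   names for finite families (defaults to the whole outcome set).
#' @return truth values in \[0, 1\].
#' @export
truth_values <- function(tf, x = NULL) {
  stopifnot(inherits(tf, "truth_function"))
  p <- tf$params
  switch(tf$family,
    gaussian = exp(-(x - p$center)^2 / (2 * p$sigma^2)),
    logistic = 1 / (1 + exp(-p$k * (x - p$x0))),
    mixture = {
      v <- p$bprime + (1 - p$bprime) * p$believable
      if (is.null(x)) v else v[x]
    },
    tabular = if (is.null(x)) p$values else p$values[x])
}

#' Read a truth function from JSON
#'
#' Schema: `{"family": "gaussian"|"logistic"|"mixture"|"tabular",
#' "params": {...}}`.
#'
#' @param path file path.
#' @return a [truth_function()].
#' @export
read_truth_function <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(truth_function, c(list(family = x$family), as.list(x$params)))
}

#' Logical probability of a label
#'
#' The prior-weighted average of a truth function,
#' `T(theta) = sum_i prior_i * truth_i`. For the medical-test mixture this
#' is `P(h1) + b' P(h0)`.
#'
#' @param prior probability vector over the outcome set (sums to 1).
#' @param truth a [truth_function()] over the same finite outcome set, or a
#'   numeric vector of truth values.
#' @return a scalar in \[0, 1\].
#' @examples
#' logical_probability(c(h0 = 0.75, h1 = 0.25),
#'                     c(h0 = 0.1, h1 = 1))   # 0.325
#' @export
logical_probability <- function(prior, truth) {
  if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
  tv <- if (inherits(truth, "truth_function")) truth_values(truth) else truth
  if (length(tv) != length(prior))
    stop("truth values and prior must have the same length")
  sum(prior * tv)
}

#' Semantic information of an outcome (bits)
#'
#' `I(x_i; theta) = log2( T(theta|x_i) / T(theta) )`. Wrong predictions
#' convey negative information; a zero truth value yields `-Inf`.
#'
#' @param outcome index or name of the outcome.
#' @inheritParams logical_probability
#' @return information in bits.
#' @examples
#' pr <- c(h0 = 0.75, h1 = 0.25); tv <- c(h0 = 0.1, h1 = 1)
#' semantic_information("h1", tv, pr)   # log2(1/0.325) = 1.621...
#' @export
semantic_information <- function(outcome, truth, prior) {
  tv <- if (inherits(truth, "truth_function")) truth_values(truth) else truth
  Tth <- logical_probability(prior, tv)
  if (Tth <= 0) stop("logical probability is zero")
  log2(tv[[outcome]] / Tth)
}

#' Average semantic information (bits)
#'
#' The generalized Kullback-Leibler information
#' `I = sum_i sampling_i * log2( truth_i / T(theta) )`, the expectation of
#' [semantic_information()] under a sampling distribution (for the medical
#' test, `P(h|e1)`). When the implied likelihood matches the sampling
#' distribution this is the KL divergence of the sampling distribution from
#' the prior. Terms with zero sampling weight contribute 0 even when the
#' truth value is 0.
#'
#' @param sampling probability vector (sums to 1), e.g. `P(h|e1)`.
#' @inheritParams logical_probability
#' @return bits; may be negative.
#' @export
avg_semantic_information <- function(sampling, truth, prior) {
  if (abs(sum(sampling) - 1) > 1e-9) stop("sampling must sum to 1")
  tv <- if (inherits(truth, "truth_function")) truth_values(truth) else truth
  Tth <- logical_probability(prior, tv)
  if (Tth <= 0) stop("logical probability is zero")
  terms <- sampling * log2(tv / Tth)
  sum(terms[sampling > 0])
}

#' Average-information objective as a function of b'
#'
#' For a table's rule `e1 -> h1`, the average semantic information of the
#' mixture truth function (1 on h1, b' on h0) as a function of the
#' unbelievable proportion b':
#' `I(b') = P(h0|e1) log2( b' / (P(h1) + b' P(h0)) )
#'        + P(h1|e1) log2( 1 / (P(h1) + b' P(h0)) )`.
#' This is the objective whose maximizer over \[0, 1\] is the closed-form
#' disconfirmation proportion (see [optimize_bprime()]).
#'
#' @param bprime numeric vector of candidate proportions in \[0, 1\].
#' @param table a [contingency_table()] or [test_profile()].
#' @return bits, vectorized over `bprime`.
#' @export
bprime_objective <- function(bprime, table) {
  r <- rates(table)
  Tth <- r$P_h1 + bprime * (1 - r$P_h1)
  r$P_h0_e1 * log2(bprime / Tth) + r$P_h1_e1 * log2(1 / Tth)
}

#' Optimal unbelievable proportion b'* of a table
#'
#' The maximizer of [bprime_objective()] has the closed form
#' `b'* = [P(h0|e1)/P(h0)] / [P(h1|e1)/P(h1)] = P(e1|h0)/P(e1|h1) = 1/LR+`.
#' The numeric mode maximizes the objective over a grid on \[0, 1\] with
#' local refinement; because the interior optimum falls outside the unit
#' interval exactly when the rule is disconfirmed (LR+ < 1), the numeric
#' argmax equals `min(closed form, 1)`.
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @param method `"closed"` (default) or `"numeric"`.
#' @param grid_step spacing of the search grid for the numeric mode.
#' @return the scalar b'* (for `"numeric"`, the constrained argmax).
#' @examples
#' optimize_bprime(test_profile(0.5, 0.95, 0.25))   # 0.1
#' @export
optimize_bprime <- function(table, method = c("closed", "numeric"),
                            grid_step = 1e-4) {
  method <- match.arg(method)
  r <- rates(table)
  if (is.nan(r$P_h1_e1) || r$P_h1_e1 == 0)
    stop("rule has no positive examples: b'* undefined")
  if (method == "closed")
    return(r$P_e1_h0 / r$P_e1_h1)
  grid <- seq(0, 1, by = grid_step)
  obj <- bprime_objective(grid, table)
  obj[!is.finite(obj)] <- -Inf
  i <- which.max(obj)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  if (lo < hi) {
    opt <- stats::optimize(function(b) bprime_objective(b, table),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    if (opt$objective >= obj[i]) return(opt$maximum)
  }
  grid[i]
}

#' Optimized (tabular) truth function of a label
#'
#' Truth values proportional to the label's transition probabilities,
#' scaled so the maximum is 1: `T*(theta_j | h) = P(e_j|h) / max_h P(e_j|h)`.
#' For the medical test with `label = "e1"` and a confirmed rule this is the
#' mixture (1 on h1, b'* on h0).
#'
#' @param table a [contingency_table()] or [test_profile()].
#' @param label `"e1"` or `"e0"`.
#' @return a tabular [truth_function()] over outcomes `(h1, h0)`.
#' @export
optimize_truth_function <- function(table, label = c("e1", "e0")) {
  label <- match.arg(label)
  r <- rates(table)
  col <- if (label == "e1") c(h1 = r$P_e1_h1, h0 = r$P_e1_h0)
         else c(h1 = r$P_e0_h1, h0 = r$P_e0_h0)
  m <- max(col)
  if (!is.finite(m) || m <= 0) stop("all-zero transition column")
  truth_function("tabular", values = col / m)
}

# Mutual information (bits) of the 2x2 joint implied by a labeling ----------

# p_x: P(x); post: P(h1|x); lab: logical, TRUE -> e1
labeling_channel <- function(p_x, post, lab) {
  p_h1 <- sum(p_x * post)
  p_xh1 <- p_x * post          # joint P(x, h1)
  p_xh0 <- p_x * (1 - post)
  # channel P(e|h): columns e0, e1; rows h0, h1
  matrix(c(sum(p_xh0[!lab]) / (1 - p_h1), sum(p_xh0[lab]) / (1 - p_h1),
           sum(p_xh1[!lab]) / p_h1,       sum(p_xh1[lab]) / p_h1),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("h0", "h1"), c("e0", "e1")))
}

labeling_mi <- function(p_x, post, lab) {
  p_h <- c(h0 = 1 - sum(p_x * post), h1 = sum(p_x * post))
  ch <- labeling_channel(p_x, post, lab)
  p_e <- c(e0 = sum(p_x[!lab]), e1 = sum(p_x[lab]))
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    pj <- p_h[i] * ch[i, j]
    if (pj > 0) mi <- mi + pj * log2(pj / (p_h[i] * p_e[j]))
  }
  mi
}

#' One classification step from label information values
#'
#' Assigns each feature value the label with the larger expected
#' information `P(h0|x) I(h0; theta_ej) + P(h1|x) I(h1; theta_ej)`; ties go
#' to `e1`.
#'
#' @param post vector of posteriors P(h1|x) per feature value.
#' @param info 2x2 matrix of information values, rows `h0`, `h1`, columns
#'   `e0`, `e1` (bits).
#' @return a logical vector, `TRUE` where the label is `e1`.
#' @export
classify <- function(post, info) {
  score_e1 <- (1 - post) * info["h0", "e1"] + post * info["h1", "e1"]
  score_e0 <- (1 - post) * info["h0", "e0"] + post * info["h1", "e0"]
  score_e1 >= score_e0
}

# One alternation run from a given initial labeling.
mmi_run <- function(p_x, post, lab, max_iter) {
  seen <- character(0)
  traj <- numeric(0)
  converged <- FALSE; cycled <- FALSE
  for (it in seq_len(max_iter)) {
    traj <- c(traj, labeling_mi(p_x, post, lab))
    p_e1 <- sum(p_x[lab])
    info <- matrix(0, 2, 2, dimnames = list(c("h0", "h1"), c("e0", "e1")))
    if (p_e1 > 0 && p_e1 < 1) {
      ch <- labeling_channel(p_x, post, lab)
      p_e <- c(e0 = 1 - p_e1, e1 = p_e1)
      for (i in c("h0", "h1")) for (j in c("e0", "e1")) {
        info[i, j] <- if (ch[i, j] > 0) log2(ch[i, j] / p_e[j]) else -Inf
      }
    }
    new_lab <- classify(post, info)
    if (identical(new_lab, lab)) { converged <- TRUE; break }
    key <- paste(as.integer(new_lab), collapse = "")
    if (key %in% seen) { cycled <- TRUE; lab <- new_lab; break }
    seen <- c(seen, key)
    lab <- new_lab
  }
  list(labels = lab, mi = labeling_mi(p_x, post, lab), trajectory = traj,
       converged = converged, cycled = cycled)
}

#' Maximum-mutual-information classifier
#'
#' Alternates two steps until the labeling is stable (or `max_iter` is
#' reached): (1) from the current labeling, re-estimate the label channel
#' `P(e|h)` and the optimized information values
#' `I(h_i; theta_ej) = log2(P(e_j|h_i)/P(e_j))`; (2) re-assign every feature
#' value to the label maximizing its expected information ([classify()]).
#'
#' Because the assignment score is linear in the posterior `P(h1|x)`, every
#' labeling the alternation produces is a threshold rule in the posterior
#' -- and for a binary label set the mutual-information-optimal
#' deterministic labeling is itself a posterior-threshold rule. The
#' alternation is therefore started from every posterior-threshold labeling
#' (at most `|X| + 1` starts, including the degenerate ones) and the best
#' fixed point is returned; since an iteration never decreases mutual
#' information, the sweep attains the maximum over all `2^|X|` labelings.
#' An empty label gets zero information (the tautology convention), so it
#' can be repopulated. Cycling (guarded, not observed with the stability
#' stop) is reported.
#'
#' @param p_x probability vector P(x) over a finite feature alphabet.
#' @param post posteriors P(h1|x), same length.
#' @param max_iter iteration cap per start.
#' @return a list with `labels` (logical, `TRUE` = e1), `channel` (P(e|h)),
#'   `mi` (mutual information in bits), `trajectory` (MI per iteration of
#'   the best run), `iterations`, `converged`, `cycled`, `starts`.
#' @export
mmi_classifier <- function(p_x, post, max_iter = 100) {
  if (length(p_x) == 0) stop("empty feature alphabet")
  if (abs(sum(p_x) - 1) > 1e-9) stop("p_x must sum to 1")
  if (any(post < 0 | post > 1)) stop("posteriors must lie in [0, 1]")
  ord <- order(post, decreasing = TRUE)
  k <- length(p_x)
  best <- NULL
  n_starts <- 0L
  for (cut in 0:k) {
    lab <- rep(FALSE, k)
    if (cut > 0) lab[ord[seq_len(cut)]] <- TRUE
    n_starts <- n_starts + 1L
    run <- mmi_run(p_x, post, lab, max_iter)
    if (is.null(best) || run$mi > best$mi + 1e-15) best <- run
  }
  p_e1_final <- sum(p_x[best$labels])
  list(labels = best$labels,
       channel = if (p_e1_final <= 0 || p_e1_final >= 1 - 1e-12) NULL
                 else labeling_channel(p_x, post, best$labels),
       mi = best$mi,
       trajectory = best$trajectory,
       iterations = length(best$trajectory),
       converged = best$converged,
       cycled = best$cycled,
       starts = n_starts)
}

#' Exhaustive-search maximum mutual information over labelings
#'
#' Brute-force oracle for small alphabets: evaluates all `2^|X|` labelings
#' and returns the maximum mutual information.
#'
#' @inheritParams mmi_classifier
#' @return a list with `mi` and the maximizing `labels`.
#' @export
exhaustive_mmi <- function(p_x, post) {
  k <- length(p_x)
  if (k > 16) stop("alphabet too large for exhaustive search")
  best <- -Inf; best_lab <- rep(FALSE, k)
  for (m in 0:(2^k - 1)) {
    lab <- as.logical(bitwAnd(m, 2^(0:(k - 1))) > 0)
    mi <- labeling_mi(p_x, post, lab)
    if (mi > best) { best <- mi; best_lab <- lab }
  }
  list(mi = best, labels = best_lab)
}
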