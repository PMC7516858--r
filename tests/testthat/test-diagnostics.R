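nat <- test_profile(0.5, 0.95, prior = 0.25, label = "NAT")
ct <- test_profile(0.8, 0.75, prior = 0.25, label = "CT")

test_that("evaluate_test scores both rules of each test result", {
  ev <- evaluate_test(nat, measures = "b*")
  expect_equal(ev$positive, 0.9, tolerance = 1e-12)
  expect_printed(ev$negative, 0.47)
  ev_ct <- evaluate_test(ct, measures = "b*")
  expect_printed(ev_ct$positive, 0.69)
  expect_printed(ev_ct$negative, 0.73)
  # a perfect test is fully confirmed in both directions
  perfect <- test_profile(1, 1, prior = 0.3)
  for (m in c("b*", "c*", "F")) {
    ev_p <- evaluate_test(perfect, measures = m)
    expect_equal(ev_p$positive, 1, label = paste(m, "positive"))
    expect_equal(ev_p$negative, 1, label = paste(m, "negative"))
  }
})

test_that("the full assessment grid matches the reference within 0.01", {
  wx <- worked_examples()
  rounded <- reproduce("assessment_grid")
  expect_equal(dimnames(rounded), dimnames(wx$assessment_grid))
  # compare unrounded values so cells printed one rounding step away
  # (e.g. 0.3548 printed as 0.36) are judged at the stated tolerance
  got <- assessment_values(wx$test_profiles)
  expect_true(all(abs(got - wx$assessment_grid) <= 0.01))
})

test_that("the b* decision grid reproduces the improved two-test diagnosis", {
  res <- two_test_decision(nat, ct, "b*")
  wx <- worked_examples()
  expect_equal(res$decision, wx$decision_grid)
  # the discordant (A-negative, B-positive) cell is the changed one
  expect_equal(res$decision["negative", "positive"], "positive")
})

test_that("measures disagree with the improved diagnosis as documented", {
  wx <- worked_examples()
  consistent <- c("D", "M", "F", "b*")
  inconsistent <- c("Z", "S", "C", "N", "c*")
  for (m in consistent) {
    expect_equal(two_test_decision(nat, ct, m)$decision, wx$decision_grid,
                 label = paste("decision grid under", m))
  }
  for (m in inconsistent) {
    expect_false(identical(two_test_decision(nat, ct, m)$decision,
                           wx$decision_grid),
                 label = paste("decision grid under", m))
  }
  # c* flips the changed cell back to negative: correctness is not what
  # a screening decision needs
  expect_equal(two_test_decision(nat, ct, "c*")$decision["negative",
                                                         "positive"],
               "negative")
})

test_that("a belief threshold suppresses unbelievable results", {
  # with an extreme threshold nothing is believable: discordant cells are
  # undecided, concordant cells pass through
  res <- two_test_decision(nat, ct, "b*", threshold = 0.95)
  expect_equal(res$decision["negative", "positive"], "undecided")
  expect_equal(res$decision["positive", "positive"], "positive")
  # with threshold 0.2 and measure b* all four degrees are believable and
  # the plain comparison is recovered
  expect_equal(two_test_decision(nat, ct, "b*", threshold = 0.2)$decision,
               two_test_decision(nat, ct, "b*")$decision)
  # ties are reported, not silently resolved: a test with equal sensitivity
  # and specificity confirms its positive and negative results equally
  same <- test_profile(0.8, 0.8, prior = 0.25)
  res_tie <- two_test_decision(same, same, "b*")
  expect_equal(res_tie$decision["negative", "positive"], "undecided")
})

test_that("simulated estimates converge to the closed-form b*", {
  est <- function(n, seed) b_star(simulate_sample(nat, n, seed))$value
  err3 <- abs(est(1e3, 101) - 0.9)
  err5 <- abs(est(1e5, 101) - 0.9)
  expect_lt(err3, 0.1)
  expect_lt(err5, 0.02)
})

test_that("bundled fixtures reproduce their expected measure grids", {
  wx <- worked_examples()
  fx <- wx$extreme_examples
  got <- reproduce("extreme_examples")
  err <- vapply(fx$errata, paste, character(1), collapse = ":")
  for (i in seq_len(nrow(got))) {
    ex <- rownames(fx$expected)[i]
    for (m in fx$measures) {
      if (paste(ex, m, sep = ":") %in% err) next
      expect_printed(got[[m]][i], fx$expected[ex, m],
                     label = paste(ex, m))
    }
  }
  # the flagged cells really disagree with their printed values
  expect_gt(abs(got[["c*"]][1] - fx$expected["ex1", "c*"]), 0.05)
  expect_gt(abs(got[["N"]][1 + 2] - fx$expected["ex3", "N"]), 0.05)
})

test_that("the prevalence sweep reproduces only the consistent cell", {
  wx <- worked_examples()$prevalence_sweep
  got <- reproduce("prevalence_sweep")
  ok <- !wx$errata
  expect_printed(got$posterior[ok], wx$printed_posterior[ok])
  # the two flagged cells are not reproducible from b* = 0.9
  expect_false(all(abs(got$posterior[!ok] -
                       wx$printed_posterior[!ok]) <= 0.05))
})
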