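test_that("truth function families evaluate into [0,1] with stated shapes", {
  g <- truth_function("gaussian", center = 20, sigma = sqrt(12.5))
  expect_equal(truth_values(g, 20), 1)
  expect_true(all(truth_values(g, seq(0, 100, 5)) <= 1))
  lg <- truth_function("logistic", k = 0.2, x0 = 65)
  v <- truth_values(lg, c(40, 65, 90))
  expect_equal(v[2], 0.5)
  expect_true(all(diff(v) > 0))  # monotone
  mx <- truth_function("mixture", believable = c(h0 = 0, h1 = 1),
                       bprime = 0.1)
  expect_equal(truth_values(mx), c(h0 = 0.1, h1 = 1))
  expect_error(truth_function("mixture", believable = c(0.3, 1),
                              bprime = 0.1), "indicator")
  expect_error(truth_function("tabular", values = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("logical probability is the prior-weighted truth average", {
  prior <- c(h0 = 0.75, h1 = 0.25)
  expect_equal(logical_probability(prior, c(1, 1)), 1)        # tautology
  expect_equal(logical_probability(prior, c(h0 = 0.1, h1 = 1)), 0.325)
  expect_equal(logical_probability(prior, c(h0 = 0, h1 = 1)), 0.25)
})

test_that("semantic information is the log truth-to-logical-probability ratio", {
  prior <- c(h0 = 0.75, h1 = 0.25)
  tv <- c(h0 = 0.1, h1 = 1)
  expect_equal(semantic_information("h1", tv, prior), log2(1 / 0.325),
               tolerance = 1e-12)
  expect_equal(semantic_information("h0", tv, prior), log2(0.1 / 0.325),
               tolerance = 1e-12)
  # constant truth conveys no information
  expect_equal(semantic_information("h1", c(h0 = 0.4, h1 = 0.4), prior), 0)
  # zero truth value: negative-infinite marker
  expect_identical(semantic_information("h0", c(h0 = 0, h1 = 1), prior),
                   -Inf)
})

test_that("average semantic information reduces to KL divergence when matched", {
  prior <- c(h0 = 0.8, h1 = 0.2)
  sampling <- c(h0 = 8 / 28, h1 = 20 / 28)
  # truth proportional to sampling/prior maximizes and equals KL divergence
  ratio <- sampling / prior
  tv <- ratio / max(ratio)
  got <- avg_semantic_information(sampling, tv, prior)
  kl <- sum(sampling * log2(sampling / prior))
  expect_equal(got, kl, tolerance = 1e-12)
  # tautology conveys zero on average
  expect_equal(avg_semantic_information(sampling, c(1, 1), prior), 0)
})

test_that("the average information times N1 matches the log-likelihood", {
  for (tab in property_tables(50)) {
    r <- rates(tab)
    n1 <- tab$a + tab$c
    prior <- c(h0 = 1 - r$P_h1, h1 = r$P_h1)
    sampling <- c(h0 = r$P_h0_e1, h1 = r$P_h1_e1)
    for (bp in c(0.05, 0.3, 0.9)) {
      tv <- c(h0 = bp, h1 = 1)
      info <- avg_semantic_information(sampling, tv, prior)
      post <- semantic_bayes(prior, tv)
      loglik <- tab$a * log2(post[["h1"]]) + tab$c * log2(post[["h0"]])
      expect_equal(n1 * (info + sum(sampling * log2(prior))), loglik,
                   tolerance = 1e-9)
    }
  }
})

test_that("optimize_bprime closed form equals 1/LR+ and the numeric argmax", {
  nat <- test_profile(0.5, 0.95, 0.25)
  expect_equal(optimize_bprime(nat), 0.1, tolerance = 1e-12)
  tab <- contingency_table(20, 180, 8, 792)
  expect_equal(optimize_bprime(tab), (8 / 800) / (20 / 200),
               tolerance = 1e-12)
  expect_equal(optimize_bprime(tab, "numeric"), 0.1, tolerance = 1e-6)
  # no counterexamples: fully believable
  expect_equal(optimize_bprime(contingency_table(5, 5, 0, 5)), 0)
  expect_error(optimize_bprime(contingency_table(0, 5, 5, 5)),
               "positive examples")
})

test_that("no grid point beats the closed-form maximizer of the objective", {
  for (tab in property_tables(30)) {
    closed <- min(optimize_bprime(tab), 1)
    grid <- seq(1e-4, 1, by = 1e-3)
    obj <- bprime_objective(grid, tab)
    best <- bprime_objective(closed, tab)
    expect_true(all(obj <= best + 1e-12))
  }
})

test_that("optimized truth functions are max-scaled transition columns", {
  nat <- test_profile(0.5, 0.95, 0.25)
  tf <- optimize_truth_function(nat, "e1")
  expect_equal(truth_values(tf), c(h1 = 1, h0 = 0.1))
  tf2 <- optimize_truth_function(contingency_table(200, 0, 720, 80), "e1")
  expect_equal(truth_values(tf2), c(h1 = 1, h0 = 0.9))
  # uniform channel: all truth values 1
  tf3 <- optimize_truth_function(contingency_table(1, 1, 1, 1), "e0")
  expect_equal(unname(truth_values(tf3)), c(1, 1))
  # b* = 1 - b'* links the truth function to the channel measure
  for (tab in property_tables(30)) {
    bp <- optimize_bprime(tab)
    if (bp <= 1)
      expect_equal(b_star(tab)$value, 1 - bp, tolerance = 1e-12)
  }
})

test_that("truth functions round-trip through their JSON schema", {
  f <- tempfile(fileext = ".json")
  writeLines('{"family": "mixture",
               "params": {"believable": [0, 1], "bprime": 0.25}}', f)
  tf <- read_truth_function(f)
  expect_equal(truth_values(tf), c(0.25, 1))
})

test_that("the classifier assigns labels by expected information", {
  # all x carry positive information about h1: everything labeled e1
  info <- matrix(c(0, -1, 0, 1), 2, 2,
                 dimnames = list(c("h0", "h1"), c("e0", "e1")))
  expect_true(all(classify(c(0.9, 0.8), info)))
  # two-symbol alphabet with opposite posteriors splits cleanly
  res <- mmi_classifier(p_x = c(0.5, 0.5), post = c(0.9, 0.1))
  expect_equal(res$labels, c(TRUE, FALSE))
  expect_true(res$converged)
  expect_equal(res$mi, exhaustive_mmi(c(0.5, 0.5), c(0.9, 0.1))$mi,
               tolerance = 1e-12)
})

test_that("the fixed point attains the exhaustive maximum on small alphabets", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    p_x <- as.vector(stats::rmultinom(1, 60, rep(1, k))) + 1
    p_x <- p_x / sum(p_x)
    post <- stats::runif(k)
    res <- mmi_classifier(p_x, post)
    oracle <- exhaustive_mmi(p_x, post)
    expect_equal(res$mi, oracle$mi, tolerance = 1e-9)
    # mutual information never decreases along the trajectory
    expect_true(all(diff(res$trajectory) >= -1e-12))
  }
})
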