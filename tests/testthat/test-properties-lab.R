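test_that("Consequent Symmetry (HS) holds for the star measures and F", {
  tabs <- property_tables(300)
  for (m in c("F", "Z", "b*", "c*", "cF*")) {
    res <- check_symmetry(m, "HS", tabs)
    expect_true(res$holds, label = paste("HS for", m))
  }
})

test_that("Antecedent and Commutativity symmetries fail with witnesses", {
  tabs <- property_tables(300)
  for (m in c("F", "b*")) {
    for (kind in c("ES", "CS")) {
      res <- check_symmetry(m, kind, tabs)
      expect_false(res$holds, label = paste(kind, "for", m))
      expect_s3_class(res$witness, "contingency_table")
    }
  }
  # the documented CS counterexample: F(e1->h1) != F(h1->e1) when b != c
  tab <- contingency_table(20, 180, 8, 792)
  expect_printed(measure_value("F", tab, "e1->h1"), 0.818)
  expect_false(isTRUE(all.equal(measure_value("F", tab, "e1->h1"),
                                measure_value("F", tab, "h1->e1"))))
})

test_that("Total Symmetry holds on fully exchange-symmetric tables", {
  tabs <- list(contingency_table(20, 10, 10, 20),
               contingency_table(7, 3, 3, 7))
  for (m in c("F", "b*", "c*")) {
    expect_true(check_symmetry(m, "TS", tabs)$holds)
  }
})

test_that("count monotonicity separates the measure families", {
  for (m in c("L", "F", "Z", "b*")) {
    expect_true(check_monotonicity(m, grid = 1:6)$holds,
                label = paste("monotonicity of", m))
  }
  for (m in c("D", "M")) {
    res <- check_monotonicity(m, grid = 1:6)
    expect_false(res$holds, label = paste("monotonicity of", m))
    expect_s3_class(res$witness, "contingency_table")
    # the witness really is a violation
    w <- res$witness
    v0 <- measure_value(m, w)
    w2 <- as.list(w)[c("a", "b", "c", "d")]
    w2[[res$direction]] <- w2[[res$direction]] + 1
    v1 <- measure_value(m, do.call(contingency_table, w2))
    sgn <- if (res$direction %in% c("a", "d")) 1 else -1
    expect_lt(sgn * (v1 - v0), 0)
  }
  # c* ignores d entirely, so it is (weakly) monotone in d
  expect_true(check_monotonicity("c*", grid = 1:6)$holds)
})

test_that("the increment experiment reproduces the reference base table", {
  wx <- worked_examples()$raven_base
  got <- raven_experiment(wx$base, measures = wx$measures)
  err <- vapply(wx$errata, paste, character(1), collapse = ":")
  for (i in seq_len(nrow(got))) {
    m <- got$measure[i]
    for (col in c("base", "delta_a", "delta_d")) {
      if (paste(m, col, sep = ":") %in% err) next
      expect_printed(got[[col]][i], wx$expected[m, col],
                     label = paste(m, col))
    }
  }
  # only c* satisfies the Nicod-Fisher criterion here
  expect_equal(got$measure[got$nicod_fisher], "c*")
  # a black raven helps c* more than a piece of chalk; the reverse for F
  expect_gt(got$diff[got$measure == "c*"], 0)
  expect_lt(got$diff[got$measure == "F"], 0)
})

test_that("increments shrink when the base sample is ten times larger", {
  small <- raven_experiment(contingency_table(20, 10, 10, 20),
                            measures = c("D", "c*"))
  big <- raven_experiment(contingency_table(200, 100, 100, 200),
                          measures = c("D", "c*"))
  # reference figures: D 0.1667 -> 0.1669, c* 0.5 -> 0.5025 under a+1
  expect_printed(big$base[big$measure == "D"], 0.1667)
  expect_printed(big$delta_a[big$measure == "D"], 0.1669)
  expect_printed(big$delta_a[big$measure == "c*"], 0.5025)
  for (m in c("D", "c*")) {
    expect_lt(abs(big$delta_a[big$measure == m] - big$base[big$measure == m]),
              abs(small$delta_a[small$measure == m] -
                  small$base[small$measure == m]))
  }
})

test_that("logicality and normalization flags separate the measures", {
  tabs <- property_tables(100)
  for (m in c("F", "Z", "b*", "c*")) {
    res <- check_logicality_normalization(m, tabs)
    expect_true(res$logicality, label = paste("logicality of", m))
    expect_true(res$normalization, label = paste("normalization of", m))
  }
  # L blows up to +Inf without counterexamples: fails both
  resL <- check_logicality_normalization("L", tabs)
  expect_false(resL$logicality)
  expect_false(resL$normalization)
  # D never reaches +-1 on generic tables: fails logicality
  expect_false(check_logicality_normalization("D", tabs)$logicality)
})

test_that("the desiderata report matches the published classification", {
  rep <- desiderata_report(measures = c("D", "F", "Z", "b*", "c*"),
                           tables = property_tables(100), grid = 1:5)
  expect_true(all(rep$HS))
  expect_false(any(rep[rep$measure %in% c("F", "b*"), "CS"]))
  expect_false(rep[rep$measure == "D", "monotone"])
  expect_true(all(rep[rep$measure %in% c("F", "Z", "b*", "c*"),
                      "logicality"]))
})
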