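# Printed-precision comparison: reference values are transcribed at mixed
# precision (1-3 decimals), so each cell is compared at the tolerance its
# own number of printed decimals implies.

printed_decimals <- function(x) {
  s <- format(x, drop0trailing = TRUE, scientific = FALSE, trim = TRUE)
  ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
}

printed_tolerance <- function(x) {
  dec <- printed_decimals(x)
  # 3+ decimals: 0.001; 2: 0.005; 1: 0.05; integers: 0.5
  c(0.5, 0.05, 0.005, 0.001)[pmin(dec, 3L) + 1L]
}

expect_printed <- function(computed, printed, label = NULL) {
  tol <- printed_tolerance(printed)
  ok <- abs(computed - printed) <= tol
  expect(isTRUE(all(ok)),
         sprintf("%s: computed %s differs from printed %s beyond +-%s",
                 if (is.null(label)) "value" else label,
                 paste(signif(computed[!ok], 6), collapse = ", "),
                 paste(printed[!ok], collapse = ", "),
                 paste(tol[!ok], collapse = ", ")))
}

# small deterministic battery shared by property tests
property_tables <- function(n = 200, seed = 42) random_tables(n, seed = seed)

# unrounded NAT/CT assessment grid in the reference layout
assessment_values <- function(profiles) {
  nat <- evaluate_test(profiles$NAT)
  ct <- evaluate_test(profiles$CT)
  rbind("NAT-" = stats::setNames(nat$negative, nat$measure),
        "NAT+" = stats::setNames(nat$positive, nat$measure),
        "CT-" = stats::setNames(ct$negative, ct$measure),
        "CT+" = stats::setNames(ct$positive, ct$measure))
}
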