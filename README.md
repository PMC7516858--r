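# confirmr

Confirmation measures for 2x2 evidence, diagnostic test evaluation, and the
raven paradox.

## What it is for

An uncertain rule "if e then h" — a positive test result predicting an
infection, or "ravens are black" — is supported or undermined by a sample
of four example types, counted in a 2x2 contingency table (`a` positive
examples (e1, h1), `b` (e0, h1), `c` counterexamples (e1, h0), `d`
(e0, h0)). A confirmation measure scores that support on a [-1, 1] scale.
`confirmr` is for statisticians and methodologists who need those scores
computed correctly and compared honestly: it implements the classical
measures

```
D = P(h1|e1) - P(h1)                    M = P(e1|h1) - P(e1)
R = log2 P(h1|e1)/P(h1)                 C = P(h1,e1) - P(e1)P(h1)
S = P(h1|e1) - P(h1|e0)                 N = P(e1|h1) - P(e1|h0)
L = log2 LR                             F = (LR - 1)/(LR + 1)
Z = [P(h1|e1) - P(h1)]/P(h0)  (confirmation branch)
```

with LR = P(e1|h1)/P(e1|h0), plus two measures derived from semantic
information theory by maximum likelihood:

* **channel confirmation** `b* = (LR - 1)/max(LR, 1)` — a normalization of
  the likelihood ratio; it scores the *testing means* and is independent
  of prevalence;
* **prediction confirmation** `c* = (a - c)/max(a, c)` — a transform of
  the correct rate P(h1|e1); it scores the *probability prediction* and
  satisfies the Nicod–Fisher criterion (only positive examples and
  counterexamples move it).

Around the measures sit: probability prediction from degrees of
confirmation (`predict_from_b`, `predict_from_c`), truth functions and
semantic Bayes machinery (`semantic_bayes`, `optimize_bprime`), a
maximum-mutual-information classifier (`mmi_classifier`), a two-test
diagnosis engine (`evaluate_test`, `two_test_decision`), and a property
lab (`check_symmetry`, `check_monotonicity`, `raven_experiment`,
`desiderata_report`) that verifies symmetry, monotonicity, normalization,
logicality and Nicod–Fisher desiderata with witnesses on failure.

## Worked example: which discordant test result should you believe?

A nucleic-acid test (NAT) for a viral infection has sensitivity 0.5 and
specificity 0.95; a CT scan has sensitivity 0.8 and specificity 0.75; the
prior prevalence is 0.25.

```r
library(confirmr)
nat <- test_profile(0.5, 0.95, prior = 0.25, label = "NAT")
ct  <- test_profile(0.8, 0.75, prior = 0.25, label = "CT")

evaluate_test(nat, measures = c("F", "b*", "c*"), digits = 2)
#>   measure positive negative
#> 1       F     0.82     0.31
#> 2      b*     0.90     0.47
#> 3      c*     0.70     0.82
```

Despite its poor sensitivity, NAT-positive is an excellent channel
(`b* = 0.90`): almost no uninfected specimen tests positive. NAT-negative
is much weaker (`b* = 0.47`). Resolving discordant results by the larger
degree of confirmation:

```r
two_test_decision(nat, ct, "b*")$decision
#>           B
#> A          negative   positive
#>   negative "negative" "positive"
#>   positive "positive" "positive"
```

The NAT-negative/CT-positive cell is diagnosed **positive** because
`b*(CT+) = 0.69` beats `b*(NAT-) = 0.47` — the behavior clinicians
adopted. A prevalence-aware prediction from the same degree:

```r
predict_from_b(0.25, b_star(nat)$value)
#> P(h1|theta) = 0.7692308, P(h0|theta) = 0.2307692
```

And the raven-paradox experiment — does one extra black raven (`a + 1`)
confirm "ravens are black" more than one extra piece of white chalk
(`d + 1`)?

```r
raven_experiment(contingency_table(20, 10, 10, 20),
                 measures = c("F", "c*"), digits = 3)
#>   measure  base delta_a delta_d   diff nicod_fisher
#> 1       F 0.333   0.340   0.348 -0.008        FALSE
#> 2      c* 0.500   0.524   0.500  0.024         TRUE
```

For F the chalk wins (`diff < 0`); only the prediction measure `c*`
responds to the raven alone, which is what dissolves the paradox.

A thin command-line wrapper over the same functions is installed at
`inst/cli/confirmr` (subcommands `measures`, `predict`, `diagnose`,
`raven`, `desiderata`, `simulate`, `reproduce`).

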