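---
title: "Channel and prediction confirmation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel and prediction confirmation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confirmr)
```

## The problem

An uncertain rule "if e then h" -- a diagnostic test result predicting an
infection, or "ravens are black" -- cannot be verified or falsified by a
single case. Its evidence is a sample of four example types, counted in a
2x2 table: `a` positive examples (e1, h1), `b` examples (e0, h1), `c`
counterexamples (e1, h0) and `d` examples (e0, h0). A *confirmation
measure* is a function f(a, b, c, d), usually in [-1, 1], scoring how
strongly the sample supports the rule.

`confirmr` implements the classical measures

* D = P(h1|e1) - P(h1), M = P(e1|h1) - P(e1), R = log2 P(h1|e1)/P(h1),
  C = P(h1, e1) - P(e1)P(h1), S = P(h1|e1) - P(h1|e0),
  N = P(e1|h1) - P(e1|h0), L = log2 P(e1|h1)/P(e1|h0),
  F = [P(e1|h1) - P(e1|h0)] / [P(e1|h1) + P(e1|h0)],
  and the piecewise-normalized Z,

together with two measures derived from semantic information theory:

* the **channel confirmation measure** `b* = (LR - 1)/max(LR, 1)`, a
  normalization of the likelihood ratio LR = P(e1|h1)/P(e1|h0), which
  scores the *testing means* (the channel); and
* the **prediction confirmation measure** `c* = (a - c)/max(a, c)`, a
  transform of the correct rate P(h1|e1), which scores the *probability
  prediction* the rule makes.

The central claim the package operationalizes is that these are two
different jobs: a test with sensitivity 0.5 and specificity 0.95 is an
excellent channel (`b* = 0.9`) even when, at low prevalence, its positive
prediction is usually wrong (`c* < 0`).

## Where b* and c* come from

A prediction e1(h) is modeled as a mixture of a crisp believable part and a
tautology with proportion b': the truth function is T(theta_e1|h1) = 1,
T(theta_e1|h0) = b'. Its logical probability under a prior P(h) is
T(theta_e1) = P(h1) + b' P(h0), and the semantic Bayes rule
posterior_i = prior_i truth_i / T(theta) turns the truth function into a
likelihood. The average semantic information conveyed by e1 about h,

I(h; theta_e1) = P(h0|e1) log2[ b' / T(theta_e1) ]
               + P(h1|e1) log2[ 1 / T(theta_e1) ],

is (up to a constant in b') the per-example log-likelihood, so maximizing
it over b' is maximum likelihood. The interior stationary point is the
closed form b'* = P(e1|h0)/P(e1|h1) = 1/LR (`optimize_bprime()`), and
b* = 1 - b'* when the rule is confirmed. When LR < 1 the stationary point
falls outside [0, 1]; the objective is then increasing on the whole unit
interval and the constrained numeric maximizer sits at the boundary 1
(the tautology), which is why the numeric mode of `optimize_bprime()` is
compared with `min(closed form, 1)`. In that regime the mixture is
re-anchored on h0 via Consequent Symmetry, giving the negative branch
b* = b'* - 1.

c* is derived the same way one level later: the *prediction*
P(h|theta_e1) is split into a believable part and an unbelievable part
with proportion c'; matching the prediction to the sample posterior gives
c'* = min(P(h0|e1)/P(h1|e1), its reciprocal) and
c* = (P(h1|e1) - P(h0|e1))/max(...) = (a - c)/max(a, c). Replacing max
with + in either shape gives the difference-over-sum variants: the channel
one is exactly measure F, the prediction one is cF* = (a - c)/(a + c).

All sixteen directional forms (four antecedent/consequent combinations,
each with a negated-consequent mirror) reduce to two conditional pairs:
the channel pair (P(ant|cons), P(ant|not-cons)) and the prediction pair
(P(cons|ant), P(not-cons|ant)). The implementation computes every form
from these pairs, so Consequent Symmetry -- m(e -> not-h) = -m(e -> h) --
holds structurally rather than by case analysis; the published count
identities (e.g. F(e1->h1) = (ad - bc)/(ad + bc + 2ac)) are kept as
cross-checks in the test suite.

## Probability predictions from degrees of confirmation

Degrees of confirmation are not just scores; they transport:

* `predict_from_b(prior, b*)` gives P(h1|theta) = prior / (1 - b*(1 -
  prior)) for b* >= 0 (and the mirrored formula for b* < 0). Because b*
  is prior-free, this is the right tool when prevalence changes: the same
  b* = 0.9 yields P(h1|theta) = 0.77 at prior 0.25 and much less at low
  priors.
* `predict_from_c(c*)` inverts the correct-rate transform, CR = 1/(2 -
  c*); `predict_from_cf(cf)` is the linear map (1 + cF*)/2.

On the table the degrees were fitted to, both routes reproduce P(h1|e1)
exactly (a property the tests assert at 1e-12); their value is in carrying
a fitted degree to new priors or communicating it on a [-1, 1] scale.

## The two-test decision engine

For two tests evaluated at a shared prior (`evaluate_test()`,
`two_test_decision()`), concordant results pass through and a discordant
pair is resolved for the result whose supporting rule has the strictly
larger degree of confirmation. With the NAT profile (sensitivity 0.5,
specificity 0.95) and the CT profile (0.8, 0.75) at prior 0.25, measure
b* gives b*(CT+) = 0.69 > b*(NAT-) = 0.47, so NAT-negative/CT-positive is
diagnosed positive -- the clinically adopted behavior. Measures that track
correctness rather than the channel (c*, Z, S, C, N) flip at least one
discordant cell. An optional belief threshold treats degrees at or below
the threshold as unbelievable; it defaults to off, since the plain
comparison is the primary rule and the threshold is a refinement used to
discriminate between otherwise-consistent measures.

## The property lab and the raven paradox

`check_symmetry()`, `check_monotonicity()`,
`check_logicality_normalization()` and `desiderata_report()` verify the
screening desiderata empirically -- symmetries on seeded random tables
(witnesses returned on failure), monotonicity exhaustively over unit
increments on a count grid. The published classification is reproduced
with one exception worth stating plainly: N = P(e1|h1) - P(e1|h0) *is*
count-monotone (all four partial derivatives carry the required signs:
dN/da = b/(a+b)^2 >= 0, dN/dd = c/(c+d)^2 >= 0, and the b, c derivatives
are non-positive), so no grid counterexample exists and the lab correctly
reports it monotone, although it is often grouped with D and M as
non-monotone.

`raven_experiment()` asks the raven-paradox question numerically: starting
from a = d = 20, b = c = 10, does one extra black raven (a + 1) raise a
measure more than one extra piece of white chalk (d + 1)? For every
classical measure the chalk does at least as well; only c*, which ignores
b and d entirely, is moved by the raven alone -- it satisfies the
Nicod-Fisher criterion (a + 1 raises it, c + 1 lowers it, b + 1 and d + 1
leave it unchanged) and so dissolves the paradox by denying the
Equivalence Condition. The lab also checks the sample-size effect: from a
ten-times larger base table the same unit increments move every measure
about ten times less, which is why the package treats confirmation as
absolute (computed from all counts) rather than incremental.

## The maximum-mutual-information classifier

`mmi_classifier()` labels a finite feature alphabet by alternating (1)
channel re-estimation with optimized information values
I(h_i; theta_ej) = log2 P(ej|h_i)/P(ej) and (2) re-assignment of each x to
the label with the larger expected information, ties to e1. Two choices
are ours because no stopping or starting rule is prescribed: iteration
stops when the labeling is stable (cap 100, cycling guarded and
reported), and the alternation is started from every posterior-threshold
labeling. The second choice matters: the assignment score is linear in
P(h1|x), so every iterate is a posterior-threshold rule, and the
MI-optimal deterministic binary labeling is itself a threshold rule; since
an iteration never decreases mutual information, the best fixed point over
the at most |X| + 1 threshold starts attains the global maximum over all
2^|X| labelings. A single-start version can stall in a local optimum (we
observed this in roughly one random setup in seven). Empty labels receive
zero information -- a tautology conveys nothing -- so they can be
repopulated. The test suite checks the fixed point against an exhaustive
2^|X| oracle on alphabets up to size 8.

## Numerical conventions and degenerate inputs

* All logarithms are base 2; information is in bits.
* Probabilities are plug-in count ratios; no smoothing anywhere. Counts
  may be non-integer reals so that profile-implied expected tables are
  exact; `round_counts()` rounds half-up when integers are wanted.
* A conditional with zero denominator is `NaN`, an explicit undefined
  marker that propagates to `defined = FALSE` -- not an exception -- so
  that logicality cases (c = 0 or a = 0) remain visible. A log of zero is
  `-Inf`, never clamped, which is what makes the normalization check fail
  for L and R as it should.
* 0/0 in a difference-over-max shape is undefined, not zero; max(x, y)
  with x = y may take either branch (the value is identical).
* Z's tie case (P(h1|e1) = P(h1)) uses the confirmation branch.
* Half-up rounding (`round_half_up()`) is used whenever values are
  reported at a reference precision, because banker's rounding would
  disagree with the printed tables on .5 boundaries.

## What the generators emulate -- and what they do not

`simulate_sample()` draws the four counts multinomially from the joint
distribution implied by a test profile (or an explicit joint), seeded and
restoring the caller's random state; `random_tables()` draws uniform
integer counts in 1..max_count for property sweeps, with zero-count edge
tables added explicitly where logicality is at stake. These emulate
sampling variation in honestly collected 2x2 evidence. They do not emulate
selection bias, dependent examples, or covariate structure (the two-test
engine deliberately assumes identical symptoms across patients), so
passing tests say nothing about those failure modes. Problem sizes used by
the test suite -- 10,000 random tables for symmetry sweeps, the {1..10}^4
grid for monotonicity, 1,000 tables for the optimizer equivalence, 100
random setups for the classifier oracle, one multinomial draw of n = 10^6
for estimator convergence -- were chosen as the smallest sizes at which
the properties are convincingly exercised.

## Known limitations

* Only 2x2 evidence; no stratified or k x k tables, and no confidence
  intervals for rates -- when samples are small the point degrees of
  confirmation are unreliable and an interval treatment would be needed.
* Continuous features enter the classifier only through a user-supplied
  discretization.
* The bundled reference grids carry erratum flags on four cells whose
  printed values contradict their own defining formulas (one c* cell and
  one N cell in the three-example grid, and the two S/N increment cells);
  `worked_examples()` documents them and the tests exclude exactly those
  cells rather than forcing agreement.
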