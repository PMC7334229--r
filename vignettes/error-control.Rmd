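---
title: "Controlling classifier error rates with per-class reject thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling classifier error rates with per-class reject thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejectr)
```

## The procedure

`rejectr` turns a two-outcome classifier (correct / wrong) into a
three-outcome one (correct / wrong / unsure) in three phases:

1. **Scoring.** A trained classifier — any model emitting a score vector
   summing to 1 — labels an evaluation dataset that is independent of its
   training data. Only the tabular output is needed: ground truth Y,
   predicted class C(X), top score S(X).
2. **Tuning.** For each class *i*, the per-class rates CCᵢ(τ), MCᵢ(τ),
   UCᵢ(τ) are computed over that class's ground-truth records as functions
   of a candidate threshold τ, and one threshold τᵢ is selected under a
   user goal.
3. **Application.** On new data, a prediction is kept when
   S(X) > τ of the **predicted** class, and rerouted to `UNSURE` otherwise.
   Ground truth plays no role in the decision.

The core assumption is exchangeability between the tuning set and the data
the thresholds are later applied to: the tuning-phase rates are empirical
estimates, and they transfer only insofar as the score distributions do.
Applying thresholds across acquisition conditions that shift the score
distribution voids the tuning-phase guarantee (the benchmark's `cross`
design exists to measure exactly this degradation under a common
generator).

Note the indexing asymmetry, which is easy to get wrong: tuning evaluates a
class's threshold on its *ground-truth* records (how many of class *i*'s
items survive), while application judges each record against its
*predicted* class's threshold (the only class known at decision time).
These are distinct operations in the package (`rates_at_threshold()` /
`rate_curve()` versus `application_rates()`), never mixed.

## Boundary and conservation conventions

Acceptance is strict: a prediction is kept only when S(X) > τ. The unsure
outcome is defined as the complement, S(X) ≤ τ, rather than by an
independent strict inequality; this is the only convention under which
CC + MC + UC = 1 holds *identically* at every τ, including thresholds that
coincide with observed scores. A record scoring exactly at its class
threshold is therefore rejected. The identity is asserted to 1e-12
throughout the test suite — the rates are ratios of integer counts over a
common denominator, so any violation beyond floating-point rounding is a
logic error, not noise.

## Threshold selection

Rates are step functions of τ: they can only jump where a record's score
sits. The candidate set for class *i* is therefore
`{0} ∪ {distinct scores of class-i records} ∪ {1}` — every achievable
(CC, MC, UC) triple occurs at one of these breakpoints, so the search is
exact rather than a grid approximation. (The test suite still scans a
1e-4-step grid as an independent oracle; the check is one-sided — the grid
can never do strictly better — because a fixed grid can skip operating
points between two scores closer than its step.)

Goals are ordered (lexicographic) objectives over the breakpoints:

* **g1**: maximize CC, then minimize MC — for users who cannot afford to
  miss an occurrence and will tolerate false alarms.
* **g2**: restrict to MC strictly below a bound (default 0.05), then
  maximize CC. The bound comparison is strict. One structural consequence
  of strict acceptance is that g2 is always feasible: τ = 1 rejects
  everything and yields MC = 0, so the bound-satisfying set is never empty.
  The infeasibility fallback (optimize the bounded quantity itself, flag
  the class) is implemented and reachable through custom bounded
  objectives, and kept for robustness.
* **g3**: minimize MC, then maximize CC — the most conservative option.
* **custom**: any ordered list of (quantity, direction, optional bound)
  objectives over {cc, mc, uc}.

Residual ties are broken toward the smallest τ by default (equal tuning
rates, higher future coverage); `largest_tau` is available. The choice is
visible only when distinct thresholds share identical tuning rates, which
happens readily with tied scores.

Classes declared but never observed as ground truth in the tuning table
receive the `ALWAYS_UNSURE` sentinel: with no data there is no risk
estimate, and rejecting every prediction of that class is the action
consistent with error control. The same conservatism drives the default
fallback for predicted classes missing from a threshold file
(`always_unsure`; `accept` and `error` are available).

## Rates, precision, and summaries

Per-class application rates (cc′, mc′, uc′) use the class's ground-truth
count as denominator, so raising any threshold can only shrink each class's
kept-and-wrong numerator: risk is anti-monotone in every threshold.
Precision ("accuracy" in the report tables) is kept-and-correct over all
kept predictions of the class; it is undefined (NA) when a class keeps no
predictions, and NA classes are excluded from aggregate means with an
explicit count, because silently coding them as 0 or 1 would bias the
summaries in opposite directions. Cross-class summaries are unweighted
means with the sample (n−1) standard deviation — every class counts
equally, rare or common.

The score-quantile diagnostic `correct_score_quantile()` reports, per
class, the lower empirical q-quantile of correct-classification scores
(default q = 0.05: the score above which 95% of correct classifications
lie) alongside the share of misclassifications scoring at or above it. A
large share is the signature of a class where no single cutoff separates
right from wrong — the motivation for per-class rather than global
thresholds.

Scores live on [0, 1] internally, always. The 0–100 percent scale seen in
reports is a display option (`render_report(scale = 100)`, the CLI's
`--scale`); files meant for further computation stay on the unit scale.
Input tables on a 0–100 scale are detected (any value > 1) and rescaled on
read, with a message.

## The synthetic score generator

No images or trained networks ship with the package; the simulator stands
in for them by reproducing the *statistical* structure that makes
thresholding non-trivial, with two score models:

* **dirichlet** (default) — the realistic model. Each record's score
  vector is Dirichlet-distributed with the predicted class's concentration
  boosted by `beta`; correct predictions use a sharper off-class base
  concentration (`alpha0_correct = 0.012`) than wrong ones
  (`alpha0 = 0.04`). The split matters: with a single concentration,
  correct and wrong top scores would be identically distributed and no
  threshold could ever separate them. With it, both overlap heavily in the
  bulk — wrong predictions frequently score above 0.9 — but correct scores
  concentrate harder in the extreme top sliver, so minimal-risk thresholds
  land very close to 1 yet retain a real fraction of correct
  classifications, mirroring how such classifiers behave in practice. The
  defaults were calibrated once against two qualitative targets (about 80%
  of top scores in [0.6, 1] for a 20-class problem at the default
  correctness probability 0.78; a fifth of wrong predictions above 0.9) and
  frozen. They are tail-sensitive: the off-class mass scales with the
  number of classes, so with very few classes (2–3) wrong scores also
  saturate near 1 and minimal-risk tuning degenerates toward full
  rejection — use more classes or the uniform_pair model for small-class
  illustrations.
* **uniform_pair** — the analytic model. Correct top scores are uniform on
  one interval, wrong ones on another. It exists because it admits the
  closed-form oracle `expected_rates()` (interval survival functions), so
  simulator and rate machinery can be checked against pencil-and-paper
  values and binomial error bars. It is deliberately unrealistic.

A rejection step in the dirichlet sampler redraws vectors whose argmax is
not the intended predicted class, keeping the table's invariants (predicted
class attains the maximum) exact. A single integer seed drives everything,
and the sampler restores the caller's RNG state.

What passing tests on simulated data do *not* show: real softmax scores
are discrete-ish, temporally correlated within a video, and can drift
between acquisition conditions; per-class tuning-set sizes in the field are
small and unbalanced. The simulator draws i.i.d. records with known
correctness probabilities — it validates the machinery and the qualitative
coverage–risk behaviour, not any particular field error rate.

## Numerical and scale choices

Test and benchmark problem sizes were chosen to exercise the method at the
scale of a realistic multi-class survey while keeping the default suite
fast: 20 classes × 500 records for the conservation sweep, 20 × 300 for
risk-bounded tuning, 10,000 records per class where empirical rates are
compared to closed forms at three-binomial-sd tolerance, and 20 independent
tune/test seed pairs (10 classes × 120 records each) for the goal-ordering
check, which tolerates at most 2 stochastic violations of
mc′(g3) ≤ mc′(g2) ≤ mc′(raw).

One subtlety the goal-ordering experiments surface: even with wrong and
correct score ranges fully disjoint, applied risk under g3 is not exactly
zero on independent data. Tuning puts τᵢ at the largest wrong score among
class *i*'s ground-truth records, but application compares a wrong record
against its *predicted* class's threshold, and an independent test table
can contain a wrong score that edges past a threshold tuned on a slightly
lower maximum. The expected number of such escapes is order one per class
regardless of sample size — the rate vanishes as n grows, and the package's
tests assert the honest near-zero version.

## Limitations

* Thresholds are empirical quantile-like statistics; for classes with few
  tuning records they are unstable. The package records per-class tuning
  counts in the threshold file but does not model that uncertainty.
* No smoothing or interpolation of rate curves, and no cross-validated
  threshold selection: one independent tuning set, as the protocol
  prescribes.
* The `UNSURE` queue is counted, not managed: routing rejected items to
  human review is out of scope.
* Scores are taken at face value; the method controls error by abstention,
  it does not recalibrate the classifier.
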