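# rejectr

Post-hoc error-rate control for multi-class classifiers via per-class
confidence thresholds — selective classification with a reject option.

## The problem

Automated species identification (and image classification generally) has a
stubborn operational flaw: a softmax classifier issues a label for *every*
image, and its scores are routinely overconfident — wrong predictions often
score above 0.9, and how badly scores overlap differs from class to class.
Ecologists processing camera or video surveys cannot use a fixed global
cutoff to keep only trustworthy labels, yet they need a controlled error
rate before feeding identifications into biodiversity assessments.

`rejectr` implements a simple post-hoc remedy that works with any classifier
whose output is a score vector, without retraining or recalibrating it. On a
scored dataset *independent* of the classifier's training data, it tunes one
confidence threshold per class; at application time, a prediction whose top
score does not exceed its *predicted* class's threshold is rerouted to a new
`UNSURE` class for human review. The error rate becomes a dial the user
sets, at the price of coverage.

## The model

For a class *i*, over its ground-truth records, with predicted class C(X),
top score S(X) and threshold τᵢ:

- CCᵢ(τ) = #(C(X) = i and S(X) > τᵢ and Y = i) / #(Y = i) — correct and kept
- MCᵢ(τ) = #(C(X) ≠ i and S(X) > τᵢ and Y = i) / #(Y = i) — wrong but kept
- UCᵢ(τ) = #(S(X) ≤ τᵢ and Y = i) / #(Y = i) — rejected ("unsure")

so CCᵢ + MCᵢ + UCᵢ = 1 identically, and coverage COVᵢ = CCᵢ + MCᵢ. All three
are step functions of τ, so tuning searches only the breakpoints (the
class's observed scores), which realize every achievable operating point.
Three lexicographic goals are built in, plus custom ones:

- **g1** — max CCᵢ, then min MCᵢ (never miss an occurrence; accept false
  alarms — e.g. invasive-species surveillance),
- **g2** — MCᵢ strictly below a bound (default 5%), then max CCᵢ (bounded
  risk at best coverage),
- **g3** — min MCᵢ, then max CCᵢ (minimal risk; most conservative).

At application time each record is judged against its *predicted* class's
threshold (τ_{C(X)}), ground truth never consulted. Per-class results are
reported as post-processed rates (cc′, mc′, uc′) plus the precision of kept
predictions, with unweighted cross-class means and sample standard
deviations.

## Worked example

Simulate a 20-class score table with class-dependent difficulty (the
Dirichlet score model emulates overconfident softmax outputs), tune
minimal-risk thresholds on one table, evaluate on an independent one:

```r
library(rejectr)

cfg <- simulation_config(
  n_per_class = 300,
  correctness_prob = seq(0.55, 0.95, length.out = 20),
  seed = 42
)
tuning <- simulate_predictions(cfg)
cfg_test <- cfg; cfg_test$seed <- 43L
test <- simulate_predictions(cfg_test)

ts <- tune(tuning, goal_spec("g3"))
tidy(ts)
#> # A tibble: 20 × 7
#>   class   tau tuning_cc tuning_mc tuning_uc n_truth feasible
#>   <chr> <dbl>     <dbl>     <dbl>     <dbl>   <int> <lgl>
#> 1 sp01  1.000     0.127         0     0.873     300 TRUE
#> 2 sp02  0.999     0.143         0     0.857     300 TRUE
#> 3 sp03  0.998     0.147         0     0.853     300 TRUE
#> # ...

ev <- evaluate_decisions(apply_thresholds(test, ts))
glance(ev)[c("mean_cc", "mean_mc", "mean_uc", "mean_accuracy",
             "mean_raw_cc", "mean_raw_mc")]
#> # A tibble: 1 × 6
#>   mean_cc mean_mc mean_uc mean_accuracy mean_raw_cc mean_raw_mc
#>     <dbl>   <dbl>   <dbl>         <dbl>       <dbl>       <dbl>
#> 1   0.217 0.00567   0.777         0.975       0.748       0.252
```

The raw classifier misidentifies 25.2% of items on average across classes;
after g3 post-processing only 0.57% of items are misclassified, 21.7% are
auto-identified (and 97.5% of kept labels are right), and the remaining
77.7% are handed to a human as `UNSURE`. Comparing all goals against the raw
baseline on the same tune/test pair:

```r
run_benchmark(cfg, design = "cross")$summary[
  c("goal", "mean_cc", "mean_mc", "mean_uc", "mean_accuracy")]
#> # A tibble: 4 × 5
#>   goal  mean_cc mean_mc mean_uc mean_accuracy
#>   <chr>   <dbl>   <dbl>   <dbl>         <dbl>
#> 1 g1      0.747 0.244   0.00867         0.751
#> 2 g2      0.507 0.0682  0.424          0.895
#> 3 g3      0.217 0.00567 0.777          0.975
#> 4 raw     0.748 0.252   0              0.745
```

`plot_rate_curve(rate_curve(tuning))` shows the per-class coverage–risk
trade-off; `autoplot(run_benchmark(cfg))` the per-goal comparison.

## Command line

A thin wrapper script is installed at
`system.file("cli", "rejectr", package = "rejectr")`:

```sh
rejectr simulate --classes a,b,c --n-per-class 200 --seed 1 --out pred.csv
rejectr tune --predictions pred.csv --goal g2 --mc-bound 0.05 --out thr.json
rejectr apply --predictions pred.csv --thresholds thr.json --out dec.csv
rejectr evaluate --decisions dec.csv --report report.csv --scale 100
rejectr benchmark --config sim.yaml --design cross --report bench.csv
```

Prediction tables are delimited text (long dialect: `item_id, true_class,
predicted_class, score`; wide dialect: one score column per class, argmax
derived). Scores on a 0–100 display scale are auto-detected and rescaled to
[0, 1]. Thresholds persist as versioned JSON.

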