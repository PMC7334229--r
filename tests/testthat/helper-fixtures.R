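# Hand-enumerable fixtures used throughout the suite.

# Five records, all ground truth "a": (Y, C(X), S(X)) =
# (a,a,0.95), (a,a,0.80), (a,b,0.90), (a,a,0.60), (a,b,0.55)
f1_table <- function() {
  prediction_table(data.frame(
    item_id = paste0("r", 1:5),
    true_class = "a",
    predicted_class = c("a", "a", "b", "a", "b"),
    top_score = c(0.95, 0.80, 0.90, 0.60, 0.55)
  ))
}

# Four records: (a,a,0.95), (a,a,0.80), (a,b,0.55), (b,b,0.45),
# decided against thresholds {a: 0.90, b: 0.50}.
f2_table <- function() {
  prediction_table(data.frame(
    item_id = paste0("q", 1:4),
    true_class = c("a", "a", "a", "b"),
    predicted_class = c("a", "a", "b", "b"),
    top_score = c(0.95, 0.80, 0.55, 0.45)
  ))
}

# Build a threshold_set directly from a named tau vector (NA = always
# unsure), bypassing tuning, for tests of the decision rule alone.
manual_thresholds <- function(taus, goal = goal_spec("g3"),
                              fallback = "always_unsure") {
  entries <- tibble::tibble(
    class = names(taus), tau = unname(taus),
    tuning_cc = NA_real_, tuning_mc = NA_real_, tuning_uc = NA_real_,
    n_truth = NA_integer_, feasible = NA
  )
  rejectr:::new_threshold_set(goal, entries, provenance = list(),
                              fallback = fallback)
}

f2_thresholds <- function() manual_thresholds(c(a = 0.90, b = 0.50))

# Random prediction table with arbitrary (not simulator-driven) structure,
# for property tests that should not depend on the generator's score models.
random_table <- function(n = 100, n_class = 4, seed = 1) {
  set.seed(seed)
  labels <- letters[seq_len(n_class)]
  truth <- sample(labels, n, replace = TRUE)
  correct <- runif(n) < runif(1, 0.3, 0.9)
  pred <- ifelse(correct, truth,
                 vapply(truth, function(y) sample(setdiff(labels, y), 1),
                        character(1)))
  # mix of continuous and tied scores so breakpoint handling is exercised
  scores <- ifelse(runif(n) < 0.3, round(runif(n), 1), runif(n))
  prediction_table(data.frame(
    item_id = sprintf("x%04d", seq_len(n)),
    true_class = truth, predicted_class = pred, top_score = scores
  ), class_set = labels)
}
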