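# Independent selection oracle: exhaustive scan over a dense threshold grid
# (step 1e-4), computing rates by direct counting, then lexicographic
# comparison. Returns the optimal (first objective value, second value).
grid_select <- function(table, cl, goal_id, mc_bound = 0.05) {
  rows <- table[table$true_class == cl, ]
  s <- sort(rows$top_score)
  correct_s <- sort(rows$top_score[rows$predicted_class == cl])
  n <- nrow(rows)
  grid <- seq(0, 1, by = 1e-4)
  # counts of scores strictly above each grid point
  above <- function(sorted) length(sorted) - findInterval(grid, sorted)
  cc <- above(correct_s) / n
  mc <- (above(s) - above(correct_s)) / n
  if (goal_id == "g1") {
    keep <- cc == max(cc)
    c(max(cc), min(mc[keep]))
  } else if (goal_id == "g3") {
    keep <- mc == min(mc)
    c(min(mc), max(cc[keep]))
  } else { # g2
    keep <- mc < mc_bound
    if (!any(keep)) keep <- mc == min(mc)
    c(min(mc[keep] [cc[keep] == max(cc[keep])]), max(cc[keep]))
  }
}

test_that("goal selections on the five-record fixture match hand search", {
  curve <- rate_curve(f1_table(), "a")

  g1 <- select_threshold(curve, goal_spec("g1"))
  expect_equal(g1$tau, 0.55)
  expect_equal(c(g1$tuning_cc, g1$tuning_mc, g1$tuning_uc),
               c(0.6, 0.2, 0.2))

  g3 <- select_threshold(curve, goal_spec("g3"))
  expect_equal(g3$tau, 0.90)
  expect_equal(c(g3$tuning_cc, g3$tuning_mc, g3$tuning_uc),
               c(0.2, 0, 0.8))

  g2 <- select_threshold(curve, goal_spec("g2", mc_bound = 0.05))
  expect_equal(g2$tau, 0.90)
  expect_true(g2$feasible)
  expect_equal(c(g2$tuning_cc, g2$tuning_mc), c(0.2, 0))
})

test_that("a separable class reaches zero risk with positive coverage", {
  sep <- prediction_table(data.frame(
    item_id = paste0("s", 1:6), true_class = "a",
    predicted_class = c("a", "a", "a", "b", "b", "b"),
    top_score = c(0.9, 0.85, 0.8, 0.6, 0.5, 0.4)
  ))
  sel <- select_threshold(rate_curve(sep, "a"), goal_spec("g3"))
  expect_equal(sel$tuning_mc, 0)
  expect_gt(sel$tuning_cc, 0)
})

test_that("g2 is always feasible: full rejection drives mc below any bound", {
  # with strict acceptance, tau = 1 rejects everything, so mc = 0 meets any
  # positive bound and the bound-satisfying set is never empty
  for (seed in 1:5) {
    tab <- random_table(n = 60, n_class = 3, seed = seed + 40)
    ts <- tune(tab, goal_spec("g2", mc_bound = 0.01))
    expect_true(all(ts$entries$feasible))
    expect_true(all(ts$entries$tuning_mc < 0.01))
  }
})

test_that("an unattainable bounded objective falls back and is flagged", {
  curve <- rate_curve(f1_table(), "a")
  impossible <- goal_spec("custom", objectives = list(
    list(quantity = "cc", direction = "max", bound = 2), # cc > 2: empty
    list(quantity = "mc", direction = "min")
  ))
  sel <- select_threshold(curve, impossible)
  expect_false(sel$feasible)
  # fallback optimizes the bounded quantity itself, then continues
  expect_equal(sel$tuning_cc, max(curve$cc))
  expect_equal(sel$tuning_mc,
               min(curve$mc[curve$cc == max(curve$cc)]))
})

test_that("the dense-grid oracle never beats the breakpoint selection", {
  # one-sided by design: breakpoints realize every achievable operating
  # point, while a fixed grid can skip those between near-tied scores
  for (seed in 1:25) {
    tab <- random_table(n = sample(20:200, 1), n_class = 3,
                        seed = seed + 300)
    cl <- unique(tab$true_class)[1]
    curve <- rate_curve(tab, cl)
    g1 <- select_threshold(curve, goal_spec("g1"))
    o1 <- grid_select(tab, cl, "g1")
    expect_true(o1[1] < g1$tuning_cc ||
                  (o1[1] == g1$tuning_cc && o1[2] >= g1$tuning_mc))

    g3 <- select_threshold(curve, goal_spec("g3"))
    o3 <- grid_select(tab, cl, "g3")
    expect_true(o3[1] > g3$tuning_mc ||
                  (o3[1] == g3$tuning_mc && o3[2] <= g3$tuning_cc))

    g2 <- select_threshold(curve, goal_spec("g2"))
    o2 <- grid_select(tab, cl, "g2")
    expect_lte(o2[2], g2$tuning_cc)
    expect_true(g2$tuning_mc < 0.05)
  }
})

test_that("goal extremes hold on every class of a simulated table", {
  tab <- simulate_predictions(simulation_config(
    class_labels = sprintf("c%02d", 1:10), n_per_class = 80, seed = 77
  ))
  curves <- rate_curve(tab)
  for (cl in unique(curves$class)) {
    cv <- curves[curves$class == cl, ]
    g1 <- select_threshold(cv, goal_spec("g1"))
    expect_equal(g1$tuning_cc, max(cv$cc)) # g1 attains the cc maximum
    g3 <- select_threshold(cv, goal_spec("g3"))
    expect_equal(g3$tuning_mc, min(cv$mc)) # g3 attains the mc minimum
    # no breakpoint strictly dominates the g3 choice lexicographically
    better <- cv$mc < g3$tuning_mc |
      (cv$mc == g3$tuning_mc & cv$cc > g3$tuning_cc)
    expect_false(any(better))
  }
})

test_that("custom lexicographic goals are honoured", {
  curve <- rate_curve(f1_table(), "a")
  # minimize uc first: raw operating point, tau = 0
  min_uc <- goal_spec("custom", objectives = list(
    list(quantity = "uc", direction = "min"),
    list(quantity = "cc", direction = "max")
  ))
  sel <- select_threshold(curve, min_uc)
  expect_equal(sel$tau, 0)
  expect_equal(sel$tuning_uc, 0)

  # bounded custom objective behaves like g2
  bounded <- goal_spec("custom", objectives = list(
    list(quantity = "mc", direction = "min", bound = 0.05),
    list(quantity = "cc", direction = "max")
  ))
  expect_equal(select_threshold(curve, bounded)$tau,
               select_threshold(curve, goal_spec("g2"))$tau)

  expect_error(goal_spec("custom"), class = "rejectr_config_error")
  expect_error(goal_spec("custom", objectives = list(list(
    quantity = "xx", direction = "max"
  ))), class = "rejectr_config_error")
})

test_that("tie-break policy resolves residual ties as configured", {
  # two breakpoints share the optimal (cc, mc): scores tied across classes
  tab <- prediction_table(data.frame(
    item_id = paste0("z", 1:2), true_class = "a",
    predicted_class = c("a", "a"), top_score = c(0.6, 0.6)
  ))
  curve <- rate_curve(tab, "a") # taus 0, 0.6, 1; cc = 1, 0, 0
  small <- select_threshold(curve, goal_spec("g3"))
  large <- select_threshold(curve,
                            goal_spec("g3", tie_break = "largest_tau"))
  expect_equal(small$tau, 0)
  expect_equal(large$tau, 0)
  # mc = 0 everywhere; cc maximal only at 0 -> no tie left. Force one:
  g_uc <- goal_spec("custom", objectives = list(
    list(quantity = "mc", direction = "min")
  ))
  g_uc_l <- goal_spec("custom", objectives = list(
    list(quantity = "mc", direction = "min")
  ), tie_break = "largest_tau")
  expect_equal(select_threshold(curve, g_uc)$tau, 0)
  expect_equal(select_threshold(curve, g_uc_l)$tau, 1)
})

test_that("tune covers every class and handles unobserved ones", {
  tab <- random_table(n = 200, n_class = 4, seed = 13)
  attr(tab, "class_set") <- c(class_set(tab), "ghost")
  expect_warning(ts <- tune(tab, goal_spec("g3")), "ghost")
  expect_setequal(ts$entries$class, c(class_set(tab)))
  ghost <- ts$entries[ts$entries$class == "ghost", ]
  expect_true(is.na(ghost$tau))
  expect_equal(ghost$n_truth, 0L)

  expect_error(tune(tab[0, ], goal_spec("g3")),
               class = "rejectr_tuning_error")
})

test_that("tuning is deterministic and self-consistent", {
  tab <- simulate_predictions(simulation_config(
    class_labels = letters[1:5], n_per_class = 100, seed = 8
  ))
  t1 <- tune(tab, goal_spec("g2"))
  t2 <- tune(tab, goal_spec("g2"))
  expect_identical(t1$entries, t2$entries)
  expect_identical(t1$provenance$content_hash, t2$provenance$content_hash)

  # re-evaluating tuning-phase rates at the stored taus reproduces entries
  for (i in seq_len(nrow(t1$entries))) {
    e <- t1$entries[i, ]
    r <- rates_at_threshold(tab, e$tau, e$class)
    expect_equal(c(r$cc, r$mc, r$uc),
                 c(e$tuning_cc, e$tuning_mc, e$tuning_uc))
  }
})

test_that("symmetric two-class tables get symmetric thresholds", {
  half <- data.frame(
    item_id = paste0("r", 1:5), true_class = "a",
    predicted_class = c("a", "a", "b", "a", "b"),
    top_score = c(0.95, 0.80, 0.90, 0.60, 0.55)
  )
  other <- half
  other$item_id <- paste0("s", 1:5)
  other$true_class <- "b"
  other$predicted_class <- c("b", "b", "a", "b", "a")
  tab <- prediction_table(rbind(half, other))
  ts <- tune(tab, goal_spec("g3"))
  expect_equal(ts$entries$tau[1], ts$entries$tau[2])
  expect_equal(ts$entries$tuning_cc[1], ts$entries$tuning_cc[2])
})
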