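# Brute-force oracle: rate triple for one class at one threshold by direct
# record-by-record enumeration, independent of the package's vectorized path.
enumerate_rates <- function(table, cl, tau = NULL) {
  rows <- table[table$true_class == cl, ]
  n <- nrow(rows)
  cc <- mc <- uc <- 0
  for (i in seq_len(n)) {
    kept <- is.null(tau) || rows$top_score[i] > tau
    if (!kept) {
      uc <- uc + 1
    } else if (rows$predicted_class[i] == cl) {
      cc <- cc + 1
    } else {
      mc <- mc + 1
    }
  }
  c(cc = cc / n, mc = mc / n, uc = uc / n)
}

test_that("raw rates match hand enumeration on the five-record fixture", {
  r <- raw_rates(f1_table(), "a")
  expect_equal(r$cc, 0.6)
  expect_equal(r$mc, 0.4)
  expect_equal(r$uc, 0)
  expect_equal(r$n_truth, 5)

  perfect <- prediction_table(data.frame(
    item_id = c("p1", "p2"), true_class = c("a", "b"),
    predicted_class = c("a", "b"), top_score = c(0.9, 0.8)
  ))
  expect_equal(raw_rates(perfect)$cc, c(1, 1))

  single <- prediction_table(data.frame(
    item_id = "s1", true_class = "a", predicted_class = "b",
    top_score = 0.99
  ))
  r1 <- raw_rates(single, "a")
  expect_equal(c(r1$cc, r1$mc), c(0, 1))
})

test_that("thresholded rates use strict acceptance and complement rejection", {
  f1 <- f1_table()
  r <- rates_at_threshold(f1, 0.7, "a")
  expect_equal(c(r$cc, r$mc, r$uc), c(0.4, 0.2, 0.4))

  # threshold-free limit: tau = 0 equals the raw rates when all scores > 0
  expect_equal(rates_at_threshold(f1, 0, "a")[c("cc", "mc", "uc")],
               dplyr::mutate(raw_rates(f1, "a")[c("cc", "mc")], uc = 0))

  # total rejection at tau = 1
  r1 <- rates_at_threshold(f1, 1, "a")
  expect_equal(c(r1$cc, r1$mc, r1$uc), c(0, 0, 1))

  # boundary: a score exactly at tau is rejected
  rb <- rates_at_threshold(f1, 0.95, "a")
  expect_equal(rb$cc, 0)
  expect_equal(rb$uc, 1)

  expect_error(rates_at_threshold(f1, 1.2, "a"),
               class = "rejectr_domain_error")
  expect_error(rates_at_threshold(f1, 0.5, "zz"),
               class = "rejectr_undefined_rate_error")
})

test_that("rates agree with brute-force enumeration at random thresholds", {
  for (seed in 1:3) {
    tab <- random_table(n = 200, n_class = 4, seed = seed)
    set.seed(seed + 100)
    taus <- runif(1000)
    cl <- sample(unique(tab$true_class), 1)
    for (tau in taus[1:50]) { # spot-check the scalar oracle densely
      expect_equal(
        unlist(rates_at_threshold(tab, tau, cl)[c("cc", "mc", "uc")],
               use.names = FALSE),
        unname(enumerate_rates(tab, cl, tau))
      )
    }
    # full 1000-threshold sweep, vectorised comparison
    got <- vapply(taus, function(t) {
      unlist(rates_at_threshold(tab, t, cl)[c("cc", "mc", "uc")])
    }, numeric(3))
    want <- vapply(taus, function(t) enumerate_rates(tab, cl, t),
                   numeric(3))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("rate curves hit exactly the achievable operating points", {
  f1 <- f1_table()
  curve <- rate_curve(f1, "a")
  expect_equal(curve$tau, c(0, 0.55, 0.60, 0.80, 0.90, 0.95, 1))

  single <- prediction_table(data.frame(
    item_id = "s1", true_class = "a", predicted_class = "a", top_score = 0.5
  ))
  sc <- rate_curve(single, "a")
  expect_equal(sc$tau, c(0, 0.5, 1))
  expect_equal(sc$cc, c(1, 0, 0)) # strict >: rejected at its own score

  # dense-grid sweep finds no triple absent from the curve
  tab <- random_table(n = 80, n_class = 3, seed = 21)
  for (cl in unique(tab$true_class)) {
    cv <- rate_curve(tab, cl)
    on_curve <- unique(paste(cv$cc, cv$mc, cv$uc))
    grid <- seq(0, 1, by = 0.001)
    swept <- vapply(grid, function(t) {
      r <- rates_at_threshold(tab, t, cl)
      paste(r$cc, r$mc, r$uc)
    }, character(1))
    expect_true(all(swept %in% on_curve))
  }
})

test_that("conservation and coverage identities hold on every curve", {
  for (seed in 1:5) {
    tab <- random_table(n = 150, n_class = 4, seed = seed)
    curve <- rate_curve(tab)
    expect_true(all(abs(curve$cc + curve$mc + curve$uc - 1) <= 1e-12))
    expect_equal(curve$cov, curve$cc + curve$mc)
  }
})

test_that("rates are monotone along the threshold", {
  for (seed in 1:5) {
    tab <- random_table(n = 150, n_class = 4, seed = seed)
    curve <- rate_curve(tab)
    for (cl in unique(curve$class)) {
      cv <- curve[curve$class == cl, ]
      expect_true(all(diff(cv$cc) <= 0))
      expect_true(all(diff(cv$mc) <= 0))
      expect_true(all(diff(cv$cov) <= 0))
      expect_true(all(diff(cv$uc) >= 0))
    }
  }
})

test_that("correct-score quantile matches the fixture enumeration", {
  q <- correct_score_quantile(f1_table(), "a", q = 1 / 3)
  expect_equal(q$sq, 0.60)
  expect_equal(q$mis_share, 0.5) # 0.90 >= 0.60, 0.55 < 0.60

  # separated distributions: every wrong score below every correct score
  sep <- prediction_table(data.frame(
    item_id = paste0("s", 1:4), true_class = "a",
    predicted_class = c("a", "a", "b", "b"),
    top_score = c(0.9, 0.8, 0.4, 0.3)
  ))
  expect_equal(correct_score_quantile(sep, "a", q = 0.05)$mis_share, 0)

  # one-point distribution: sq is that score for any q
  one <- prediction_table(data.frame(
    item_id = c("o1", "o2"), true_class = "a",
    predicted_class = c("a", "b"), top_score = c(0.7, 0.9)
  ))
  for (qq in c(0.05, 0.5, 0.95)) {
    expect_equal(correct_score_quantile(one, "a", q = qq)$sq, 0.7)
  }

  none <- prediction_table(data.frame(
    item_id = "n1", true_class = "a", predicted_class = "b",
    top_score = 0.9
  ))
  expect_error(correct_score_quantile(none, "a"),
               class = "rejectr_undefined_rate_error")
})

test_that("cross-class summaries use the sample standard deviation", {
  expect_equal(summarize_rates(c(0.5, 0.5)), tibble::tibble(
    mean = 0.5, sd = 0, n_used = 2L, n_na = 0L
  ))
  s <- summarize_rates(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, sqrt(0.5), tolerance = 1e-12)

  set.seed(42)
  x <- runif(20)
  s2 <- summarize_rates(x)
  # textbook-formula recomputation
  expect_equal(s2$mean, sum(x) / 20)
  expect_equal(s2$sd, sqrt(sum((x - sum(x) / 20)^2) / 19))

  expect_equal(summarize_rates(c(0.2, NA, 0.4))$n_na, 1L)
  expect_error(summarize_rates(numeric(0)), class = "rejectr_domain_error")
})
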