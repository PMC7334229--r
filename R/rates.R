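#' Per-class classification rates
#'
#' For each ground-truth class the classifier's behaviour is summarised by
#' three rates over that class's items: the correct-classification rate `cc`
#' (predicted as the class and kept), the misclassification rate `mc`
#' (predicted as another class and kept), and the unsure rate `uc` (rejected).
#' Without a threshold (`raw_rates`) nothing is rejected, so `uc = 0`. With a
#' confidence threshold `tau` (`rates_at_threshold`) a prediction is kept only
#' when its top score strictly exceeds `tau`; records with score `<= tau`
#' count as unsure, so `cc + mc + uc = 1` identically and the coverage
#' `cov = cc + mc` is the fraction of items still classified at all.
#'
#' These are *tuning-phase* rates: the threshold is indexed by the
#' ground-truth class. Rates after applying a tuned threshold set — where
#' each record is judged against its *predicted* class's threshold — are
#' computed by [application_rates()].
#'
#' @param table A [prediction_table()] (any data frame with `true_class`,
#'   `predicted_class`, `top_score` columns works).
#' @param classes Classes to compute rates for; default all classes with at
#'   least one ground-truth record. Requesting a class with no ground-truth
#'   records is an error (its rates are undefined).
#' @param tau Confidence threshold in \[0, 1\].
#' @return A tibble with one row per class and columns `class`, `tau`
#'   (`NA` for raw rates), `cc`, `mc`, `uc`, `cov`, `n_truth`.
#' @examples
#' f1 <- prediction_table(data.frame(
#'   item_id = paste0("r", 1:5), true_class = "a",
#'   predicted_class = c("a", "a", "b", "a", "b"),
#'   top_score = c(0.95, 0.80, 0.90, 0.60, 0.55)
#' ))
#' raw_rates(f1, "a")            # cc = 0.6, mc = 0.4
#' rates_at_threshold(f1, 0.7, "a")  # cc = 0.4, mc = 0.2, uc = 0.4
#' @export
raw_rates <- function(table, classes = NULL) {
  rates_by_class(table, classes, tau = NA_real_)
}

#' @rdname raw_rates
#' @export
rates_at_threshold <- function(table, tau, classes = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) ||
      tau < 0 || tau > 1) {
    abort("`tau` must be a single number in [0, 1]",
          class = "rejectr_domain_error")
  }
  rates_by_class(table, classes, tau = tau)
}

rates_by_class <- function(table, classes, tau) {
  observed <- unique(table$true_class)
  if (is.null(classes)) {
    classes <- sort(observed)
  }
  missing <- setdiff(classes, observed)
  if (length(missing) > 0) {
    abort(paste0("Rates undefined: no ground-truth records for class(es) ",
                 paste(missing, collapse = ", ")),
          class = "rejectr_undefined_rate_error")
  }
  purrr::map_dfr(classes, function(cl) {
    sub <- table[table$true_class == cl, , drop = FALSE]
    kept <- if (is.na(tau)) rep(TRUE, nrow(sub)) else sub$top_score > tau
    cc <- mean(sub$predicted_class == cl & kept)
    mc <- mean(sub$predicted_class != cl & kept)
    uc <- mean(!kept)
    tibble(class = cl, tau = tau, cc = cc, mc = mc, uc = uc,
           cov = cc + mc, n_truth = nrow(sub))
  })
}

#' Rate curves: rates at every achievable operating point
#'
#' `cc`, `mc` and `uc` are step functions of the threshold, jumping only at
#' observed scores. The curve therefore evaluates [rates_at_threshold()] at
#' the breakpoints `{0} U {distinct scores of the class's records} U {1}`:
#' every `(cc, mc, uc)` triple achievable by any threshold in \[0, 1\]
#' appears at one of these breakpoints, so downstream threshold selection
#' over breakpoints is exact, not a grid approximation.
#'
#' @inheritParams raw_rates
#' @return A tibble with one row per class x breakpoint, columns as in
#'   [raw_rates()] plus `tau` set to the breakpoint.
#' @export
rate_curve <- function(table, classes = NULL) {
  observed <- unique(table$true_class)
  if (is.null(classes)) {
    classes <- sort(observed)
  }
  missing <- setdiff(classes, observed)
  if (length(missing) > 0) {
    abort(paste0("Rate curve undefined: no ground-truth records for ",
                 "class(es) ", paste(missing, collapse = ", ")),
          class = "rejectr_undefined_rate_error")
  }
  purrr::map_dfr(classes, function(cl) {
    sub <- table[table$true_class == cl, , drop = FALSE]
    s <- sub$top_score
    correct <- sub$predicted_class == cl
    breaks <- sort(unique(c(0, s, 1)))
    cc <- vapply(breaks, function(b) mean(correct & s > b), numeric(1))
    mc <- vapply(breaks, function(b) mean(!correct & s > b), numeric(1))
    uc <- vapply(breaks, function(b) mean(s <= b), numeric(1))
    tibble(class = cl, tau = breaks, cc = cc, mc = mc, uc = uc,
           cov = cc + mc, n_truth = nrow(sub))
  })
}

#' Rates and precision after applying a threshold set
#'
#' Computed on a decided table (see [apply_thresholds()]), per ground-truth
#' class: `cc` is the fraction whose final decision equals the class, `mc`
#' the fraction whose final decision is a *different* class (the prediction
#' was kept because its score exceeded the predicted class's threshold), and
#' `uc` the fraction rerouted to `UNSURE`. `accuracy` is the precision of the
#' kept predictions of the class over the whole table — kept-and-correct over
#' all kept predictions of that class — and is `NA` when the class keeps no
#' predictions at all.
#'
#' @param post A decided table from [apply_thresholds()] (needs columns
#'   `true_class`, `decision`).
#' @inheritParams raw_rates
#' @return A tibble with columns `class`, `cc`, `mc`, `uc`, `cov`,
#'   `accuracy`, `n_truth`, `n_kept` (number of kept predictions of the
#'   class, the precision denominator).
#' @export
application_rates <- function(post, classes = NULL) {
  observed <- unique(post$true_class)
  if (is.null(classes)) {
    classes <- sort(observed)
  }
  missing <- setdiff(classes, observed)
  if (length(missing) > 0) {
    abort(paste0("Rates undefined: no ground-truth records for class(es) ",
                 paste(missing, collapse = ", ")),
          class = "rejectr_undefined_rate_error")
  }
  purrr::map_dfr(classes, function(cl) {
    sub <- post[post$true_class == cl, , drop = FALSE]
    cc <- mean(sub$decision == cl)
    uc <- mean(sub$decision == UNSURE)
    mc <- mean(sub$decision != cl & sub$decision != UNSURE)
    kept <- post[post$decision == cl, , drop = FALSE]
    acc <- if (nrow(kept) == 0) NA_real_ else mean(kept$true_class == cl)
    tibble(class = cl, cc = cc, mc = mc, uc = uc, cov = cc + mc,
           accuracy = acc, n_truth = nrow(sub), n_kept = nrow(kept))
  })
}

#' Score quantile of correct classifications
#'
#' For each class, `sq` is the lower empirical `q`-quantile of the scores of
#' its correctly classified records: the smallest observed correct score such
#' that at least a fraction `q` of correct scores lie at or below it —
#' equivalently, at least `1 - q` of correct classifications score at or
#' above `sq`. `mis_share` is the fraction of the class's misclassified
#' records scoring at or above `sq`. With the default `q = 0.05` this is the
#' diagnostic "the score above which 95% of correct classifications lie, and
#' the share of misclassifications reaching it": a large `mis_share` means no
#' single cutoff separates right from wrong for that class.
#'
#' @inheritParams raw_rates
#' @param q Quantile level in (0, 1); default 0.05.
#' @return A tibble with columns `class`, `sq`, `mis_share`, `n_correct`,
#'   `n_mis`, on the unit score scale. `mis_share` is `NA` when the class has
#'   no misclassified records (no distribution to take a share of).
#' @export
correct_score_quantile <- function(table, classes = NULL, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must be a single number in (0, 1)",
          class = "rejectr_domain_error")
  }
  observed <- unique(table$true_class)
  if (is.null(classes)) {
    classes <- sort(observed)
  }
  purrr::map_dfr(classes, function(cl) {
    sub <- table[table$true_class == cl, , drop = FALSE]
    correct <- sub$top_score[sub$predicted_class == cl]
    wrong <- sub$top_score[sub$predicted_class != cl]
    if (length(correct) == 0) {
      abort(paste0("Quantile undefined: class '", cl,
                   "' has no correct classifications"),
            class = "rejectr_undefined_rate_error")
    }
    sq <- sort(correct)[ceiling(q * length(correct))]
    mis_share <- if (length(wrong) == 0) NA_real_ else mean(wrong >= sq)
    tibble(class = cl, sq = sq, mis_share = mis_share,
           n_correct = length(correct), n_mis = length(wrong))
  })
}

#' Mean and sample standard deviation across classes
#'
#' The unweighted summary used in report footers: every class contributes
#' equally regardless of its record count, and the spread is the sample
#' (n - 1) standard deviation. `NA` entries (e.g. undefined precisions) are
#' dropped, with the number of classes actually summarised reported.
#'
#' @param x Numeric vector of per-class values.
#' @return A tibble with columns `mean`, `sd`, `n_used`, `n_na`.
#' @export
summarize_rates <- function(x) {
  if (length(x) == 0) {
    abort("Cannot summarise an empty vector", class = "rejectr_domain_error")
  }
  keep <- x[!is.na(x)]
  tibble(
    mean = if (length(keep) == 0) NA_real_ else mean(keep),
    sd = if (length(keep) < 2) NA_real_ else sd(keep),
    n_used = length(keep),
    n_na = sum(is.na(x))
  )
}
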