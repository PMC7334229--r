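#' Apply tuned thresholds to a prediction table
#'
#' The application-phase decision rule: each record is judged against the
#' threshold of its *predicted* class. The prediction is confirmed when the
#' top score strictly exceeds that threshold and rerouted to [UNSURE]
#' otherwise — including when the score exactly equals the threshold, and
#' always for classes carrying the `ALWAYS_UNSURE` sentinel. Ground truth is
#' never consulted: shuffling the `true_class` column changes no decision.
#'
#' Predicted classes absent from the threshold set are handled by the set's
#' fallback policy (overridable here): `"always_unsure"` rejects them
#' (conservative default), `"accept"` keeps them, `"error"` fails naming the
#' class.
#'
#' @param table A [prediction_table()] to post-process.
#' @param thresholds A `threshold_set` from [tune()] or [read_thresholds()].
#' @param fallback Optional override of the set's missing-class policy.
#' @return A tibble of class `decided_table`: the input records plus
#'   `decision` (a class label or `"UNSURE"`) and `applied_tau` (the
#'   threshold compared against; `NA` for always-unsure and rejected-fallback
#'   cases), in input order, with the threshold provenance attached as the
#'   `threshold_provenance` attribute.
#' @examples
#' tab <- prediction_table(data.frame(
#'   item_id = paste0("q", 1:4), true_class = c("a", "a", "a", "b"),
#'   predicted_class = c("a", "a", "b", "b"),
#'   top_score = c(0.95, 0.80, 0.55, 0.45)
#' ))
#' ts <- tune(tab, goal_spec("g3"))
#' apply_thresholds(tab, ts)
#' @export
apply_thresholds <- function(table, thresholds, fallback = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  fallback <- fallback %||% thresholds$fallback
  fallback <- match.arg(fallback, c("always_unsure", "accept", "error"))

  entries <- thresholds$entries
  idx <- match(table$predicted_class, entries$class)
  missing <- unique(table$predicted_class[is.na(idx)])
  if (length(missing) > 0 && fallback == "error") {
    abort(paste0("No threshold for predicted class(es): ",
                 paste(missing, collapse = ", ")),
          class = "rejectr_decision_error")
  }
  tau <- entries$tau[idx] # NA for sentinel entries and for missing classes
  known <- !is.na(idx)
  keep <- known & !is.na(tau) & table$top_score > tau
  if (fallback == "accept") {
    keep <- keep | !known
  }
  out <- as_tibble(table)
  out$decision <- ifelse(keep, table$predicted_class, UNSURE)
  out$applied_tau <- tau
  attr(out, "class_set") <- class_set(table)
  attr(out, "threshold_provenance") <- list(
    goal = thresholds$goal$goal_id,
    fallback = fallback,
    provenance = thresholds$provenance
  )
  class(out) <- unique(c("decided_table", class(out)))
  out
}

#' Decide a single record
#'
#' Scalar form of the rule in [apply_thresholds()], convenient for
#' inspection: returns the confirmed class label or `"UNSURE"`.
#'
#' @param predicted_class Predicted class label.
#' @param top_score Top softmax score in \[0, 1\].
#' @param thresholds A `threshold_set`.
#' @param fallback Optional override of the missing-class policy.
#' @return A length-one character vector.
#' @export
decide <- function(predicted_class, top_score, thresholds, fallback = NULL) {
  tab <- tibble(
    item_id = "x", true_class = predicted_class,
    predicted_class = predicted_class, top_score = top_score
  )
  apply_thresholds(prediction_table(tab, validate = FALSE), thresholds,
                   fallback = fallback)$decision
}

#' Evaluate a decided table
#'
#' Per-class application rates (via [application_rates()]) with unweighted
#' mean and sample-sd aggregates across classes, side by side with the raw
#' (no post-processing) rates of the same records for comparison. Classes
#' with undefined precision (no kept predictions) are excluded from the
#' precision aggregate, with the exclusion count reported.
#'
#' @param post A `decided_table` from [apply_thresholds()].
#' @return A `rejectr_evaluation` object; see [tidy.rejectr_evaluation()] for
#'   the per-class table and [glance.rejectr_evaluation()] for aggregates.
#' @export
evaluate_decisions <- function(post) {
  if (nrow(post) == 0) {
    abort("Cannot evaluate an empty decided table",
          class = "rejectr_evaluation_error")
  }
  if (!"decision" %in% names(post)) {
    abort("`post` must come from apply_thresholds() (missing `decision`)",
          class = "rejectr_evaluation_error")
  }
  applied <- application_rates(post)
  raw <- raw_rates(post)
  raw$accuracy <- purrr::map_dbl(raw$class, function(cl) {
    kept <- post$predicted_class == cl
    if (!any(kept)) NA_real_ else mean(post$true_class[kept] == cl)
  })
  structure(
    list(per_class = applied, raw = raw,
         provenance = attr(post, "threshold_provenance")),
    class = "rejectr_evaluation"
  )
}

#' @export
print.rejectr_evaluation <- function(x, ...) {
  cat("<rejectr_evaluation> ", nrow(x$per_class), " classes",
      if (!is.null(x$provenance$goal)) paste0(", goal ", x$provenance$goal),
      "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy an evaluation
#'
#' @param x A `rejectr_evaluation` from [evaluate_decisions()].
#' @param ... Unused.
#' @return One row per class with post-processed rates (`cc`, `mc`, `uc`,
#'   `cov`, `accuracy`) and the raw baseline (`raw_cc`, `raw_mc`,
#'   `raw_accuracy`).
#' @method tidy rejectr_evaluation
#' @export
tidy.rejectr_evaluation <- function(x, ...) {
  raw <- x$raw %>%
    select("class", raw_cc = "cc", raw_mc = "mc", raw_accuracy = "accuracy")
  x$per_class %>%
    select("class", "cc", "mc", "uc", "cov", "accuracy", "n_truth",
           "n_kept") %>%
    left_join(raw, by = "class")
}

#' @rdname tidy.rejectr_evaluation
#' @return For `glance`, a one-row tibble of unweighted cross-class means
#'   and sample standard deviations of each rate, plus
#'   `n_accuracy_undefined`, the number of classes excluded from the
#'   precision aggregate.
#' @method glance rejectr_evaluation
#' @export
glance.rejectr_evaluation <- function(x, ...) {
  p <- x$per_class
  acc <- summarize_rates(p$accuracy)
  tibble(
    n_classes = nrow(p),
    mean_cc = mean(p$cc), sd_cc = sd(p$cc),
    mean_mc = mean(p$mc), sd_mc = sd(p$mc),
    mean_uc = mean(p$uc), sd_uc = sd(p$uc),
    mean_accuracy = acc$mean, sd_accuracy = acc$sd,
    n_accuracy_undefined = acc$n_na,
    mean_raw_cc = mean(x$raw$cc), mean_raw_mc = mean(x$raw$mc)
  )
}
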