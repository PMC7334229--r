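#' Specify a threshold-selection goal
#'
#' A goal is a lexicographic objective over the operating points of a class's
#' rate curve. Three standard goals are built in:
#'
#' * `g1` — keep the best correct-classification rate: maximize `cc`, then
#'   among the maximizers minimize `mc`.
#' * `g2` — bound the risk: restrict to thresholds with `mc` strictly below
#'   `mc_bound` (default 5%), then maximize `cc`. If no threshold meets the
#'   bound the class falls back to the `mc`-minimizing thresholds and is
#'   flagged infeasible.
#' * `g3` — minimal risk: minimize `mc`, then among the minimizers maximize
#'   `cc`.
#'
#' `custom` goals give an ordered list of objectives, each
#' `list(quantity =, direction =, bound =)` with quantity in
#' `{"cc", "mc", "uc"}` and direction `"max"` or `"min"`; an objective with a
#' bound filters (strictly better than the bound in its direction) before
#' later objectives optimize, with the same empty-set fallback as `g2`.
#'
#' Remaining ties are broken by `tie_break`: `"smallest_tau"` (default —
#' keeps future coverage as high as possible at equal tuning rates) or
#' `"largest_tau"`.
#'
#' @param goal_id One of `"g1"`, `"g2"`, `"g3"`, `"custom"`.
#' @param mc_bound Misclassification upper bound for `g2`, in (0, 1\].
#' @param objectives For `"custom"`, ordered list of objectives (see above).
#' @param tie_break `"smallest_tau"` or `"largest_tau"`.
#' @return A `goal_spec` object.
#' @examples
#' goal_spec("g2", mc_bound = 0.05)
#' goal_spec("custom",
#'   objectives = list(list(quantity = "uc", direction = "min")))
#' @export
goal_spec <- function(goal_id = c("g1", "g2", "g3", "custom"),
                      mc_bound = 0.05, objectives = NULL,
                      tie_break = c("smallest_tau", "largest_tau")) {
  goal_id <- match.arg(goal_id)
  tie_break <- match.arg(tie_break)
  if (goal_id == "g2") {
    if (!is.numeric(mc_bound) || length(mc_bound) != 1 ||
        mc_bound <= 0 || mc_bound > 1) {
      abort("g2 requires `mc_bound` in (0, 1]",
            class = "rejectr_config_error")
    }
  }
  if (goal_id == "custom") {
    if (is.null(objectives) || length(objectives) == 0) {
      abort("A custom goal needs at least one objective",
            class = "rejectr_config_error")
    }
    for (o in objectives) {
      if (!is.list(o) || !o$quantity %in% c("cc", "mc", "uc") ||
          !o$direction %in% c("max", "min")) {
        abort("Each objective needs quantity in {cc, mc, uc} and direction in {max, min}",
              class = "rejectr_config_error")
      }
    }
  }
  structure(
    list(goal_id = goal_id, mc_bound = mc_bound,
         objectives = objectives, tie_break = tie_break),
    class = "goal_spec"
  )
}

#' @export
print.goal_spec <- function(x, ...) {
  cat("<goal_spec> ", x$goal_id, sep = "")
  if (x$goal_id == "g2") cat(" (mc < ", x$mc_bound, ")", sep = "")
  cat(", tie break: ", x$tie_break, "\n", sep = "")
  invisible(x)
}

# Normalize any goal to an ordered list of lexicographic objectives.
goal_objectives <- function(goal) {
  switch(goal$goal_id,
    g1 = list(list(quantity = "cc", direction = "max"),
              list(quantity = "mc", direction = "min")),
    g2 = list(list(quantity = "mc", direction = "min",
                   bound = goal$mc_bound),
              list(quantity = "cc", direction = "max")),
    g3 = list(list(quantity = "mc", direction = "min"),
              list(quantity = "cc", direction = "max")),
    custom = goal$objectives
  )
}

#' Select one threshold from a rate curve under a goal
#'
#' Works over the curve's breakpoints, which realize every achievable
#' operating point (the rates are step functions of the threshold), so the
#' selection is exact. Objectives are applied in order; a bounded objective
#' keeps the breakpoints strictly inside its bound (e.g. `mc < 5%` for the
#' risk-bounding goal) and, when none qualify, falls back to the breakpoints
#' optimizing that quantity and flags the class infeasible. Final ties go to
#' the goal's tie-break policy.
#'
#' @param curve A single class's slice of a [rate_curve()] (one row per
#'   breakpoint).
#' @param goal A [goal_spec()].
#' @return A one-row tibble: `class`, `tau`, `tuning_cc`, `tuning_mc`,
#'   `tuning_uc`, `n_truth`, `feasible` (`FALSE` only when a bounded
#'   objective had to fall back).
#' @export
select_threshold <- function(curve, goal) {
  stopifnot(inherits(goal, "goal_spec"))
  if (nrow(curve) == 0) {
    abort("Cannot select a threshold from an empty rate curve",
          class = "rejectr_selection_error")
  }
  if (length(unique(curve$class)) != 1) {
    abort("`curve` must contain a single class",
          class = "rejectr_selection_error")
  }
  cand <- curve
  feasible <- TRUE
  for (obj in goal_objectives(goal)) {
    v <- cand[[obj$quantity]]
    if (!is.null(obj$bound)) {
      ok <- if (obj$direction == "min") v < obj$bound else v > obj$bound
      if (any(ok)) {
        cand <- cand[ok, , drop = FALSE]
      } else {
        feasible <- FALSE
        best <- if (obj$direction == "min") min(v) else max(v)
        cand <- cand[v == best, , drop = FALSE]
      }
    } else {
      best <- if (obj$direction == "min") min(v) else max(v)
      cand <- cand[v == best, , drop = FALSE]
    }
  }
  row <- if (goal$tie_break == "smallest_tau") {
    cand[which.min(cand$tau), , drop = FALSE]
  } else {
    cand[which.max(cand$tau), , drop = FALSE]
  }
  tibble(
    class = row$class, tau = row$tau,
    tuning_cc = row$cc, tuning_mc = row$mc, tuning_uc = row$uc,
    n_truth = row$n_truth, feasible = feasible
  )
}

new_threshold_set <- function(goal, entries, provenance, fallback) {
  structure(
    list(goal = goal, entries = as_tibble(entries),
         provenance = provenance, fallback = fallback),
    class = "threshold_set"
  )
}

#' Tune one confidence threshold per class
#'
#' The tuning phase: on an independent scored dataset, build each class's
#' rate curve over its ground-truth records and select the threshold meeting
#' the goal. Classes declared in the class set but never observed as ground
#' truth get the `ALWAYS_UNSURE` sentinel (`tau = NA`): with no data there is
#' no risk estimate, and rejecting everything is the conservative action.
#'
#' @param table A [prediction_table()] of tuning-set classifier outputs.
#' @param goal A [goal_spec()]; default `goal_spec("g3")`.
#' @param fallback Policy when, at application time, a record's predicted
#'   class has no entry: `"always_unsure"` (default), `"accept"`, or
#'   `"error"`.
#' @return A `threshold_set`: the goal, one entry per class (threshold plus
#'   the tuning rates achieved at it), the fallback policy, and provenance of
#'   the tuning table (record count, per-class counts, content hash).
#' @examples
#' tab <- simulate_predictions(simulation_config(
#'   class_labels = c("a", "b"), n_per_class = 50, seed = 1
#' ))
#' tune(tab, goal_spec("g3"))
#' @export
tune <- function(table, goal = goal_spec("g3"),
                 fallback = c("always_unsure", "accept", "error")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(goal, "goal_spec"))
  if (nrow(table) == 0) {
    abort("Cannot tune thresholds on an empty table",
          class = "rejectr_tuning_error")
  }
  cs <- class_set(table)
  observed <- unique(table$true_class)
  unobserved <- setdiff(cs, observed)
  if (length(unobserved) > 0) {
    warn(paste0("No ground-truth records for class(es) ",
                paste(unobserved, collapse = ", "),
                "; assigning ALWAYS_UNSURE."))
  }
  curves <- rate_curve(table, classes = intersect(cs, observed))
  entries <- purrr::map_dfr(split(curves, curves$class),
                            select_threshold, goal = goal)
  if (length(unobserved) > 0) {
    entries <- bind_rows(entries, tibble(
      class = unobserved, tau = NA_real_,
      tuning_cc = NA_real_, tuning_mc = NA_real_, tuning_uc = NA_real_,
      n_truth = 0L, feasible = NA
    ))
  }
  entries <- arrange(entries, .data$class)
  class_counts <- as.list(table(table$true_class))
  provenance <- list(
    n_records = nrow(table),
    class_counts = class_counts,
    content_hash = rlang::hash(list(
      table$item_id, table$true_class, table$predicted_class,
      table$top_score
    ))
  )
  new_threshold_set(goal, entries, provenance, fallback)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> goal ", x$goal$goal_id, ", ",
      nrow(x$entries), " classes, tuned on ",
      x$provenance$n_records %||% NA, " records\n", sep = "")
  print(x$entries, n = 10)
  invisible(x)
}

#' Tidy a threshold set
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return One row per class: `class`, `tau` (`NA` for always-unsure
#'   classes), the tuning rates at `tau`, `n_truth` and the feasibility flag.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  x$entries
}

#' @rdname tidy.threshold_set
#' @return For `glance`, a one-row summary: goal, number of classes,
#'   infeasible count, mean tuning rates, tuning-set size.
#' @method glance threshold_set
#' @export
glance.threshold_set <- function(x, ...) {
  e <- x$entries
  tibble(
    goal = x$goal$goal_id,
    n_classes = nrow(e),
    n_always_unsure = sum(is.na(e$tau)),
    n_infeasible = sum(!e$feasible, na.rm = TRUE),
    mean_tau = mean(e$tau, na.rm = TRUE),
    mean_tuning_cc = mean(e$tuning_cc, na.rm = TRUE),
    mean_tuning_mc = mean(e$tuning_mc, na.rm = TRUE),
    n_records = x$provenance$n_records %||% NA_integer_
  )
}
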