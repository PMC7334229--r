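#' Read a prediction table from delimited text
#'
#' Two dialects are supported. The *long* dialect has columns `item_id`,
#' `true_class`, `predicted_class`, `score` (the top softmax score). The
#' *wide* dialect has `item_id`, `true_class`, then one score column per
#' class (either bare class labels or `score_<class>` headers); the predicted
#' class and top score are derived as the argmax column and its value.
#' The delimiter (comma or tab) is sniffed from the header line.
#'
#' Scores reported on a 0-100 display scale are detected (any value > 1
#' present) and divided by 100, with a message; internally all scores live on
#' \[0, 1\].
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param dialect `"auto"` (default, decided from the header), `"long"` or
#'   `"wide"`.
#' @param class_set Optional extra class labels to declare (long dialect
#'   only; wide tables declare their classes through their columns).
#' @return A validated [prediction_table()].
#' @export
read_predictions <- function(path, dialect = c("auto", "long", "wide"),
                             class_set = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "rejectr_io_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (dialect == "auto") {
    dialect <- if ("score" %in% names(raw) &&
                   "predicted_class" %in% names(raw)) "long" else "wide"
  }

  if (dialect == "long") {
    required <- c("item_id", "true_class", "predicted_class", "score")
    miss <- setdiff(required, names(raw))
    if (length(miss) > 0) {
      abort(paste0("Long-dialect file is missing column(s): ",
                   paste(miss, collapse = ", ")),
            class = "rejectr_format_error")
    }
    scores <- rescale_scores(as.double(raw$score), path)
    out <- tibble(
      item_id = as.character(raw$item_id),
      true_class = as.character(raw$true_class),
      predicted_class = as.character(raw$predicted_class),
      top_score = scores
    )
    check_score_range(out$top_score)
    return(prediction_table(out, class_set = class_set))
  }

  # wide dialect: everything beyond item_id/true_class is a per-class score
  required <- c("item_id", "true_class")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Wide-dialect file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "rejectr_format_error")
  }
  class_cols <- setdiff(names(raw), required)
  if (length(class_cols) < 2) {
    abort("Wide-dialect file needs at least two class score columns",
          class = "rejectr_format_error")
  }
  labels <- sub("^score_", "", class_cols)
  m <- as.matrix(raw[class_cols])
  storage.mode(m) <- "double"
  m <- rescale_scores(m, path)
  check_score_range(as.vector(m))
  top_idx <- max.col(m, ties.method = "first")
  out <- tibble(
    item_id = as.character(raw$item_id),
    true_class = as.character(raw$true_class),
    predicted_class = labels[top_idx],
    top_score = m[cbind(seq_len(nrow(m)), top_idx)]
  )
  colnames(m) <- paste0("score_", labels)
  out <- dplyr::bind_cols(out, as_tibble(m))
  prediction_table(out, class_set = labels)
}

rescale_scores <- function(scores, path) {
  if (any(scores > 1, na.rm = TRUE)) {
    inform(paste0("Scores in '", path,
                  "' look like a 0-100 scale; dividing by 100."))
    scores <- scores / 100
  }
  scores
}

check_score_range <- function(scores) {
  bad <- which(!is.finite(scores) | scores < 0 | scores > 1)
  if (length(bad) > 0) {
    abort(paste0("Score outside [0, 1] after scale detection at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")),
          class = "rejectr_validation_error")
  }
  invisible(scores)
}

#' Write a prediction table to delimited text
#'
#' Scores are serialized on the \[0, 1\] scale with full double precision, so
#' `read_predictions(write_predictions(t))` round-trips record for record. In
#' the wide dialect the file carries one `score_<class>` column per class in
#' class-set order; a table without full score vectors cannot be written wide.
#'
#' @param table A [prediction_table()].
#' @param path Output file path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(table, path, dialect = c("long", "wide"),
                              delim = ",") {
  dialect <- match.arg(dialect)
  validate_predictions(table)
  if (dialect == "long") {
    out <- tibble(
      item_id = table$item_id,
      true_class = table$true_class,
      predicted_class = table$predicted_class,
      score = table$top_score
    )
  } else {
    sc <- score_columns(table)
    if (length(sc) == 0) {
      abort("Wide dialect requires full score vectors (score_* columns)",
            class = "rejectr_format_error")
    }
    cs <- class_set(table)
    out <- dplyr::bind_cols(
      tibble(item_id = table$item_id, true_class = table$true_class),
      table[paste0("score_", cs)]
    )
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Read / write a tuned threshold set
#'
#' Threshold sets are persisted as JSON with a `format_version` field, the
#' goal (and its misclassification bound where relevant), the fallback policy
#' for predicted classes missing from the set, per-class entries
#' (`class`, `tau`, tuning rates, feasibility flag) and the tuning-table
#' provenance. `tau` is a number in \[0, 1\] or the sentinel string
#' `"ALWAYS_UNSURE"` (represented as `NA` in the in-memory tibble), meaning
#' every prediction of that class is rejected.
#'
#' @param path JSON file path.
#' @return For `read_thresholds`, a `threshold_set` object; for
#'   `write_thresholds`, `path` invisibly.
#' @seealso [tune()], which produces threshold sets.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "rejectr_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  goal_id <- obj$goal$goal_id %||% obj$goal
  if (!is.character(goal_id) || !goal_id %in% c("g1", "g2", "g3", "custom")) {
    abort(paste0("Unknown goal id in threshold file: ",
                 deparse(goal_id)), class = "rejectr_format_error")
  }
  goal <- goal_spec(
    goal_id,
    mc_bound = obj$goal$mc_bound %||% 0.05,
    objectives = parse_objectives(obj$goal$objectives),
    tie_break = obj$goal$tie_break %||% "smallest_tau"
  )
  entries <- purrr::map_dfr(obj$entries, function(e) {
    tau <- e$tau
    if (identical(tau, ALWAYS_UNSURE)) {
      tau <- NA_real_
    } else {
      tau <- as.double(tau)
      if (!is.finite(tau) || tau < 0 || tau > 1) {
        abort(paste0("tau outside [0, 1] for class '", e$class, "'"),
              class = "rejectr_validation_error")
      }
    }
    tibble(
      class = as.character(e$class),
      tau = tau,
      tuning_cc = as.double(e$tuning_cc %||% NA_real_),
      tuning_mc = as.double(e$tuning_mc %||% NA_real_),
      tuning_uc = as.double(e$tuning_uc %||% NA_real_),
      n_truth = as.integer(e$n_truth %||% NA_integer_),
      feasible = as.logical(e$feasible %||% NA)
    )
  })
  new_threshold_set(
    goal = goal,
    entries = entries,
    provenance = obj$provenance %||% list(),
    fallback = obj$fallback %||% "always_unsure"
  )
}

#' @rdname read_thresholds
#' @param set A `threshold_set` as produced by [tune()].
#' @export
write_thresholds <- function(set, path) {
  stopifnot(inherits(set, "threshold_set"))
  entries <- purrr::pmap(set$entries, function(class, tau, tuning_cc,
                                               tuning_mc, tuning_uc,
                                               n_truth, feasible, ...) {
    list(
      class = class,
      tau = if (is.na(tau)) ALWAYS_UNSURE else tau,
      tuning_cc = tuning_cc, tuning_mc = tuning_mc, tuning_uc = tuning_uc,
      n_truth = n_truth, feasible = feasible
    )
  })
  obj <- list(
    format_version = "1.0",
    goal = list(
      goal_id = set$goal$goal_id,
      mc_bound = set$goal$mc_bound,
      objectives = set$goal$objectives,
      tie_break = set$goal$tie_break
    ),
    fallback = set$fallback,
    entries = entries,
    provenance = set$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

parse_objectives <- function(objs) {
  if (is.null(objs) || length(objs) == 0) {
    return(NULL)
  }
  purrr::map(objs, function(o) {
    list(quantity = o$quantity, direction = o$direction,
         bound = o$bound %||% NULL)
  })
}
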