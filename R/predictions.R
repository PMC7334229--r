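#' Build a prediction table from classifier outputs
#'
#' A prediction table is a tibble with one row per scored item and columns
#' `item_id`, `true_class`, `predicted_class` and `top_score` (the maximum
#' softmax score, on the unit scale). Full score vectors, when available, are
#' stored in additional columns named `score_<class>`. The set of classes the
#' classifier can emit is carried in the `class_set` attribute; it is the
#' union of the labels observed in the table and any labels declared via
#' `class_set`.
#'
#' @param x A data frame with at least the four core columns above. Extra
#'   `score_<class>` columns are kept and validated.
#' @param class_set Optional character vector of class labels to declare in
#'   addition to those observed. Labels are case-sensitive opaque strings.
#' @param validate If `TRUE` (default), check invariants and fail loudly.
#' @return A tibble of class `prediction_table` with a `class_set` attribute.
#' @examples
#' prediction_table(data.frame(
#'   item_id = c("r1", "r2"), true_class = "a",
#'   predicted_class = c("a", "b"), top_score = c(0.95, 0.90)
#' ))
#' @export
prediction_table <- function(x, class_set = NULL, validate = TRUE) {
  x <- as_tibble(x)
  required <- c("item_id", "true_class", "predicted_class", "top_score")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Prediction table is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "rejectr_format_error"
    )
  }
  x$item_id <- as.character(x$item_id)
  x$true_class <- as.character(x$true_class)
  x$predicted_class <- as.character(x$predicted_class)
  x$top_score <- as.double(x$top_score)

  observed <- union(unique(x$true_class), unique(x$predicted_class))
  cs <- union(observed, as.character(class_set %||% character()))
  cs <- sort(cs)
  attr(x, "class_set") <- cs
  class(x) <- unique(c("prediction_table", class(x)))
  if (validate) validate_predictions(x)
  x
}

#' Class set of a prediction table
#'
#' @param x A prediction table (or any data frame with prediction columns).
#' @return Character vector of class labels: the `class_set` attribute if
#'   present, otherwise the union of observed true and predicted labels.
#' @export
class_set <- function(x) {
  cs <- attr(x, "class_set", exact = TRUE)
  if (!is.null(cs)) {
    return(cs)
  }
  sort(union(unique(as.character(x$true_class)),
             unique(as.character(x$predicted_class))))
}

score_columns <- function(x) {
  grep("^score_", names(x), value = TRUE)
}

#' Validate a prediction table
#'
#' Checks the structural invariants: unique item ids, scores in \[0, 1\],
#' labels drawn from the class set, the reserved `UNSURE` label unused, and —
#' when full score vectors are present — that scores sum to 1 (tolerance
#' 1e-6), that the predicted class attains the maximum, and that `top_score`
#' equals that maximum (tolerance 1e-9).
#'
#' @param x A prediction table.
#' @return `x`, invisibly, if valid; otherwise an error of class
#'   `rejectr_validation_error`.
#' @export
validate_predictions <- function(x) {
  fail <- function(msg) abort(msg, class = "rejectr_validation_error")
  if (anyDuplicated(x$item_id)) {
    dup <- x$item_id[duplicated(x$item_id)][1]
    fail(paste0("Duplicate item_id: '", dup, "'"))
  }
  bad <- which(!is.finite(x$top_score) | x$top_score < 0 | x$top_score > 1)
  if (length(bad) > 0) {
    fail(paste0("top_score outside [0, 1] at row(s): ",
                paste(utils::head(bad, 5), collapse = ", ")))
  }
  cs <- class_set(x)
  if (UNSURE %in% cs) {
    fail(paste0("'", UNSURE, "' is a reserved label and cannot be a class"))
  }
  stray <- setdiff(union(x$true_class, x$predicted_class), cs)
  if (length(stray) > 0) {
    fail(paste0("Label(s) outside the declared class set: ",
                paste(stray, collapse = ", ")))
  }

  sc <- score_columns(x)
  if (length(sc) > 0) {
    labels <- sub("^score_", "", sc)
    stray_sc <- setdiff(labels, cs)
    if (length(stray_sc) > 0) {
      fail(paste0("Score column(s) for undeclared class(es): ",
                  paste(stray_sc, collapse = ", ")))
    }
    m <- as.matrix(x[sc])
    if (any(!is.finite(m) | m < 0 | m > 1)) {
      fail("Score vector entries must lie in [0, 1]")
    }
    sums <- rowSums(m)
    bad_sum <- which(abs(sums - 1) > 1e-6)
    if (length(bad_sum) > 0) {
      fail(paste0("Score vector does not sum to 1 at row(s): ",
                  paste(utils::head(bad_sum, 5), collapse = ", ")))
    }
    top <- apply(m, 1L, max)
    if (any(abs(top - x$top_score) > 1e-9)) {
      fail("top_score must equal the maximum of the score vector")
    }
    pred_score <- m[cbind(seq_len(nrow(m)),
                          match(paste0("score_", x$predicted_class), sc))]
    if (any(pred_score < top - 1e-9)) {
      fail("predicted_class must attain the maximum score")
    }
  }
  invisible(x)
}
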