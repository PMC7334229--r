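#' Plot per-class rate curves
#'
#' Stacked-area view of the coverage-risk trade-off: for each class, the
#' correct, misclassified and unsure rates as step functions of the
#' confidence threshold. The misclassified band shrinking toward zero as the
#' threshold grows — at the price of a growing unsure band — is the whole
#' point of the method.
#'
#' @param curve A [rate_curve()] tibble (one or more classes).
#' @return A ggplot object, faceted by class.
#' @export
plot_rate_curve <- function(curve) {
  long <- curve %>%
    select("class", "tau", "cc", "mc", "uc") %>%
    tidyr::pivot_longer(c("cc", "mc", "uc"),
                        names_to = "outcome", values_to = "rate") %>%
    mutate(outcome = factor(.data$outcome, levels = c("mc", "uc", "cc"),
                            labels = c("misclassified", "unsure",
                                       "correct")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$rate,
                                     fill = .data$outcome)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_manual(values = c(misclassified = "#d1495b",
                                          unsure = "#edae49",
                                          correct = "#00798c")) +
    ggplot2::labs(x = "confidence threshold", y = "rate", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-goal benchmark comparison
#'
#' Bar chart of the aggregate correct / misclassified / unsure rates for
#' each goal next to the raw no-post-processing baseline.
#'
#' @param x A `rejectr_benchmark` from [run_benchmark()].
#' @return A ggplot object.
#' @export
plot_goal_comparison <- function(x) {
  stopifnot(inherits(x, "rejectr_benchmark"))
  long <- x$summary %>%
    select("goal", "mean_cc", "mean_mc", "mean_uc") %>%
    tidyr::pivot_longer(-"goal", names_to = "outcome",
                        values_to = "rate") %>%
    mutate(outcome = factor(.data$outcome,
                            levels = c("mean_cc", "mean_mc", "mean_uc"),
                            labels = c("correct", "misclassified",
                                       "unsure")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$goal, y = .data$rate,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(misclassified = "#d1495b",
                                          unsure = "#edae49",
                                          correct = "#00798c")) +
    ggplot2::labs(x = NULL, y = "mean rate across classes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot rejectr_benchmark
#' @export
autoplot.rejectr_benchmark <- function(object, ...) {
  plot_goal_comparison(object)
}

#' @method autoplot threshold_set
#' @export
autoplot.threshold_set <- function(object, ...) {
  e <- object$entries[!is.na(object$entries$tau), , drop = FALSE]
  ggplot2::ggplot(e, ggplot2::aes(x = .data$class, y = .data$tau)) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$class, yend = 0)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "tuned confidence threshold") +
    ggplot2::theme_minimal()
}
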