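#' Configure a synthetic score-table simulation
#'
#' The simulator emulates the outputs of a trained multi-class image
#' classifier — not the images or the network — with the structure seen in
#' practice: class-dependent correctness probabilities, and score
#' distributions in which both correct and wrong predictions frequently
#' receive very high softmax scores, so that no single global cutoff
#' separates them.
#'
#' Two score models are available:
#'
#' * `"dirichlet"` — the full score vector of each record is drawn from a
#'   Dirichlet distribution with base concentration `alpha0` on the
#'   non-predicted classes and `alpha0 + beta` on the predicted class
#'   (redrawn until the predicted class attains the maximum). Correct
#'   predictions use the sharper base concentration `alpha0_correct`,
#'   concentrating their top scores in the extreme upper sliver the way a
#'   well-trained network's correct classifications do, while wrong
#'   predictions still reach very high scores — overlapping distributions
#'   that only per-class thresholds near the top can pull apart. The
#'   defaults (`alpha0 = 0.04`, `alpha0_correct = 0.012`, `beta = 1.2`,
#'   20 classes) are calibrated once so roughly 80% of top scores land in
#'   \[0.6, 1\] and about a fifth of wrong predictions still score above
#'   0.9.
#' * `"uniform_pair"` — the top score of a correct prediction is uniform on
#'   `correct_interval` and of a wrong one uniform on `wrong_interval`. This
#'   model exists to admit the closed-form oracle [expected_rates()]; it is
#'   deliberately simple, not realistic.
#'
#' @param class_labels Character vector of class names (>= 2).
#' @param n_per_class Records per class; a single count or one per class.
#' @param correctness_prob Per-class probability that the prediction is
#'   correct; a single value or one per class. Default 0.78.
#' @param confusion_weights Optional matrix (classes x classes, rows summing
#'   to 1 off-diagonal with zero diagonal) giving, for each true class, the
#'   distribution of wrong predicted labels; default uniform over the other
#'   classes.
#' @param score_model `"dirichlet"` (default) or `"uniform_pair"`.
#' @param alpha0,alpha0_correct,beta Dirichlet base concentrations for the
#'   non-predicted classes (wrong and correct predictions respectively) and
#'   the predicted-class boost.
#' @param correct_interval,wrong_interval Score intervals for the
#'   `uniform_pair` model, each within \[0, 1\] with `a < b`.
#' @param full_vector If `TRUE`, emit `score_<class>` columns with the full
#'   vector (always available under `dirichlet`; under `uniform_pair` the
#'   remainder `1 - top` is spread equally over the other classes, redrawing
#'   the top score in the rare case that would dethrone the argmax).
#' @param seed Integer seed; the single source of randomness.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(class_labels = sprintf("sp%02d", 1:20),
                              n_per_class = 500,
                              correctness_prob = 0.78,
                              confusion_weights = NULL,
                              score_model = c("dirichlet", "uniform_pair"),
                              alpha0 = 0.04, alpha0_correct = 0.012,
                              beta = 1.2,
                              correct_interval = c(0.8, 1.0),
                              wrong_interval = c(0.5, 0.9),
                              full_vector = FALSE,
                              seed = 1L) {
  score_model <- match.arg(score_model)
  cfg_fail <- function(msg) abort(msg, class = "rejectr_config_error")
  class_labels <- as.character(class_labels)
  n <- length(class_labels)
  if (n < 2 || anyDuplicated(class_labels)) {
    cfg_fail("`class_labels` must be >= 2 distinct labels")
  }
  if (UNSURE %in% class_labels) {
    cfg_fail(paste0("'", UNSURE, "' is reserved and cannot be simulated"))
  }
  n_per_class <- rep_len(as.integer(n_per_class), n)
  if (any(n_per_class < 1)) cfg_fail("`n_per_class` must be >= 1")
  correctness_prob <- rep_len(as.double(correctness_prob), n)
  if (any(correctness_prob < 0 | correctness_prob > 1)) {
    cfg_fail("`correctness_prob` must lie in [0, 1]")
  }
  if (is.null(confusion_weights)) {
    confusion_weights <- matrix(1 / (n - 1), n, n,
                                dimnames = list(class_labels, class_labels))
    diag(confusion_weights) <- 0
  } else {
    confusion_weights <- as.matrix(confusion_weights)
    if (!identical(dim(confusion_weights), c(n, n)) ||
        any(diag(confusion_weights) != 0) ||
        any(confusion_weights < 0) ||
        any(abs(rowSums(confusion_weights) - 1) > 1e-9)) {
      cfg_fail(paste0("`confusion_weights` must be an n x n matrix with ",
                      "zero diagonal and rows summing to 1"))
    }
    dimnames(confusion_weights) <- list(class_labels, class_labels)
  }
  check_interval <- function(iv, nm) {
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > 1 || iv[1] >= iv[2]) {
      cfg_fail(paste0("`", nm, "` must be [a, b] within [0, 1] with a < b"))
    }
  }
  check_interval(correct_interval, "correct_interval")
  check_interval(wrong_interval, "wrong_interval")
  if (alpha0 <= 0 || alpha0_correct <= 0 || beta <= 0) {
    cfg_fail("`alpha0`, `alpha0_correct` and `beta` must be > 0")
  }

  structure(
    list(class_labels = class_labels, n_per_class = n_per_class,
         correctness_prob = correctness_prob,
         confusion_weights = confusion_weights,
         score_model = score_model, alpha0 = alpha0,
         alpha0_correct = alpha0_correct, beta = beta,
         correct_interval = as.double(correct_interval),
         wrong_interval = as.double(wrong_interval),
         full_vector = isTRUE(full_vector), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a prediction table
#'
#' Draws, for each record of true class i, a predicted class (equal to i
#' with that class's correctness probability, otherwise from the confusion
#' weights) and a score under the configured score model. Fully reproducible
#' from the config's seed; the caller's RNG state is untouched.
#'
#' @param config A [simulation_config()].
#' @return A validated [prediction_table()].
#' @examples
#' cfg <- simulation_config(class_labels = c("a", "b"), n_per_class = 100,
#'                          score_model = "uniform_pair", seed = 7)
#' tab <- simulate_predictions(cfg)
#' raw_rates(tab)
#' @export
simulate_predictions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- config$class_labels
  n_class <- length(labels)
  true_idx <- rep(seq_len(n_class), times = config$n_per_class)
  m <- length(true_idx)

  # restore the caller's RNG state on exit: the config seed is the only
  # source of randomness, without clobbering an enclosing simulation
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)

  correct <- runif(m) < config$correctness_prob[true_idx]
  pred_idx <- true_idx
  wrong <- which(!correct)
  if (length(wrong) > 0) {
    pred_idx[wrong] <- vapply(wrong, function(k) {
      sample.int(n_class, 1L, prob = config$confusion_weights[true_idx[k], ])
    }, integer(1))
  }

  if (config$score_model == "uniform_pair") {
    iv_a <- ifelse(correct, config$correct_interval[1],
                   config$wrong_interval[1])
    iv_b <- ifelse(correct, config$correct_interval[2],
                   config$wrong_interval[2])
    top <- runif(m, iv_a, iv_b)
    if (config$full_vector) {
      # remainder spread equally; redraw tops that would lose the argmax
      bad <- which((1 - top) / (n_class - 1) >= top)
      while (length(bad) > 0) {
        top[bad] <- runif(length(bad), iv_a[bad], iv_b[bad])
        bad <- bad[(1 - top[bad]) / (n_class - 1) >= top[bad]]
      }
      mat <- matrix((1 - top) / (n_class - 1), m, n_class)
      mat[cbind(seq_len(m), pred_idx)] <- top
    }
  } else {
    mat <- matrix(NA_real_, m, n_class)
    todo <- seq_len(m)
    while (length(todo) > 0) {
      base <- ifelse(correct[todo], config$alpha0_correct, config$alpha0)
      draws <- matrix(rep(base, each = n_class), ncol = n_class,
                      byrow = TRUE)
      draws[cbind(seq_along(todo), pred_idx[todo])] <-
        base + config$beta
      g <- matrix(stats::rgamma(length(todo) * n_class, shape = draws),
                  nrow = length(todo))
      g <- g / rowSums(g)
      ok <- max.col(g, ties.method = "first") == pred_idx[todo]
      mat[todo[ok], ] <- g[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    top <- mat[cbind(seq_len(m), pred_idx)]
  }

  out <- tibble(
    item_id = sprintf("sim%06d", seq_len(m)),
    true_class = labels[true_idx],
    predicted_class = labels[pred_idx],
    top_score = top
  )
  if (config$full_vector || config$score_model == "dirichlet") {
    colnames(mat) <- paste0("score_", labels)
    out <- dplyr::bind_cols(out, as_tibble(mat))
  }
  prediction_table(out, class_set = labels)
}

#' Closed-form expected rates under the uniform-pair score model
#'
#' The analytic oracle the simulator is checked against. For a class with
#' correctness probability p, correct scores uniform on `[a_c, b_c]` and
#' wrong scores uniform on `[a_w, b_w]`, a threshold `tau` keeps a correct
#' prediction with probability `len((max(tau, a_c), b_c]) / (b_c - a_c)`, so
#' `E[cc] = p * that`, similarly for `E[mc]` with `1 - p` and the wrong
#' interval, and `E[uc] = 1 - E[cc] - E[mc]`.
#'
#' @param config A [simulation_config()] with `score_model = "uniform_pair"`.
#' @param tau Threshold in \[0, 1\].
#' @param classes Classes to report; default all.
#' @return A tibble like [rates_at_threshold()] but with expected values.
#' @export
expected_rates <- function(config, tau, classes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$score_model != "uniform_pair") {
    abort("expected_rates is only defined for the uniform_pair score model",
          class = "rejectr_unsupported_model_error")
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    abort("`tau` must be a single number in [0, 1]",
          class = "rejectr_domain_error")
  }
  classes <- classes %||% config$class_labels
  surv <- function(iv) {
    max(0, min(1, (iv[2] - max(tau, iv[1])) / (iv[2] - iv[1])))
  }
  purrr::map_dfr(classes, function(cl) {
    i <- match(cl, config$class_labels)
    p <- config$correctness_prob[i]
    cc <- p * surv(config$correct_interval)
    mc <- (1 - p) * surv(config$wrong_interval)
    tibble(class = cl, tau = tau, cc = cc, mc = mc, uc = 1 - cc - mc,
           cov = cc + mc, n_truth = config$n_per_class[i])
  })
}
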