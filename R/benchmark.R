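#' Run the tune/apply benchmark protocols on simulated data
#'
#' Two experiment designs, mirroring how threshold post-processing is
#' evaluated in practice:
#'
#' * `"self"` — tune the thresholds on a table and evaluate on the *same*
#'   table (the idealised upper bound: tuning and test conditions identical).
#' * `"cross"` — tune on one table and evaluate on an independently
#'   simulated table from the same generator (the realistic protocol: the
#'   tuning set is independent of the test set).
#'
#' For each goal the per-class application rates are aggregated across
#' classes (unweighted mean and sample sd) and reported next to the raw
#' no-post-processing baseline.
#'
#' @param config A [simulation_config()] describing the generator. Its seed
#'   produces the tuning table; the independent test table of the cross
#'   design uses `seed + 1`.
#' @param goals Character vector of goal ids to compare; default
#'   `c("g1", "g2", "g3")`.
#' @param design `"cross"` (default) or `"self"`.
#' @param mc_bound Misclassification bound passed to the `g2` goal.
#' @return A `rejectr_benchmark` object: `$summary` (one row per goal plus a
#'   `raw` row with aggregate `mean_cc`, `mean_mc`, `mean_uc`,
#'   `mean_accuracy` and their sds), `$per_class` (per goal x class rates),
#'   `$thresholds` (a list of `threshold_set`s), and the design metadata.
#' @examples
#' cfg <- simulation_config(class_labels = c("a", "b", "c"),
#'                          n_per_class = 200, seed = 42)
#' run_benchmark(cfg, design = "self")
#' @export
run_benchmark <- function(config, goals = c("g1", "g2", "g3"),
                          design = c("cross", "self"), mc_bound = 0.05) {
  design <- match.arg(design)
  stopifnot(inherits(config, "simulation_config"))
  tune_tab <- simulate_predictions(config)
  test_tab <- if (design == "self") {
    tune_tab
  } else {
    cfg2 <- config
    cfg2$seed <- config$seed + 1L
    simulate_predictions(cfg2)
  }

  thresholds <- list()
  per_class <- list()
  summary_rows <- list()
  for (g in goals) {
    spec <- goal_spec(g, mc_bound = mc_bound)
    ts <- tune(tune_tab, spec)
    ev <- evaluate_decisions(apply_thresholds(test_tab, ts))
    thresholds[[g]] <- ts
    per_class[[g]] <- mutate(tidy(ev), goal = g, .before = 1)
    gl <- glance(ev)
    summary_rows[[g]] <- tibble(
      goal = g,
      mean_cc = gl$mean_cc, sd_cc = gl$sd_cc,
      mean_mc = gl$mean_mc, sd_mc = gl$sd_mc,
      mean_uc = gl$mean_uc, sd_uc = gl$sd_uc,
      mean_accuracy = gl$mean_accuracy, sd_accuracy = gl$sd_accuracy,
      n_accuracy_undefined = gl$n_accuracy_undefined
    )
  }

  raw <- raw_rates(test_tab)
  raw$accuracy <- purrr::map_dbl(raw$class, function(cl) {
    kept <- test_tab$predicted_class == cl
    if (!any(kept)) NA_real_ else mean(test_tab$true_class[kept] == cl)
  })
  acc <- summarize_rates(raw$accuracy)
  summary_rows[["raw"]] <- tibble(
    goal = "raw",
    mean_cc = mean(raw$cc), sd_cc = sd(raw$cc),
    mean_mc = mean(raw$mc), sd_mc = sd(raw$mc),
    mean_uc = 0, sd_uc = 0,
    mean_accuracy = acc$mean, sd_accuracy = acc$sd,
    n_accuracy_undefined = acc$n_na
  )

  structure(
    list(summary = bind_rows(summary_rows),
         per_class = bind_rows(per_class),
         raw_per_class = raw,
         thresholds = thresholds,
         design = design, config = config),
    class = "rejectr_benchmark"
  )
}

#' @export
print.rejectr_benchmark <- function(x, ...) {
  cat("<rejectr_benchmark> design: ", x$design, ", ",
      length(x$config$class_labels), " classes\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method tidy rejectr_benchmark
#' @export
tidy.rejectr_benchmark <- function(x, ...) {
  x$per_class
}

#' @method glance rejectr_benchmark
#' @export
glance.rejectr_benchmark <- function(x, ...) {
  x$summary
}

#' Render an evaluation or benchmark as a report table
#'
#' Produces the standard report layout: one row per class with the raw and
#' per-goal rates/precision, followed by `Mean` and `Standard deviation`
#' footer rows (unweighted across classes; undefined precisions render as
#' `NA` and are excluded from the footers). Rates are shown on the 0-100
#' percentage scale by default, matching how such tables are usually read;
#' machine-readable output for further computation should stay on the unit
#' scale (`scale = 1`).
#'
#' @param x A `rejectr_evaluation` or `rejectr_benchmark`.
#' @param format `"tibble"` (default), `"csv"`, `"json"` or `"markdown"`.
#' @param path Output file path; required for `"csv"` and `"json"`.
#' @param scale 100 (default) or 1; multiplies the rate columns for display.
#'   Precision columns follow the same scale.
#' @return The report tibble (invisibly for file formats). All formats carry
#'   identical numeric content.
#' @export
render_report <- function(x, format = c("tibble", "csv", "json", "markdown"),
                          path = NULL, scale = 100) {
  format <- match.arg(format)
  if (!scale %in% c(1, 100)) {
    abort("`scale` must be 1 or 100", class = "rejectr_usage_error")
  }
  body <- report_body(x)
  num_cols <- setdiff(names(body), "class")
  footer <- bind_rows(
    tibble(class = "Mean",
           !!!purrr::map(body[num_cols], ~ summarize_rates(.x)$mean)),
    tibble(class = "Standard deviation",
           !!!purrr::map(body[num_cols], ~ summarize_rates(.x)$sd))
  )
  out <- bind_rows(body, footer)
  out[num_cols] <- lapply(out[num_cols], function(v) v * scale)

  if (format == "tibble") {
    return(out)
  }
  if (format == "markdown") {
    return(markdown_table(out))
  }
  if (is.null(path)) {
    abort("`path` is required for csv/json output",
          class = "rejectr_usage_error")
  }
  if (format == "csv") {
    readr::write_csv(out, path, na = "NA")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(out)
}

report_body <- function(x) {
  if (inherits(x, "rejectr_evaluation")) {
    td <- tidy(x)
    return(select(td, "class", raw_cc = "raw_cc", raw_mc = "raw_mc",
                  raw_accuracy = "raw_accuracy", cc = "cc", mc = "mc",
                  uc = "uc", accuracy = "accuracy"))
  }
  if (inherits(x, "rejectr_benchmark")) {
    raw <- select(x$raw_per_class, "class", raw_cc = "cc", raw_mc = "mc",
                  raw_accuracy = "accuracy")
    wide <- x$per_class %>%
      select("goal", "class", "cc", "mc", "uc", "accuracy") %>%
      tidyr::pivot_wider(names_from = "goal",
                         values_from = c("cc", "mc", "uc", "accuracy"),
                         names_glue = "{goal}_{.value}")
    return(left_join(raw, wide, by = "class"))
  }
  abort("Cannot render a report from this object",
        class = "rejectr_usage_error")
}

markdown_table <- function(df) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "NA", formatC(v, digits = 4,
                                                      format = "fg"))
    else as.character(v)
  }
  cells <- purrr::map(df, fmt)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(purrr::map_chr(cells, i), collapse = " | "), " |")
  })
  paste(c(header, sep, rows), collapse = "\n")
}
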