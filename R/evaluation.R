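#' Jackknife (leave-one-out) evaluation
#'
#' Evaluates a predictor backend by the jackknife test: each drug in the
#' dataset is predicted in turn with itself removed from the training set
#' and every other drug retained, and the prediction is correct iff it
#' equals the held-out drug's true group. The jackknife is the least
#' arbitrary cross-validation protocol — every sample is tested exactly
#' once against the maximal training set — and, up to tie-break randomness,
#' yields a unique result for a given dataset.
#'
#' No-prediction outcomes (empty neighbor set) count as incorrect and are
#' additionally reported in `n_no_prediction`. The master `seed` spawns a
#' per-query tie-breaking seed by counter, so the whole report is
#' reproducible and any single prediction can be re-run in isolation with
#' its own seed.
#'
#' @param drugs A drug table tibble with at least 2 records and 2 groups.
#' @param backend `"ontology"` or `"interaction"`.
#' @param g An [ontology_graph][parse_obo] (ontology backend).
#' @param interactions An interaction table (interaction backend).
#' @param seed Integer master seed.
#'
#' @return A `target_eval` object: list with `per_group` (tibble `group`,
#'   `n_correct`, `n_total`, `accuracy`), `overall` (same fields, one row),
#'   `n_no_prediction`, `protocol`, `seed`, `backend` and `predictions`
#'   (tibble with one row per query: `drug_id`, `truth`, `predicted`,
#'   `correct`, `tie_broken`, `n_neighbors`).
#' @seealso [independent_test()], [write_report()]
#' @export
jackknife <- function(drugs, backend = c("ontology", "interaction"),
                      g = NULL, interactions = NULL, seed = 1L) {
  backend <- match.arg(backend)
  if (nrow(drugs) < 2L || dplyr::n_distinct(drugs$group) < 2L) {
    stop("jackknife needs at least 2 records and 2 distinct groups",
         call. = FALSE)
  }
  preds <- purrr::map_dfr(seq_len(nrow(drugs)), function(i) {
    train <- drugs[-i, , drop = FALSE]
    stopifnot(!drugs$drug_id[i] %in% train$drug_id)
    p <- predict_target(
      train,
      query_terms = drugs$terms[[i]],
      query_id = drugs$drug_id[i],
      backend = backend, g = g, interactions = interactions,
      seed = query_seed(seed, i)
    )
    prediction_row(p, truth = drugs$group[i])
  })
  new_target_eval(preds, groups = unique(drugs$group),
                  protocol = "jackknife", seed = seed, backend = backend)
}

#' Independent-test evaluation
#'
#' Predicts every drug of a held-out test set against a fixed training set
#' (the model never sees the test drugs), producing the same report shape as
#' [jackknife()]. The two sets must be disjoint by drug id.
#'
#' @param train,test Drug table tibbles, disjoint by `drug_id`.
#' @inheritParams jackknife
#' @return A `target_eval` object with `protocol = "independent_test"`.
#' @export
independent_test <- function(train, test,
                             backend = c("ontology", "interaction"),
                             g = NULL, interactions = NULL, seed = 1L) {
  backend <- match.arg(backend)
  overlap <- intersect(train$drug_id, test$drug_id)
  if (length(overlap) > 0L) {
    stop("train and test sets overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  preds <- purrr::map_dfr(seq_len(nrow(test)), function(i) {
    p <- predict_target(
      train,
      query_terms = test$terms[[i]],
      query_id = test$drug_id[i],
      backend = backend, g = g, interactions = interactions,
      seed = query_seed(seed, i)
    )
    prediction_row(p, truth = test$group[i])
  })
  new_target_eval(preds, groups = unique(c(train$group, test$group)),
                  protocol = "independent_test", seed = seed,
                  backend = backend)
}

# Per-query tie-break seed spawned from the master seed by counter.
query_seed <- function(seed, i) {
  (as.integer(seed) + i * 7919L) %% 2147483587L
}

prediction_row <- function(p, truth) {
  tibble::tibble(
    drug_id = p$drug_id,
    truth = truth,
    predicted = p$predicted_group,
    correct = !is.na(p$predicted_group) && p$predicted_group == truth,
    tie_broken = p$tie_broken,
    n_neighbors = nrow(p$neighbors$members)
  )
}

new_target_eval <- function(predictions, groups, protocol, seed, backend) {
  counts <- predictions |>
    dplyr::group_by(group = .data$truth) |>
    dplyr::summarise(
      n_correct = sum(.data$correct),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  per_group <- tibble::tibble(group = sort(unique(groups))) |>
    dplyr::left_join(counts, by = "group") |>
    dplyr::mutate(
      n_correct = dplyr::coalesce(.data$n_correct, 0L),
      n_total = dplyr::coalesce(.data$n_total, 0L),
      accuracy = ifelse(.data$n_total > 0,
                        .data$n_correct / .data$n_total, NA_real_)
    )
  structure(
    list(
      per_group = per_group,
      overall = tibble::tibble(
        n_correct = sum(per_group$n_correct),
        n_total = sum(per_group$n_total),
        accuracy = sum(per_group$n_correct) / sum(per_group$n_total)
      ),
      n_no_prediction = sum(is.na(predictions$predicted)),
      protocol = protocol,
      seed = as.integer(seed),
      backend = backend,
      predictions = predictions
    ),
    class = "target_eval"
  )
}

#' @export
print.target_eval <- function(x, ...) {
  cat("Target-group prediction accuracy (", x$protocol, ", ",
      x$backend, " backend)\n\n", sep = "")
  fmt <- function(correct, total) {
    if (total == 0) "n/a" else sprintf("%.2f%%", 100 * correct / total)
  }
  w <- max(nchar(c(x$per_group$group, "Overall")))
  for (i in seq_len(nrow(x$per_group))) {
    cat(sprintf("  %-*s  %8s  (%d/%d)\n", w, x$per_group$group[i],
                fmt(x$per_group$n_correct[i], x$per_group$n_total[i]),
                x$per_group$n_correct[i], x$per_group$n_total[i]))
  }
  cat(sprintf("  %-*s  %8s  (%d/%d)\n", w, "Overall",
              fmt(x$overall$n_correct, x$overall$n_total),
              x$overall$n_correct, x$overall$n_total))
  if (x$n_no_prediction > 0) {
    cat("\n  No-prediction outcomes (counted incorrect): ",
        x$n_no_prediction, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy and summarize evaluation results
#'
#' `tidy()` on a `target_eval` returns the per-group accuracy table;
#' `glance()` returns a one-row overall summary. `tidy()` on a
#' `target_prediction` returns the vote tally.
#'
#' @param x A `target_eval` or `target_prediction` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.target_eval <- function(x, ...) {
  x$per_group
}

#' @rdname tidy.target_eval
#' @export
glance.target_eval <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    backend = x$backend,
    n_correct = x$overall$n_correct,
    n_total = x$overall$n_total,
    accuracy = x$overall$accuracy,
    n_no_prediction = x$n_no_prediction,
    seed = x$seed
  )
}

#' Plot per-group accuracy of an evaluation report
#'
#' Bar chart of per-group prediction accuracy with the overall accuracy as
#' a dashed reference line.
#'
#' @param object A `target_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.target_eval <- function(object, ...) {
  dat <- dplyr::filter(object$per_group, .data$n_total > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall$accuracy,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Prediction accuracy",
      title = sprintf("%s accuracy by target group (%s backend)",
                      object$protocol, object$backend),
      subtitle = sprintf("Overall %.2f%% (%d/%d)",
                         100 * object$overall$accuracy,
                         object$overall$n_correct, object$overall$n_total)
    ) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report as JSON
#'
#' Serializes a `target_eval` to JSON. Only integer counts are stored;
#' accuracies and percentages are always recomputed from the counts, so the
#' per-group/overall identity can never drift through rounding.
#' `read_report()` reconstructs an equal report (minus the per-prediction
#' detail rows, which are optional in the file).
#'
#' @param r A `target_eval` object.
#' @param path Output (input) file path.
#' @param predictions Include the per-prediction rows? Default `TRUE`.
#' @return `write_report()`: `path`, invisibly. `read_report()`: a
#'   `target_eval` object.
#' @export
write_report <- function(r, path, predictions = TRUE) {
  stopifnot(inherits(r, "target_eval"))
  obj <- list(
    protocol = r$protocol,
    backend = r$backend,
    seed = r$seed,
    n_no_prediction = r$n_no_prediction,
    per_group = r$per_group[, c("group", "n_correct", "n_total")],
    overall = list(n_correct = r$overall$n_correct,
                   n_total = r$overall$n_total)
  )
  if (predictions) obj$predictions <- r$predictions
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  per_group <- tibble::as_tibble(obj$per_group) |>
    dplyr::mutate(
      n_correct = as.integer(.data$n_correct),
      n_total = as.integer(.data$n_total),
      accuracy = ifelse(.data$n_total > 0,
                        .data$n_correct / .data$n_total, NA_real_)
    )
  predictions <- if (!is.null(obj$predictions)) {
    tibble::as_tibble(obj$predictions)
  } else {
    NULL
  }
  structure(
    list(
      per_group = per_group,
      overall = tibble::tibble(
        n_correct = as.integer(obj$overall$n_correct),
        n_total = as.integer(obj$overall$n_total),
        accuracy = obj$overall$n_correct / obj$overall$n_total
      ),
      n_no_prediction = as.integer(obj$n_no_prediction),
      protocol = obj$protocol,
      seed = as.integer(obj$seed),
      backend = obj$backend,
      predictions = predictions
    ),
    class = "target_eval"
  )
}
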