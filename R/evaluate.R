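#' Evaluate the intent classifier on a labeled test set
#'
#' Decision accuracy is the fraction of questions whose predicted
#' category equals the gold label, reported overall and per category,
#' together with the full confusion table.
#'
#' @param model A trained `kgqa_ig`.
#' @param data Tibble with list-column `features` and column `category`
#'   (see [structure_questions()]).
#' @return A `kgqa_eval` report.
#' @export
evaluate_classifier <- function(model, data) {
  if (nrow(data) == 0) abort("empty test set")
  predicted <- vapply(
    data$features, function(f) classify_intent(f, model)$category, character(1)
  )
  build_eval_report(gold = data$category, predicted = predicted)
}

#' Evaluate end-to-end disease diagnosis
#'
#' Runs the full answering pipeline on each diagnosis question and scores
#' the top-ranked disease against the gold label. Decision accuracy is
#' the fraction of questions answered with the gold disease;
#' disease coverage is the fraction of distinct gold diseases correctly
#' diagnosed at least once.
#'
#' @param kg A `medkg` graph.
#' @param model A trained `kgqa_ig`.
#' @param data Tibble with columns `question` and `gold` (a disease name).
#' @param ... Passed to [answer_question()].
#' @return A `kgqa_eval` report with `disease_coverage` filled.
#' @export
evaluate_diagnosis <- function(kg, model, data, ...) {
  if (nrow(data) == 0) abort("empty test set")
  predicted <- vapply(data$question, function(q) {
    ans <- tryCatch(answer_question(q, kg, model, ...), error = function(e) NULL)
    if (is.null(ans) || is.na(ans$answer_entity)) "" else ans$answer_entity
  }, character(1), USE.NAMES = FALSE)
  correct <- normalize_name(predicted) == normalize_name(data$gold)
  report <- build_eval_report(gold = data$gold, predicted = predicted)
  golds <- unique(normalize_name(data$gold))
  covered <- unique(normalize_name(data$gold)[correct])
  report$disease_coverage <- length(covered) / length(golds)
  report
}

build_eval_report <- function(gold, predicted) {
  correct <- gold == predicted
  confusion <- dplyr::count(
    tibble(gold = gold, predicted = predicted), .data$gold, .data$predicted,
    name = "n"
  )
  per_category <- dplyr::summarise(
    dplyr::group_by(tibble(gold = gold, correct = correct), category = .data$gold),
    n = dplyr::n(), accuracy = mean(.data$correct), .groups = "drop"
  )
  structure(
    list(
      overall_accuracy = mean(correct),
      per_category = per_category,
      disease_coverage = NA_real_,
      n_questions = length(gold),
      confusion = confusion
    ),
    class = "kgqa_eval"
  )
}

#' @method tidy kgqa_eval
#' @export
tidy.kgqa_eval <- function(x, ...) x$per_category

#' @method glance kgqa_eval
#' @export
glance.kgqa_eval <- function(x, ...) {
  tibble(
    overall_accuracy = x$overall_accuracy,
    disease_coverage = x$disease_coverage,
    n_questions = x$n_questions
  )
}

#' @export
print.kgqa_eval <- function(x, ...) {
  cat(sprintf(
    "<kgqa_eval> %d questions, accuracy %.4f%s\n",
    x$n_questions, x$overall_accuracy,
    if (!is.na(x$disease_coverage)) {
      sprintf(", disease coverage %.4f", x$disease_coverage)
    } else ""
  ))
  print(x$per_category)
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Emits per-category rows (category, n, accuracy), an `overall` row, a
#' `disease_coverage` row when applicable, and the confusion counts.
#'
#' @param report A `kgqa_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  num <- function(x) format(x, digits = 17)
  lines <- c(
    "section\tkey\tn\tvalue",
    sprintf(
      "per_category\t%s\t%d\t%s",
      report$per_category$category, report$per_category$n,
      num(report$per_category$accuracy)
    ),
    sprintf("overall\taccuracy\t%d\t%s", report$n_questions, num(report$overall_accuracy))
  )
  if (!is.na(report$disease_coverage)) {
    lines <- c(lines, sprintf(
      "overall\tdisease_coverage\t%d\t%s",
      report$n_questions, num(report$disease_coverage)
    ))
  }
  lines <- c(lines, sprintf(
    "confusion\t%s->%s\t%d\t%s",
    report$confusion$gold, report$confusion$predicted, report$confusion$n, ""
  ))
  writeLines(lines, path)
  invisible(path)
}
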