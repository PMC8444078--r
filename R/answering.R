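#' Default answer templates
#'
#' One template per category, with slots `[@concept]` (an entity name) or
#' `[@concept]-[@property]` (that entity's property values or typed
#' neighbors, joined as prose). Slot labels are case-insensitive.
#'
#' @return Named character vector, one template per category.
#' @export
default_answer_templates <- function() {
  c(
    disease_diagnosis = paste0(
      "Hello, we think it perhaps be a [@disease]. ",
      "The main symptoms of [@disease] include [@disease]-[@symptom]."
    ),
    drug_recommendation = "According to your descriptions, we recommend the drug [@drug].",
    symptom = "The main symptoms of [@disease] include [@disease]-[@symptom].",
    treatment = "The treatments for [@disease] include [@disease]-[@treatment].",
    diet = "The suggested diet for [@disease]: [@disease]-[@diet].",
    cause = "The causes of [@disease] include [@disease]-[@cause].",
    prevention = "To prevent [@disease]: [@disease]-[@prevention].",
    indication = "[@drug] is indicated for [@drug]-[@indication].",
    taboo_population = "[@drug] is taboo for [@drug]-[@taboo_population]."
  )
}

#' Default refusal text for unsupported questions
#' @return A string.
#' @export
default_refusal <- function() {
  "Sorry, we cannot recognize the intention of your question."
}

slot_pattern <- "\\[@[A-Za-z_]+\\](?:-\\[@[A-Za-z_]+\\])?"

template_slots <- function(template) {
  m <- stringr::str_extract_all(template, slot_pattern)[[1]]
  # composite slots first so their component slots are not double-counted
  unique(m[order(-nchar(m))])
}

#' Fill an answer template
#'
#' Literal slot substitution: every slot occurring in the template must be
#' bound; no other text changes. Slot names are matched case-insensitively.
#'
#' @param template Template string with `[@concept]` /
#'   `[@concept]-[@property]` slots.
#' @param bindings Named character vector or list, names are slot strings
#'   (brackets included, case-insensitive).
#' @return The rendered string.
#' @export
#' @examples
#' fill_template(
#'   "According to your descriptions, your most possible illness is a [@disease]",
#'   c("[@disease]" = "cold")
#' )
fill_template <- function(template, bindings) {
  slots <- template_slots(template)
  if (length(bindings) == 0) bindings <- setNames(character(), character())
  names(bindings) <- stringr::str_to_lower(names(bindings))
  out <- template
  for (slot in slots) {
    key <- stringr::str_to_lower(slot)
    if (!key %in% names(bindings)) {
      abort(paste0("unbound template slot: ", slot))
    }
    out <- gsub(slot, bindings[[key]], out, fixed = TRUE)
  }
  out
}

join_prose <- function(x) {
  if (length(x) <= 1) return(paste(x, collapse = ""))
  paste0(paste(x[-length(x)], collapse = ", "), " and ", x[length(x)])
}

#' Answer a question end to end
#'
#' Runs the full pipeline: entity extraction against the graph dictionary,
#' concept generalization, intent classification, then either weighted
#' path-ranking inference (disease diagnosis, drug recommendation) or
#' direct property lookup (the other seven categories), and finally slot
#' template rendering. Unsupported questions get the fixed refusal text.
#'
#' @param question Question text.
#' @param kg A `medkg` graph.
#' @param model A trained `kgqa_ig` model.
#' @param templates Named templates per category.
#' @param routing Category routing table.
#' @param stopwords Stop-word vector.
#' @param refusal Refusal text for unsupported questions.
#' @param alpha,threshold,max_iter Path-ranking parameters.
#' @return A `kgqa_answer`: list with `text`, `category`, `answer_entity`
#'   (name or `NA`), `evidence` (ranked candidates or looked-up values),
#'   `structured` (the processed question) and `scores` (for rank routes).
#' @export
answer_question <- function(question, kg, model,
                            templates = default_answer_templates(),
                            routing = default_category_routing(),
                            stopwords = default_stopwords(),
                            refusal = default_refusal(),
                            alpha = 0.85, threshold = 1e-6, max_iter = 100) {
  sq <- generalize(extract_entities(question, kg, stopwords))
  intent <- classify_intent(sq, model)
  category <- intent$category
  ans <- function(text, answer_entity = NA_character_, evidence = NULL,
                  scores = NULL) {
    structure(
      list(
        text = text, category = category, answer_entity = answer_entity,
        evidence = evidence, structured = sq, intent = intent, scores = scores
      ),
      class = "kgqa_answer"
    )
  }
  if (category == "unsupported") return(ans(refusal))
  route <- routing[[category]]
  if (is.null(route)) abort(paste0("no routing entry for category '", category, "'"))
  template <- templates[[category]]
  if (is.null(template)) abort(paste0("no answer template for category '", category, "'"))
  seed_ids <- unique(sq$matched$entity_id[!is.na(sq$matched$entity_id)])
  if (length(seed_ids) == 0) {
    abort("cannot ground question: no knowledge-graph entities matched",
          class = "medkgqa_no_entities")
  }

  if (route$strategy == "rank") {
    sv <- weighted_path_rank(
      kg, seed_ids, alpha = alpha, threshold = threshold,
      max_iter = max_iter, symmetrize = TRUE
    )
    ranked <- select_candidates(sv, kg, route$target_concept)
    top <- ranked$name[1]
    bindings <- setNames(top, paste0("[@", route$target_concept, "]"))
    for (slot in template_slots(template)) {
      key <- stringr::str_to_lower(slot)
      if (key %in% names(bindings)) next
      m <- stringr::str_match(key, "^\\[@([a-z_]+)\\]-\\[@([a-z_]+)\\]$")
      if (!is.na(m[1, 1]) && m[1, 2] == route$target_concept) {
        prop <- m[1, 3]
        vals <- kg_property(kg, ranked$id[1], prop)
        if (!length(vals)) {
          nb <- kg_neighbors(kg, ranked$id[1], "out")
          vals <- nb$name[nb$concept == prop]
        }
        bindings[key] <- join_prose(vals)
      }
    }
    return(ans(
      fill_template(template, bindings), answer_entity = top,
      evidence = ranked, scores = sv
    ))
  }

  # lookup route: prefer a subject entity of the routed concept
  m <- sq$matched[!is.na(sq$matched$entity_id), ]
  subj_rows <- which(m$concept == (route$subject_concept %||% ""))
  subj_id <- if (length(subj_rows)) m$entity_id[subj_rows[1]] else m$entity_id[1]
  subj_concept <- if (length(subj_rows)) route$subject_concept else m$concept[1]
  vals <- property_lookup(kg, subj_id, category, routing)
  subj_name <- kg$entities$name[match(subj_id, kg$entities$id)]
  bindings <- setNames(
    c(subj_name, join_prose(vals)),
    c(
      paste0("[@", subj_concept, "]"),
      paste0("[@", subj_concept, "]-[@", route$slot_property %||% category_slot(category), "]")
    )
  )
  ans(
    fill_template(template, bindings), answer_entity = subj_name,
    evidence = tibble(value = vals)
  )
}

category_slot <- function(category) {
  # property slot label used by the default templates for each category
  switch(category,
    symptom = "symptom", treatment = "treatment", diet = "diet",
    cause = "cause", prevention = "prevention", indication = "indication",
    taboo_population = "taboo_population", category
  )
}

#' @export
print.kgqa_answer <- function(x, ...) {
  cat("<kgqa_answer> [", x$category, "]\n", sep = "")
  cat(x$text, "\n")
  invisible(x)
}

#' Read and write answer template files
#'
#' YAML mapping category labels to template strings; an optional
#' `unsupported` key overrides the refusal text.
#'
#' @param templates Named character vector of templates.
#' @param path File path.
#' @return `read_answer_templates()` returns a named character vector.
#' @export
write_answer_templates <- function(templates, path) {
  yaml::write_yaml(as.list(templates), path)
  invisible(path)
}

#' @rdname write_answer_templates
#' @export
read_answer_templates <- function(path) {
  unlist(yaml::read_yaml(path))
}
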