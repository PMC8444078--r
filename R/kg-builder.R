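#' Relation weight configuration
#'
#' Relations carry signed weights: positive for supporting relations,
#' negative for contraindications. Strong disease-symptom correlations
#' (main symptoms) default to 1.0 and weak ones (complications) to 0.5;
#' drug indications are 1.0 and taboo-population edges -1.0. Any value can
#' be overridden, e.g. `weight_config(complication = 1.0)` to score
#' complications as strongly as main symptoms.
#'
#' @param ... Named overrides or additional relation types, all non-zero.
#' @return Named list of default weights by relation type.
#' @export
weight_config <- function(...) {
  w <- list(
    main_symptom = 1.0,
    complication = 0.5,
    indication = 1.0,
    taboo_population = -1.0,
    located_in = 1.0
  )
  dots <- list(...)
  for (nm in names(dots)) w[[nm]] <- as.double(dots[[nm]])
  if (any(vapply(w, function(x) x == 0 || !is.finite(x), logical(1)))) {
    abort("weight configuration must not contain zero or non-finite weights")
  }
  w
}

#' Define a semantic-template extraction rule
#'
#' A rule anchors on literal cue phrases in free instruction text (e.g.
#' "the common is", "Complications may include"); the enumeration span
#' following an anchor is split on list separators and each item is kept
#' iff it matches a dictionary name of the rule's tail concept.
#'
#' @param id Rule identifier.
#' @param head_concept Concept of the record's head entity.
#' @param tail_concept Concept the extracted names must belong to.
#' @param rel_type Relation type the rule asserts (must have a configured
#'   default weight).
#' @param anchors Character vector of literal cue phrases (case-insensitive),
#'   at least one.
#' @param separators Strings splitting the enumeration.
#' @return A `medkg_rule` object.
#' @export
template_rule <- function(id, head_concept, tail_concept, rel_type, anchors,
                          separators = c(",", ";", " and ")) {
  anchors <- as.character(anchors)
  if (length(anchors) == 0) abort("a template rule needs at least one anchor phrase")
  structure(
    list(
      id = id, head_concept = head_concept, tail_concept = tail_concept,
      rel_type = rel_type, anchors = anchors, separators = separators
    ),
    class = "medkg_rule"
  )
}

#' Default semantic-template rules
#'
#' Covers the common phrasings for main symptoms and complications in
#' disease instruction text.
#'
#' @return List of `medkg_rule` objects.
#' @export
default_template_rules <- function() {
  list(
    template_rule(
      "main_symptom_text", "disease", "symptom", "main_symptom",
      anchors = c(
        "the common is", "the common symptoms are", "the main symptoms are",
        "major symptoms are", "symptoms include"
      )
    ),
    template_rule(
      "complication_text", "disease", "symptom", "complication",
      anchors = c("complications may include", "complications include")
    )
  )
}

clean_list_item <- function(x) {
  # strip ellipses, surrounding punctuation and whitespace
  x <- gsub("…", " ", x, fixed = TRUE)
  x <- gsub("\\.{2,}", " ", x)
  x <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", x)
  stringr::str_squish(x)
}

#' Apply one template rule to free text
#'
#' Each anchor occurrence opens an enumeration span, ending at the next
#' sentence terminator (`.`, `!`, `?`) or the next anchor. The span is
#' split on the rule's separators and each item is retained iff the
#' longest case-insensitive match against a dictionary name of the rule's
#' tail concept succeeds; items with no dictionary match are dropped.
#' Duplicates are removed preserving first occurrence.
#'
#' @param text Free instruction text.
#' @param rule A `medkg_rule`.
#' @param dictionary Named character vector mapping entity common names to
#'   concepts (names = entity names, values = concept labels).
#' @return Character vector of matched dictionary names (dictionary
#'   spelling), possibly empty.
#' @export
apply_template_rule <- function(text, rule, dictionary) {
  low <- stringr::str_to_lower(text)
  dict_names <- names(dictionary)[dictionary == rule$tail_concept]
  dict_norm <- normalize_name(dict_names)
  # longest-first so the longest dictionary name wins inside an item
  ord <- order(-nchar(dict_norm))
  dict_names <- dict_names[ord]
  dict_norm <- dict_norm[ord]

  anchor_pos <- purrr::map(stringr::str_to_lower(rule$anchors), function(a) {
    m <- stringr::str_locate_all(low, stringr::fixed(a))[[1]]
    m
  })
  starts <- do.call(rbind, anchor_pos)
  if (is.null(starts) || nrow(starts) == 0) return(character())
  all_anchor_starts <- sort(starts[, "start"])

  out <- character()
  for (k in seq_len(nrow(starts))) {
    span_start <- starts[k, "end"] + 1L
    terminators <- c(
      stringr::str_locate_all(low, "[.!?]")[[1]][, "start"],
      all_anchor_starts[all_anchor_starts > span_start]
    )
    terminators <- terminators[terminators >= span_start]
    span_end <- if (length(terminators)) min(terminators) - 1L else nchar(low)
    if (span_end < span_start) next
    span <- substr(text, span_start, span_end)
    pieces <- span
    for (sep in rule$separators) {
      pieces <- unlist(strsplit(pieces, sep, fixed = TRUE))
    }
    for (piece in pieces) {
      piece <- clean_list_item(piece)
      if (!nzchar(piece)) next
      pn <- normalize_name(piece)
      hit <- which(dict_norm == pn)
      if (length(hit) == 0) {
        # fall back to the longest dictionary name embedded in the item
        hit <- which(vapply(
          dict_norm,
          function(d) grepl(paste0("\\b", escape_regex(d), "\\b"), pn),
          logical(1)
        ))
      }
      if (length(hit)) out <- c(out, dict_names[hit[1]])
    }
  }
  unique(out)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Construct a medical instruction record
#'
#' One structured drug or disease instruction: a head common name plus a
#' map of fields. Entity-list fields (e.g. `main_symptom`,
#' `adaptation_disease`, `taboo_population`) hold character vectors of
#' entity names; property fields (`treatment`, `prevention`, `cause`,
#' `diet`, `hospital_department`, `sex`) hold free text stored on the head
#' entity; the `description` field holds free text parsed by template
#' rules.
#'
#' @param kind `"drug"` or `"disease"`.
#' @param common_name Head entity common name.
#' @param fields Named list of fields from the instruction vocabulary.
#' @return A `medkg_instruction` object.
#' @export
instruction_record <- function(kind, common_name, fields = list()) {
  kind <- match.arg(kind, c("drug", "disease"))
  if (is.null(common_name) || !nzchar(normalize_name(common_name))) {
    abort("instruction record is missing its common name")
  }
  vocab <- names(instruction_field_map())
  bad <- setdiff(names(fields), vocab)
  if (length(bad)) {
    abort(paste0(
      "unknown instruction field(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(vocab, collapse = ", ")
    ))
  }
  structure(
    list(kind = kind, common_name = common_name, fields = fields),
    class = "medkg_instruction"
  )
}

#' Field vocabulary of instruction records
#'
#' Maps each field label to how it is consumed: a relation (with tail
#' concept and relation type), a head-entity property, or free text for
#' template-rule parsing.
#'
#' @return Named list describing each field.
#' @export
instruction_field_map <- function() {
  list(
    adaptation_disease = list(role = "relation", rel_type = "indication", tail_concept = "disease"),
    adaptation_symptom = list(role = "relation", rel_type = "indication", tail_concept = "symptom"),
    taboo_population = list(role = "relation", rel_type = "taboo_population", tail_concept = "population"),
    main_symptom = list(role = "relation", rel_type = "main_symptom", tail_concept = "symptom"),
    complication_symptom = list(role = "relation", rel_type = "complication", tail_concept = "symptom"),
    body = list(role = "relation", rel_type = "located_in", tail_concept = "body_part"),
    sex = list(role = "property"),
    hospital_department = list(role = "property"),
    treatment = list(role = "property"),
    prevention = list(role = "property"),
    cause = list(role = "property"),
    diet = list(role = "property"),
    indications = list(role = "property"),
    contraindication = list(role = "property"),
    symptom = list(role = "property"),
    description = list(role = "free_text")
  )
}

#' Extract entities and relations from one instruction record
#'
#' The record's common name becomes the head entity (concept from the
#' record kind). Entity-list fields map directly to one relation per
#' listed name; the `description` field is parsed with the template rules
#' against the dictionary. Weights resolve from the weight configuration.
#'
#' @param record A `medkg_instruction`.
#' @param rules List of `medkg_rule` objects for free-text fields.
#' @param dictionary Named character vector name -> concept for rule
#'   matching (may be empty if no free text).
#' @param weights A [weight_config()].
#' @return List with `entities` (tibble: name, concept) and `relations`
#'   (tibble: src_name, dst_name, rel_type, weight), plus `properties`
#'   (named list for the head entity), in deterministic order.
#' @export
parse_instruction <- function(record, rules = default_template_rules(),
                              dictionary = character(), weights = weight_config()) {
  stopifnot(inherits(record, "medkg_instruction"))
  head_concept <- if (record$kind == "drug") "drug" else "disease"
  fmap <- instruction_field_map()
  ents <- tibble(name = record$common_name, concept = head_concept)
  rels <- tibble(
    src_name = character(), dst_name = character(),
    rel_type = character(), weight = double()
  )
  props <- list()
  add_rel <- function(rels, tails, rel_type, tail_concept) {
    w <- weights[[rel_type]]
    if (is.null(w)) abort(paste0("rel_type '", rel_type, "' has no configured weight"))
    dplyr::bind_rows(rels, tibble(
      src_name = record$common_name, dst_name = as.character(tails),
      rel_type = rel_type, weight = w
    ))
  }
  for (lab in names(record$fields)) {
    val <- record$fields[[lab]]
    role <- fmap[[lab]]$role
    if (role == "relation") {
      tails <- as.character(val)
      tails <- tails[nzchar(normalize_name(tails))]
      if (length(tails)) {
        ents <- dplyr::bind_rows(ents, tibble(name = tails, concept = fmap[[lab]]$tail_concept))
        rels <- add_rel(rels, tails, fmap[[lab]]$rel_type, fmap[[lab]]$tail_concept)
      }
    } else if (role == "property") {
      props[[lab]] <- as.character(val)
    } else { # free text: run every rule whose head concept matches
      for (rule in rules) {
        if (rule$head_concept != head_concept) next
        tails <- apply_template_rule(val, rule, dictionary)
        if (length(tails)) {
          ents <- dplyr::bind_rows(ents, tibble(name = tails, concept = rule$tail_concept))
          rels <- add_rel(rels, tails, rule$rel_type, rule$tail_concept)
        }
      }
    }
  }
  ents <- dplyr::distinct(ents, normalize_name(.data$name), .data$concept, .keep_all = TRUE)
  ents <- ents[, c("name", "concept")]
  list(entities = ents, relations = rels, properties = props)
}

#' Build a knowledge graph from instruction records
#'
#' Unions the per-record extractions of [parse_instruction()] into one
#' graph. Entities merge by normalized (name, concept); the dictionary
#' used for free-text rule matching defaults to the union of all record
#' common names plus any supplied lexicon. Building is deterministic:
#' identical inputs yield structurally identical graphs.
#'
#' @param records List of `medkg_instruction` objects.
#' @param rules Template rules for free-text fields.
#' @param dictionary Optional named character vector (name -> concept)
#'   merged with the record-derived names.
#' @param weights A [weight_config()].
#' @param concepts Concept vocabulary for the new graph.
#' @return A `medkg` graph.
#' @export
build_graph <- function(records, rules = default_template_rules(),
                        dictionary = character(), weights = weight_config(),
                        concepts = default_concepts()) {
  if (length(records) == 0) abort("no instruction records supplied")
  auto <- setNames(
    vapply(records, function(r) if (r$kind == "drug") "drug" else "disease", character(1)),
    vapply(records, function(r) r$common_name, character(1))
  )
  dictionary <- c(dictionary, auto[!names(auto) %in% names(dictionary)])
  kg <- kg_new(concepts = concepts, weights = weights)
  for (ri in seq_along(records)) {
    parsed <- tryCatch(
      parse_instruction(records[[ri]], rules, dictionary, weights),
      error = function(e) {
        abort(paste0("record ", ri, " (", records[[ri]]$common_name %||% "?", "): ",
                     conditionMessage(e)))
      }
    )
    for (k in seq_len(nrow(parsed$entities))) {
      kg <- kg_add_entity(kg, parsed$entities$name[k], parsed$entities$concept[k])
    }
    if (length(parsed$properties)) {
      kg <- kg_add_entity(
        kg, records[[ri]]$common_name,
        if (records[[ri]]$kind == "drug") "drug" else "disease",
        properties = parsed$properties
      )
    }
    for (k in seq_len(nrow(parsed$relations))) {
      kg <- kg_add_relation(
        kg, parsed$relations$src_name[k], parsed$relations$dst_name[k],
        parsed$relations$rel_type[k], parsed$relations$weight[k]
      )
    }
  }
  kg
}

#' Read and write instruction record files
#'
#' Instruction records are stored line-delimited: one JSON object per
#' line with keys `kind`, `common_name` and `fields`.
#'
#' @param records List of `medkg_instruction` objects.
#' @param path File path.
#' @return `write_instructions()` returns `path` invisibly;
#'   `read_instructions()` a list of `medkg_instruction` objects.
#' @export
write_instructions <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(
      list(kind = r$kind, common_name = r$common_name, fields = r$fields),
      auto_unbox = TRUE
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instructions
#' @export
read_instructions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  purrr::imap(lines, function(ln, i) {
    obj <- tryCatch(
      jsonlite::fromJSON(ln, simplifyVector = TRUE, simplifyMatrix = FALSE),
      error = function(e) parse_abort(path, i, "bad instruction JSON")
    )
    fields <- purrr::map(as.list(obj$fields), as.character)
    instruction_record(obj$kind, obj$common_name, fields)
  })
}

#' Read a rules-and-weights configuration file
#'
#' YAML with two top-level keys: `weights` (relation type -> weight) and
#' `rules` (list with id, head_concept, tail_concept, rel_type, anchors,
#' optional separators).
#'
#' @param path YAML file path.
#' @return List with elements `weights` and `rules`.
#' @export
read_kg_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  weights <- do.call(weight_config, as.list(cfg$weights %||% list()))
  rules <- purrr::map(cfg$rules %||% list(), function(r) {
    template_rule(
      r$id, r$head_concept, r$tail_concept, r$rel_type,
      anchors = unlist(r$anchors),
      separators = unlist(r$separators %||% list(",", ";", " and "))
    )
  })
  if (length(rules) == 0) rules <- default_template_rules()
  list(weights = weights, rules = rules)
}
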