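#' The nine supported question categories
#'
#' Question intents outside these nine map to `"unsupported"`.
#'
#' @return Character vector of the nine category labels.
#' @export
question_categories <- function() {
  c(
    "disease_diagnosis", "symptom", "treatment", "diet", "cause",
    "drug_recommendation", "taboo_population", "indication", "prevention"
  )
}

#' Default English stop-word list
#'
#' Function words removed before entity matching and feature building.
#' Auxiliaries like "has"/"have" are deliberately retained: they survive
#' into the structured representation of questions such as "My child has a
#' cough ...".
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "the", "my", "your", "his", "her", "its", "our", "their",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "them",
    "am", "is", "are", "was", "were", "be", "been", "being",
    "do", "does", "did", "to", "of", "in", "on", "at", "for", "from",
    "and", "or", "as", "by", "with", "this", "that", "these", "those",
    "there", "here", "please", "s"
  )
}

tokenize_question <- function(question, stopwords) {
  toks <- stringr::str_extract_all(
    stringr::str_to_lower(question), "[a-z0-9][a-z0-9'-]*"
  )[[1]]
  toks[!toks %in% stopwords]
}

#' Extract question entities against the knowledge-graph dictionary
#'
#' Tokenizes the question (lower-case, punctuation split), removes stop
#' words, then scans token n-grams longest-match-first, left to right and
#' non-overlapping, against the graph's name index. Concept labels
#' themselves (e.g. the bare word "disease") are also recorded as matched
#' entities when `match_concept_names` is on, but are kept as literal
#' words during generalization.
#'
#' @param question Question text.
#' @param kg A `medkg` graph providing the entity dictionary.
#' @param stopwords Stop-word vector.
#' @param match_concept_names Also match bare concept labels.
#' @return A `kgqa_question` with `raw`, `tokens`, and a `matched` tibble
#'   (surface, entity_id, concept, token_start, token_end, generalize).
#' @export
extract_entities <- function(question, kg, stopwords = default_stopwords(),
                             match_concept_names = TRUE) {
  tokens <- tokenize_question(question, stopwords)
  norms <- kg$entities$norm
  max_len <- if (length(norms)) max(stringr::str_count(norms, " ") + 1L) else 1L
  matched <- list()
  i <- 1L
  while (i <= length(tokens)) {
    hit <- NULL
    for (len in seq(min(max_len, length(tokens) - i + 1L), 1L)) {
      phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      idx <- which(norms == phrase)
      if (length(idx)) {
        idx <- idx[1]
        hit <- list(
          surface = phrase, entity_id = kg$entities$id[idx],
          concept = kg$entities$concept[idx],
          token_start = i, token_end = i + len - 1L, generalize = TRUE
        )
        break
      }
      if (len == 1L && match_concept_names && phrase %in% kg$concepts) {
        hit <- list(
          surface = phrase, entity_id = NA_integer_, concept = phrase,
          token_start = i, token_end = i, generalize = FALSE
        )
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      matched[[length(matched) + 1L]] <- hit
      i <- hit$token_end + 1L
    }
  }
  matched <- if (length(matched)) dplyr::bind_rows(matched) else tibble(
    surface = character(), entity_id = integer(), concept = character(),
    token_start = integer(), token_end = integer(), generalize = logical()
  )
  structure(
    list(raw = question, tokens = tokens, matched = matched, features = NULL),
    class = "kgqa_question"
  )
}

#' Generalize matched entities to concept placeholders
#'
#' Replaces each matched entity span in the token sequence by its concept
#' placeholder `@<concept>`, keeping residual words as-is (already
#' lower-cased). Concept-label mentions stay literal. The ordered result
#' is the question's feature sequence; classification uses its one-hot
#' (set) view.
#'
#' @param sq A `kgqa_question` from [extract_entities()].
#' @return The question with `features` filled.
#' @export
generalize <- function(sq) {
  stopifnot(inherits(sq, "kgqa_question"))
  feats <- character()
  m <- sq$matched
  i <- 1L
  while (i <= length(sq$tokens)) {
    row <- which(m$token_start == i)
    if (length(row) == 1L) {
      feats <- c(feats, if (m$generalize[row]) paste0("@", m$concept[row]) else m$surface[row])
      i <- m$token_end[row] + 1L
    } else {
      feats <- c(feats, sq$tokens[i])
      i <- i + 1L
    }
  }
  sq$features <- feats
  sq
}

#' @export
print.kgqa_question <- function(x, ...) {
  cat("<kgqa_question>", x$raw, "\n")
  ents <- unique(x$matched$surface)
  cat("  entities: {", paste(ents, collapse = ", "), "}\n")
  if (!is.null(x$features)) {
    cat("  features: {", paste(x$features, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Structure a batch of questions
#'
#' Convenience wrapper running [extract_entities()] and [generalize()]
#' over a tibble of questions, adding a `features` list-column.
#'
#' @param data Tibble with a `question` column.
#' @param kg A `medkg` graph.
#' @param stopwords Stop-word vector.
#' @param match_concept_names Passed to [extract_entities()].
#' @return `data` with a `features` list-column appended.
#' @export
structure_questions <- function(data, kg, stopwords = default_stopwords(),
                                match_concept_names = TRUE) {
  data$features <- purrr::map(data$question, function(q) {
    generalize(extract_entities(q, kg, stopwords, match_concept_names))$features
  })
  data
}

#' Train the information-gain intent classifier
#'
#' For every feature x (a concept placeholder or residual word) and
#' category c, the model stores an information-gain score. The literal
#' variant is IG(x, c) = p(x|c) * ln(p(x|c) / (p(x) p(c))); the joint
#' variant substitutes the joint probability p(x, c) for p(x|c) both
#' inside and outside the logarithm, which makes IG of an independent
#' feature exactly zero on exact-count corpora. Probabilities are question
#' frequencies under one-hot (presence) semantics; IG is 0 whenever
#' p(x|c) = 0.
#'
#' @param data Tibble with list-column `features` (character vectors, see
#'   [structure_questions()]) and column `category`.
#' @param variant `"literal"` (as-printed conditional form, default) or
#'   `"joint"`.
#' @param smoothing Add-one style smoothing pseudo-count on feature
#'   presence (default 0, off).
#' @return A `kgqa_ig` model.
#' @export
train_intent_classifier <- function(data, variant = c("literal", "joint"),
                                    smoothing = 0) {
  variant <- match.arg(variant)
  if (nrow(data) == 0) abort("empty training set")
  cats_present <- sort(unique(data$category))
  missing_cats <- setdiff(question_categories(), cats_present)
  if (length(missing_cats) && any(cats_present %in% question_categories())) {
    warn(paste0(
      "no training examples for category(ies): ",
      paste(missing_cats, collapse = ", "), "; their IG rows are absent"
    ))
  }
  featsets <- purrr::map(data$features, unique)
  vocab <- sort(unique(unlist(featsets)))
  n <- nrow(data)
  priors <- table(factor(data$category, levels = cats_present)) / n
  # presence matrix: questions x features
  pres <- vapply(
    vocab, function(f) purrr::map_lgl(featsets, function(fs) f %in% fs),
    logical(n)
  )
  pres <- matrix(pres, nrow = n, dimnames = list(NULL, vocab))
  p_x <- (colSums(pres) + smoothing) / (n + 2 * smoothing)
  n_c <- as.vector(table(factor(data$category, levels = cats_present)))
  count_xc <- rowsum(pres + 0, group = factor(data$category, levels = cats_present))
  p_x_c <- t((t(count_xc) + smoothing)) / (n_c + 2 * smoothing) # categories x features
  p_joint <- t(count_xc + smoothing) / (n + 2 * smoothing)      # features x categories
  p_x_c <- t(p_x_c)                                             # features x categories
  pr <- as.vector(priors)
  inner <- if (variant == "literal") p_x_c else p_joint
  ratio <- sweep(inner, 1, p_x, "/")
  ratio <- sweep(ratio, 2, pr, "/")
  ig <- inner * ifelse(inner > 0, log(pmax(ratio, .Machine$double.xmin)), 0)
  ig[inner == 0] <- 0
  dimnames(ig) <- list(vocab, cats_present)
  dimnames(p_x_c) <- list(vocab, cats_present)
  structure(
    list(
      vocabulary = vocab, categories = cats_present,
      priors = setNames(as.vector(priors), cats_present),
      p_x = setNames(p_x, vocab), p_x_given_c = p_x_c, ig = ig,
      variant = variant, smoothing = smoothing, n_questions = n
    ),
    class = "kgqa_ig"
  )
}

#' Information gain of one (feature, category) pair
#'
#' @param feature Feature string (e.g. `"@symptom"` or `"prevent"`).
#' @param category Category label.
#' @param model A trained `kgqa_ig` model.
#' @return The IG value; 0 for a feature or category the model has not
#'   seen (documented convention, not an error).
#' @export
information_gain <- function(feature, category, model) {
  stopifnot(inherits(model, "kgqa_ig"))
  if (!feature %in% model$vocabulary || !category %in% model$categories) return(0)
  unname(model$ig[feature, category])
}

#' Classify question intent
#'
#' Sums the information gain of the question's present features for each
#' category (one-hot semantics: feature repetition does not change the
#' value) and returns the arg-max category. Ties break to the
#' lexicographically smallest label; if the maximum value is not positive
#' the question is `"unsupported"`.
#'
#' @param x A `kgqa_question` with features filled, or a character vector
#'   of features.
#' @param model A trained `kgqa_ig` model.
#' @return A `kgqa_intent`: list with `category` and a `values` tibble
#'   (category, value) sorted by decreasing value.
#' @export
classify_intent <- function(x, model) {
  stopifnot(inherits(model, "kgqa_ig"))
  feats <- if (inherits(x, "kgqa_question")) {
    if (is.null(x$features)) abort("question features not filled; run generalize() first")
    x$features
  } else {
    as.character(x)
  }
  feats <- unique(feats)
  feats <- feats[feats %in% model$vocabulary]
  values <- if (length(feats)) {
    colSums(model$ig[feats, , drop = FALSE])
  } else {
    setNames(rep(0, length(model$categories)), model$categories)
  }
  # refuse when there is no recognized evidence at all, or when the best
  # achievable value is negative; zero-valued ties on known features still
  # resolve by arg-max (lexicographically smallest label)
  best <- if (length(feats) == 0 || max(values) < 0) {
    "unsupported"
  } else {
    cand <- names(values)[values == max(values)]
    sort(cand)[1]
  }
  structure(
    list(
      category = best,
      values = dplyr::arrange(
        tibble(category = names(values), value = unname(values)),
        dplyr::desc(.data$value), .data$category
      )
    ),
    class = "kgqa_intent"
  )
}

#' @export
print.kgqa_intent <- function(x, ...) {
  cat("<kgqa_intent>", x$category, "\n")
  print(x$values, n = 5)
  invisible(x)
}

#' @method tidy kgqa_ig
#' @export
tidy.kgqa_ig <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x$ig), feature = x$vocabulary),
    -"feature", names_to = "category", values_to = "ig"
  )
}

#' @method glance kgqa_ig
#' @export
glance.kgqa_ig <- function(x, ...) {
  tibble(
    n_features = length(x$vocabulary), n_categories = length(x$categories),
    n_questions = x$n_questions, variant = x$variant
  )
}

#' Read and write labeled question files
#'
#' Tab-separated, one question per line: question text, category, and an
#' optional gold answer entity.
#'
#' @param data Tibble with columns `question`, `category`, optionally
#'   `gold`.
#' @param path File path.
#' @return `read_labeled_questions()` returns a tibble (question,
#'   category, gold).
#' @export
write_labeled_questions <- function(data, path) {
  gold <- if ("gold" %in% names(data)) data$gold else rep("", nrow(data))
  writeLines(sprintf("%s\t%s\t%s", data$question, data$category, gold), path)
  invisible(path)
}

#' @rdname write_labeled_questions
#' @export
read_labeled_questions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(paste0(path, ": no labeled questions found"))
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  tibble(question = parts[, 1], category = parts[, 2], gold = parts[, 3])
}

#' Serialize an information-gain model
#'
#' Sectioned structured-text format storing the variant, priors, feature
#' probabilities and the full IG table; `read_ig_model(write_ig_model(m))`
#' reproduces the model.
#'
#' @param model A `kgqa_ig` model.
#' @param path File path.
#' @return `read_ig_model()` returns a `kgqa_ig`.
#' @export
write_ig_model <- function(model, path) {
  num <- function(x) format(x, digits = 17)
  vocab <- model$vocabulary
  cats <- model$categories
  cond <- expand.grid(feature = vocab, category = cats, stringsAsFactors = FALSE)
  lines <- c(
    "# kgqa_ig v1",
    paste0("variant\t", model$variant),
    paste0("smoothing\t", num(model$smoothing)),
    paste0("n_questions\t", model$n_questions),
    "[priors]",
    sprintf("%s\t%s", cats, num(unname(model$priors[cats]))),
    "[features]",
    sprintf("%s\t%s", vocab, num(unname(model$p_x[vocab]))),
    "[conditional]",
    sprintf(
      "%s\t%s\t%s\t%s", cond$feature, cond$category,
      num(model$p_x_given_c[cbind(cond$feature, cond$category)]),
      num(model$ig[cbind(cond$feature, cond$category)])
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ig_model
#' @export
read_ig_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "# kgqa_ig v1") {
    parse_abort(path, 1L, "not a kgqa_ig v1 model file")
  }
  section <- "header"
  hdr <- list()
  priors <- c()
  p_x <- c()
  cond <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (ln %in% c("[priors]", "[features]", "[conditional]")) {
      section <- ln
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "header") {
      hdr[[f[1]]] <- f[2]
    } else if (section == "[priors]") {
      priors[f[1]] <- as.double(f[2])
    } else if (section == "[features]") {
      p_x[f[1]] <- as.double(f[2])
    } else {
      if (length(f) != 4) parse_abort(path, i, "conditional line needs 4 fields")
      cond[[length(cond) + 1L]] <- f
    }
  }
  cats <- names(priors)
  vocab <- names(p_x)
  p_x_c <- matrix(0, length(vocab), length(cats), dimnames = list(vocab, cats))
  ig <- p_x_c
  for (f in cond) {
    p_x_c[f[1], f[2]] <- as.double(f[3])
    ig[f[1], f[2]] <- as.double(f[4])
  }
  structure(
    list(
      vocabulary = vocab, categories = cats, priors = priors, p_x = p_x,
      p_x_given_c = p_x_c, ig = ig, variant = hdr$variant %||% "literal",
      smoothing = as.double(hdr$smoothing %||% "0"),
      n_questions = as.integer(hdr$n_questions %||% "0")
    ),
    class = "kgqa_ig"
  )
}
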