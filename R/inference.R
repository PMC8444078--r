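#' Weighted path-ranking scores over the knowledge graph
#'
#' Seed entities (the question's matched entities) are initialized to
#' score 1.0 and clamped there on every sweep; all other entities start at
#' 0.0 and are updated synchronously by
#' \deqn{WScore(e_i) = (1-\alpha)\,\alpha \sum_{e_j \in In(e_i)}
#'   \frac{w_{j,i}}{\sum_{e_k \in Out(e_j)} |w_{j,k}|}\, WScore(e_j)}
#' i.e. each in-neighbor passes on its score scaled by the damping factor
#' and by its edge weight normalized by the neighbor's total absolute
#' out-weight (identical to plain out-weight normalization when all
#' weights are positive; the absolute value keeps mixed-sign denominators
#' well-defined, with signs carried in the numerator). Iteration stops
#' when the total L1 change over all entities drops below `threshold`, or
#' after `max_iter` sweeps.
#'
#' By default propagation follows the stored edge direction. With
#' `symmetrize = TRUE` every stored edge is also traversable in reverse
#' at the same weight, which lets symptom seeds reach the disease nodes
#' that point at them — the configuration the answering pipeline uses for
#' diagnosis and drug recommendation.
#'
#' @param kg A `medkg` graph.
#' @param seeds Entity ids or names (non-empty, all present in `kg`).
#' @param alpha Damping factor in (0, 1); 0.85 by default.
#' @param threshold Convergence threshold on the L1 change (default 1e-6).
#' @param max_iter Sweep cap (default 100).
#' @param symmetrize Traverse edges in both directions.
#' @return A `kgqa_scores` object; `tidy()` gives the per-entity table.
#' @export
#' @examples
#' kg <- kg_new() |>
#'   kg_add_entity("cold", "disease") |>
#'   kg_add_entity("cough", "symptom") |>
#'   kg_add_relation("cold", "cough", "main_symptom")
#' sv <- weighted_path_rank(kg, seeds = "cold")
#' tidy(sv)
weighted_path_rank <- function(kg, seeds, alpha = 0.85, threshold = 1e-6,
                               max_iter = 100, symmetrize = FALSE) {
  stopifnot(inherits(kg, "medkg"))
  if (length(seeds) == 0) abort("seed set must be non-empty")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (threshold <= 0) abort("threshold must be positive")
  seed_ids <- vapply(seeds, function(s) resolve_entity(kg, s), integer(1))
  seed_ids <- unique(unname(seed_ids))

  ids <- kg$entities$id
  n <- length(ids)
  pos <- match(ids, ids) # identity, but scores indexed by position
  idx_of <- setNames(seq_len(n), as.character(ids))
  src <- kg$relations$src
  dst <- kg$relations$dst
  w <- kg$relations$weight
  if (symmetrize) {
    src2 <- c(src, dst)
    dst2 <- c(dst, src)
    w <- c(w, w)
    src <- src2
    dst <- dst2
  }
  s_pos <- idx_of[as.character(src)]
  d_pos <- idx_of[as.character(dst)]
  out_abs <- numeric(n)
  if (length(w)) {
    agg <- rowsum(abs(w), group = s_pos)
    out_abs[as.integer(rownames(agg))] <- agg[, 1]
  }
  coef <- if (length(w)) (1 - alpha) * alpha * w / out_abs[s_pos] else numeric(0)

  seed_pos <- idx_of[as.character(seed_ids)]
  scores <- numeric(n)
  scores[seed_pos] <- 1.0
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    new <- numeric(n)
    if (length(coef)) {
      agg <- rowsum(coef * scores[s_pos], group = d_pos)
      new[as.integer(rownames(agg))] <- agg[, 1]
    }
    new[seed_pos] <- 1.0
    if (any(!is.finite(new))) abort("non-finite scores; check edge weights")
    delta <- sum(abs(new - scores))
    scores <- new
    if (delta < threshold) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      scores = tibble(
        id = ids, name = kg$entities$name, concept = kg$entities$concept,
        score = scores
      ),
      seeds = seed_ids, alpha = alpha, threshold = threshold,
      iterations = iterations, converged = converged, symmetrize = symmetrize
    ),
    class = "kgqa_scores"
  )
}

#' @method tidy kgqa_scores
#' @export
tidy.kgqa_scores <- function(x, ...) {
  dplyr::arrange(x$scores, dplyr::desc(.data$score), .data$id)
}

#' @method glance kgqa_scores
#' @export
glance.kgqa_scores <- function(x, ...) {
  tibble(
    n_entities = nrow(x$scores), n_seeds = length(x$seeds), alpha = x$alpha,
    threshold = x$threshold, iterations = x$iterations, converged = x$converged
  )
}

#' @export
print.kgqa_scores <- function(x, ...) {
  cat(sprintf(
    "<kgqa_scores> %d entities, %d seeds, alpha %.2f, %d iterations (%s)\n",
    nrow(x$scores), length(x$seeds), x$alpha, x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  print(head(tidy(x), 5))
  invisible(x)
}

#' Dump a score vector to a tab-separated file
#'
#' Columns: entity name, concept, score; ordered by descending score then
#' entity id.
#'
#' @param sv A `kgqa_scores` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sv, path) {
  tab <- tidy(sv)
  writeLines(
    c("entity\tconcept\tscore",
      sprintf("%s\t%s\t%s", tab$name, tab$concept, format(tab$score, digits = 17))),
    path
  )
  invisible(path)
}

#' Select ranked answer candidates of a concept
#'
#' Restricts a score vector to entities of the question's target concept,
#' excludes the seeds themselves, and orders by descending score with ties
#' broken by entity id. Errors (class `medkgqa_no_answer`) when no entity
#' of the concept scored positively.
#'
#' @param sv A `kgqa_scores` object.
#' @param kg The graph the scores were computed on.
#' @param concept Target concept (e.g. `"disease"`).
#' @return A tibble (id, name, score) with attribute `concept`; the first
#'   row is the answer candidate.
#' @export
select_candidates <- function(sv, kg, concept) {
  stopifnot(inherits(sv, "kgqa_scores"))
  tab <- sv$scores
  tab <- tab[tab$concept == concept & !tab$id %in% sv$seeds, ]
  if (nrow(tab) == 0 || max(tab$score) <= 0) {
    abort(paste0("no answer found: no '", concept, "' entity received a positive score"),
          class = "medkgqa_no_answer")
  }
  tab <- dplyr::arrange(tab[, c("id", "name", "score")],
                        dplyr::desc(.data$score), .data$id)
  attr(tab, "concept") <- concept
  tab
}

#' Category routing table
#'
#' Maps each of the nine question categories to its answering strategy:
#' `"rank"` (weighted path ranking toward a target concept) for disease
#' diagnosis and drug recommendation, `"lookup"` (direct property /
#' typed-neighbor retrieval on a subject entity) for the other seven.
#'
#' @return Named list of per-category routing entries.
#' @export
default_category_routing <- function() {
  list(
    disease_diagnosis = list(strategy = "rank", target_concept = "disease"),
    drug_recommendation = list(strategy = "rank", target_concept = "drug"),
    symptom = list(
      strategy = "lookup", subject_concept = "disease",
      property = "symptom", rel_type = c("main_symptom", "complication")
    ),
    treatment = list(strategy = "lookup", subject_concept = "disease", property = "treatment"),
    diet = list(strategy = "lookup", subject_concept = "disease", property = "diet"),
    cause = list(strategy = "lookup", subject_concept = "disease", property = "cause"),
    prevention = list(strategy = "lookup", subject_concept = "disease", property = "prevention"),
    indication = list(
      strategy = "lookup", subject_concept = "drug",
      property = "indications", rel_type = "indication"
    ),
    taboo_population = list(
      strategy = "lookup", subject_concept = "drug",
      property = "contraindication", rel_type = "taboo_population"
    )
  )
}

#' Answer a question by direct graph lookup
#'
#' Returns the entity's stored property for the category's mapped
#' property label or, failing that, the names of its out-neighbors over
#' the category's mapped relation type(s). Errors with class
#' `medkgqa_unknown` when neither exists.
#'
#' @param kg A `medkg` graph.
#' @param entity Entity id or name.
#' @param category Question category (one of the nine).
#' @param routing Routing table, see [default_category_routing()].
#' @return Character vector of answer strings.
#' @export
property_lookup <- function(kg, entity, category,
                            routing = default_category_routing()) {
  id <- resolve_entity(kg, entity)
  route <- routing[[category]]
  if (is.null(route)) abort(paste0("no routing entry for category '", category, "'"))
  if (!is.null(route$property)) {
    vals <- kg_property(kg, id, route$property)
    if (length(vals)) return(vals)
  }
  if (!is.null(route$rel_type)) {
    nb <- kg_neighbors(kg, id, "out", rel_type = route$rel_type)
    if (nrow(nb)) return(nb$name)
  }
  abort(
    paste0("unknown: entity has no '", category, "' information stored"),
    class = "medkgqa_unknown"
  )
}
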