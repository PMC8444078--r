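#' Create an empty medical knowledge graph
#'
#' A knowledge graph holds typed entities (disease, symptom, drug, ...),
#' directed signed weighted relations between them, and per-entity property
#' maps (free-text fields such as treatment or prevention). Entities are
#' indexed by their normalized common name within a concept, so the same
#' name added twice resolves to one node.
#'
#' @param concepts Character vector of allowed concept labels. The default
#'   covers the medical concept set; pass extra labels to extend it.
#' @param weights A weight configuration from [weight_config()], used to
#'   resolve default relation weights and check weight signs.
#' @return An object of class `medkg`.
#' @seealso [kg_add_entity()], [kg_add_relation()], [kg_stats()]
#' @export
#' @examples
#' kg <- kg_new() |>
#'   kg_add_entity("Gastritis", "disease") |>
#'   kg_add_entity("Upper abdominal pain", "symptom") |>
#'   kg_add_relation("Gastritis", "Upper abdominal pain", "main_symptom")
#' kg_stats(kg)
kg_new <- function(concepts = default_concepts(), weights = weight_config()) {
  concepts <- unique(as.character(concepts))
  if (any(!nzchar(concepts))) abort("concept labels must be non-empty")
  structure(
    list(
      entities = tibble(
        id = integer(), name = character(), norm = character(),
        concept = character(), properties = list()
      ),
      relations = tibble(
        src = integer(), dst = integer(),
        rel_type = character(), weight = double()
      ),
      concepts = concepts,
      weights = weights,
      next_id = 1L
    ),
    class = "medkg"
  )
}

#' @export
#' @rdname kg_new
default_concepts <- function() {
  c("disease", "symptom", "drug", "sex", "population", "body_part")
}

#' Normalize an entity common name
#'
#' Trims, case-folds, and collapses internal whitespace, so that
#' "Gastritis" and " gastritis " index the same node.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- stringr::str_squish(as.character(x))
  stringr::str_to_lower(x)
}

#' Add an entity to a knowledge graph
#'
#' Adding an existing (name, concept) pair is idempotent: the entity keeps
#' its id and any new properties are merged into its property map.
#'
#' @param kg A `medkg` graph.
#' @param name Common name of the entity; normalized for indexing, the
#'   original spelling of the first insertion is kept for display.
#' @param concept Concept label; must be one of `kg$concepts`.
#' @param properties Named list of character vectors (e.g.
#'   `list(treatment = "rest and fluids")`).
#' @return The updated graph (pipeable). Look ids up with [kg_entity_id()].
#' @export
kg_add_entity <- function(kg, name, concept, properties = list()) {
  stopifnot(inherits(kg, "medkg"))
  norm <- normalize_name(name)
  if (!nzchar(norm)) abort("entity name must be non-empty after normalization")
  if (!concept %in% kg$concepts) {
    abort(paste0("unknown concept label: '", concept, "'"))
  }
  hit <- which(kg$entities$norm == norm & kg$entities$concept == concept)
  if (length(hit) == 1L) {
    if (length(properties)) {
      old <- kg$entities$properties[[hit]]
      for (lab in names(properties)) {
        old[[lab]] <- unique(c(old[[lab]], as.character(properties[[lab]])))
      }
      kg$entities$properties[[hit]] <- old
    }
    return(kg)
  }
  kg$entities <- dplyr::bind_rows(
    kg$entities,
    tibble(
      id = kg$next_id, name = stringr::str_squish(as.character(name)),
      norm = norm, concept = concept,
      properties = list(purrr::map(properties, as.character))
    )
  )
  kg$next_id <- kg$next_id + 1L
  kg
}

#' Look up an entity id by name
#'
#' @param kg A `medkg` graph.
#' @param name Entity common name (normalization applied).
#' @param concept Optional concept restriction.
#' @return Integer entity id, or `NA` if absent (ambiguous names across
#'   concepts also return `NA` unless `concept` is given).
#' @export
kg_entity_id <- function(kg, name, concept = NULL) {
  norm <- normalize_name(name)
  hit <- kg$entities$norm == norm
  if (!is.null(concept)) hit <- hit & kg$entities$concept == concept
  ids <- kg$entities$id[hit]
  if (length(ids) == 1L) ids else NA_integer_
}

resolve_entity <- function(kg, e, concept = NULL) {
  if (is.numeric(e)) {
    id <- as.integer(e)
    if (!id %in% kg$entities$id) abort(paste0("unknown entity id: ", id))
    return(id)
  }
  id <- kg_entity_id(kg, e, concept)
  if (is.na(id)) abort(paste0("unknown entity: '", e, "'"))
  id
}

#' Add a directed signed relation
#'
#' Weights default from the relation type via the graph's weight
#' configuration: main symptoms carry 1.0 (strong correlation),
#' complications 0.5 (weak), drug indications 1.0, and taboo-population
#' contraindications -1.0. Re-adding an existing (src, dst, rel_type) edge
#' keeps the maximum-magnitude weight. Self-loops are rejected.
#'
#' @param kg A `medkg` graph.
#' @param src,dst Entity ids or names (names resolved via the index).
#' @param rel_type Relation type label (e.g. `"main_symptom"`).
#' @param weight Edge weight; `NULL` resolves the default for `rel_type`.
#'   Must be non-zero, with sign matching the configured polarity.
#' @return The updated graph.
#' @export
kg_add_relation <- function(kg, src, dst, rel_type, weight = NULL) {
  stopifnot(inherits(kg, "medkg"))
  src <- resolve_entity(kg, src)
  dst <- resolve_entity(kg, dst)
  if (src == dst) abort("self-loops are not allowed")
  if (is.null(weight)) {
    weight <- kg$weights[[rel_type]]
    if (is.null(weight)) {
      abort(paste0("no default weight configured for rel_type '", rel_type, "'"))
    }
  }
  weight <- as.double(weight)
  if (!is.finite(weight) || weight == 0) abort("relation weight must be non-zero and finite")
  cfg <- kg$weights[[rel_type]]
  if (!is.null(cfg) && sign(cfg) != sign(weight)) {
    abort(paste0(
      "weight sign ", sign(weight), " conflicts with configured polarity of '",
      rel_type, "'"
    ))
  }
  hit <- which(kg$relations$src == src & kg$relations$dst == dst &
                 kg$relations$rel_type == rel_type)
  if (length(hit) == 1L) {
    if (abs(weight) > abs(kg$relations$weight[hit])) {
      kg$relations$weight[hit] <- weight
    }
    return(kg)
  }
  kg$relations <- dplyr::bind_rows(
    kg$relations,
    tibble(src = src, dst = dst, rel_type = rel_type, weight = weight)
  )
  kg
}

#' Entity and relation tables of a graph
#'
#' @param kg A `medkg` graph.
#' @return `kg_entities()`: a tibble with columns id, name, concept and a
#'   properties list-column. `kg_relations()`: a tibble with columns src,
#'   dst, rel_type, weight.
#' @export
kg_entities <- function(kg) kg$entities[, c("id", "name", "concept", "properties")]

#' @rdname kg_entities
#' @export
kg_relations <- function(kg) kg$relations

#' Neighbors of an entity
#'
#' Follows the stored edge direction: `direction = "out"` lists edges
#' leaving the entity, `"in"` lists edges arriving at it. Ordering is
#' deterministic (by neighbor id).
#'
#' @param kg A `medkg` graph.
#' @param entity Entity id or name.
#' @param direction `"out"` or `"in"`.
#' @param rel_type Optional filter on relation types.
#' @return Tibble with columns id, name, concept, rel_type, weight.
#' @export
kg_neighbors <- function(kg, entity, direction = c("out", "in"), rel_type = NULL) {
  direction <- match.arg(direction)
  id <- resolve_entity(kg, entity)
  rel <- kg$relations
  if (direction == "out") {
    rel <- rel[rel$src == id, ]
    nb <- rel$dst
  } else {
    rel <- rel[rel$dst == id, ]
    nb <- rel$src
  }
  out <- tibble(
    id = nb,
    name = kg$entities$name[match(nb, kg$entities$id)],
    concept = kg$entities$concept[match(nb, kg$entities$id)],
    rel_type = rel$rel_type,
    weight = rel$weight
  )
  if (!is.null(rel_type)) out <- out[out$rel_type %in% rel_type, ]
  dplyr::arrange(out, .data$id, .data$rel_type)
}

#' Read a property of an entity
#'
#' @param kg A `medkg` graph.
#' @param entity Entity id or name.
#' @param label Property label (e.g. `"treatment"`).
#' @return Character vector (may be empty).
#' @export
kg_property <- function(kg, entity, label) {
  id <- resolve_entity(kg, entity)
  props <- kg$entities$properties[[match(id, kg$entities$id)]]
  as.character(props[[label]] %||% character())
}

#' Global topology statistics of a knowledge graph
#'
#' Statistics are computed on the undirected simple projection: each
#' directed edge counts once per unordered node pair, regardless of
#' relation type or direction. For N nodes and E undirected edges, the
#' average number of neighbors is 2E/N and the graph density 2E/(N(N-1));
#' both are defined as 0 for N <= 1.
#'
#' @param kg A `medkg` graph, or `NULL` to use explicit counts.
#' @param n_nodes,n_edges Override counts (used to report statistics for a
#'   graph known only by its totals).
#' @return One-row tibble: n_nodes, n_edges, avg_neighbors, density.
#' @export
#' @examples
#' kg_stats(n_nodes = 34788, n_edges = 601475)
kg_stats <- function(kg = NULL, n_nodes = NULL, n_edges = NULL) {
  if (!is.null(kg)) {
    stopifnot(inherits(kg, "medkg"))
    n_nodes <- nrow(kg$entities)
    pairs <- unique(tibble(
      a = pmin(kg$relations$src, kg$relations$dst),
      b = pmax(kg$relations$src, kg$relations$dst)
    ))
    n_edges <- nrow(pairs)
  }
  if (is.null(n_nodes) || is.null(n_edges)) {
    abort("supply a graph or both n_nodes and n_edges")
  }
  if (n_nodes <= 1) {
    avg <- 0
    dens <- 0
  } else {
    avg <- 2 * n_edges / n_nodes
    dens <- 2 * n_edges / (n_nodes * (n_nodes - 1))
  }
  tibble(
    n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
    avg_neighbors = avg, density = dens
  )
}

#' @export
print.medkg <- function(x, ...) {
  st <- kg_stats(x)
  cat(sprintf(
    "<medkg> %d entities (%s), %d relations\n",
    st$n_nodes,
    paste(names(sort(table(x$entities$concept), decreasing = TRUE)), collapse = ", "),
    nrow(x$relations)
  ))
  invisible(x)
}

#' @export
format.medkg <- function(x, ...) {
  sprintf("<medkg: %d entities, %d relations>", nrow(x$entities), nrow(x$relations))
}
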