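#' Write and read a knowledge graph as structured text
#'
#' The graph file is a sectioned plain-text format:
#' ```
#' # medkg v1
#' [concepts]
#' disease
#' [entities]
#' id <TAB> name <TAB> concept <TAB> properties-as-JSON
#' [relations]
#' src <TAB> dst <TAB> rel_type <TAB> weight
#' [weights]
#' rel_type <TAB> weight
#' ```
#' `kg_read(kg_write(kg, path))` is structurally lossless: entity ids,
#' names, concepts, properties and edge weights round-trip bit-exactly.
#'
#' @param kg A `medkg` graph.
#' @param path File path.
#' @return `kg_write()` returns `path` invisibly; `kg_read()` a `medkg`.
#'   Malformed input aborts with the offending line number.
#' @export
kg_write <- function(kg, path) {
  stopifnot(inherits(kg, "medkg"))
  ent <- kg$entities
  lines <- c(
    "# medkg v1",
    "[concepts]",
    kg$concepts,
    "[entities]",
    sprintf(
      "%d\t%s\t%s\t%s", ent$id, ent$name, ent$concept,
      purrr::map_chr(ent$properties, function(p) {
        as.character(jsonlite::toJSON(p %||% setNames(list(), character())))
      })
    ),
    "[relations]",
    sprintf(
      "%d\t%d\t%s\t%s", kg$relations$src, kg$relations$dst,
      kg$relations$rel_type, format(kg$relations$weight, digits = 17)
    ),
    "[weights]",
    sprintf("%s\t%s", names(kg$weights), format(unname(unlist(kg$weights)), digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

parse_abort <- function(path, lineno, msg) {
  abort(sprintf("%s:%d: %s", path, lineno, msg), class = "medkg_parse_error")
}

#' @rdname kg_write
#' @export
kg_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "# medkg v1") {
    parse_abort(path, 1L, "not a medkg v1 graph file")
  }
  section <- ""
  concepts <- character()
  ents <- list()
  rels <- list()
  wts <- list()
  required <- c("[concepts]", "[entities]", "[relations]", "[weights]")
  seen <- character()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      if (!ln %in% required) parse_abort(path, i, paste0("unknown section ", ln))
      section <- ln
      seen <- c(seen, ln)
      next
    }
    if (section == "[concepts]") {
      concepts <- c(concepts, ln)
    } else if (section == "[entities]") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 4) parse_abort(path, i, "entity line needs 4 tab-separated fields")
      props <- tryCatch(
        jsonlite::fromJSON(f[4], simplifyVector = TRUE, simplifyMatrix = FALSE),
        error = function(e) parse_abort(path, i, "bad properties JSON")
      )
      ents[[length(ents) + 1L]] <- list(
        id = as.integer(f[1]), name = f[2], concept = f[3],
        properties = purrr::map(as.list(props), as.character)
      )
    } else if (section == "[relations]") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 4) parse_abort(path, i, "relation line needs 4 tab-separated fields")
      w <- suppressWarnings(as.double(f[4]))
      if (is.na(w)) parse_abort(path, i, "bad weight")
      rels[[length(rels) + 1L]] <- list(
        src = as.integer(f[1]), dst = as.integer(f[2]), rel_type = f[3], weight = w
      )
    } else if (section == "[weights]") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 2) parse_abort(path, i, "weight line needs 2 tab-separated fields")
      wts[[f[1]]] <- as.double(f[2])
    } else {
      parse_abort(path, i, "content before first section header")
    }
  }
  if (!all(required %in% seen)) {
    parse_abort(path, length(lines), paste0(
      "truncated graph file; missing section(s): ",
      paste(setdiff(required, seen), collapse = ", ")
    ))
  }
  kg <- kg_new(concepts = concepts, weights = do.call(weight_config, wts))
  if (length(ents)) {
    kg$entities <- tibble(
      id = purrr::map_int(ents, "id"),
      name = purrr::map_chr(ents, "name"),
      norm = normalize_name(purrr::map_chr(ents, "name")),
      concept = purrr::map_chr(ents, "concept"),
      properties = purrr::map(ents, "properties")
    )
    bad <- setdiff(unique(kg$entities$concept), concepts)
    if (length(bad)) parse_abort(path, 1L, paste0("entity concept(s) not declared: ", paste(bad, collapse = ", ")))
    kg$next_id <- max(kg$entities$id) + 1L
  }
  if (length(rels)) {
    kg$relations <- tibble(
      src = purrr::map_int(rels, "src"),
      dst = purrr::map_int(rels, "dst"),
      rel_type = purrr::map_chr(rels, "rel_type"),
      weight = purrr::map_dbl(rels, "weight")
    )
    if (!all(kg$relations$src %in% kg$entities$id) ||
        !all(kg$relations$dst %in% kg$entities$id)) {
      parse_abort(path, 1L, "relation references an undeclared entity id")
    }
  }
  kg
}

#' Export a knowledge graph for external viewers
#'
#' `kg_write_edgelist()` writes a tab-separated edge list
#' (src, dst, rel_type, weight) with entity names, preceded by a header
#' row. `kg_write_graphml()` writes GraphML (via igraph) with name,
#' concept, rel_type and weight attributes.
#'
#' @param kg A `medkg` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kg_write_edgelist <- function(kg, path) {
  rel <- kg$relations
  lines <- c(
    "src\tdst\trel_type\tweight",
    sprintf(
      "%s\t%s\t%s\t%s",
      kg$entities$name[match(rel$src, kg$entities$id)],
      kg$entities$name[match(rel$dst, kg$entities$id)],
      rel$rel_type, format(rel$weight, digits = 17)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname kg_write_edgelist
#' @export
kg_write_graphml <- function(kg, path) {
  g <- kg_as_igraph(kg)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert to an igraph object
#'
#' Directed igraph with vertex attributes `name` (the entity id as a
#' string), `label` and `concept`, and edge attributes `rel_type` and
#' `weight`.
#'
#' @param kg A `medkg` graph.
#' @return An igraph graph.
#' @export
kg_as_igraph <- function(kg) {
  verts <- data.frame(
    name = as.character(kg$entities$id),
    label = kg$entities$name,
    concept = kg$entities$concept,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = as.character(kg$relations$src),
    to = as.character(kg$relations$dst),
    rel_type = kg$relations$rel_type,
    weight = kg$relations$weight,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}
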