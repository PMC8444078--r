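# Shared fixtures and independent oracles.

# Tiny disease-symptom graph: cold -> {cough, fever}, flu -> {fever, chill}.
tiny_kg <- function() {
  kg_new() |>
    kg_add_entity("cold", "disease") |>
    kg_add_entity("flu", "disease") |>
    kg_add_entity("cough", "symptom") |>
    kg_add_entity("fever", "symptom") |>
    kg_add_entity("chill", "symptom") |>
    kg_add_relation("cold", "cough", "main_symptom") |>
    kg_add_relation("cold", "fever", "main_symptom") |>
    kg_add_relation("flu", "fever", "main_symptom") |>
    kg_add_relation("flu", "chill", "main_symptom")
}

# Independent fixed-point oracle: solves the clamped linear system
# (I - M) x = M 1_seeds directly, never iterating. M holds the damped,
# out-|weight|-normalized coefficients of the score recurrence.
oracle_scores <- function(kg, seed_ids, alpha = 0.85, symmetrize = FALSE) {
  ids <- kg$entities$id
  n <- length(ids)
  src <- kg$relations$src
  dst <- kg$relations$dst
  w <- kg$relations$weight
  if (symmetrize) {
    src0 <- src
    src <- c(src, dst)
    dst <- c(dst, src0)
    w <- c(w, w)
  }
  sp <- match(src, ids)
  dp <- match(dst, ids)
  out_abs <- rep(0, n)
  for (k in seq_along(sp)) out_abs[sp[k]] <- out_abs[sp[k]] + abs(w[k])
  M <- matrix(0, n, n)
  for (k in seq_along(sp)) {
    M[dp[k], sp[k]] <- M[dp[k], sp[k]] + (1 - alpha) * alpha * w[k] / out_abs[sp[k]]
  }
  seed_pos <- match(seed_ids, ids)
  free <- setdiff(seq_len(n), seed_pos)
  x <- rep(0, n)
  x[seed_pos] <- 1
  if (length(free)) {
    A <- diag(length(free)) - M[free, free, drop = FALSE]
    b <- M[free, seed_pos, drop = FALSE] %*% rep(1, length(seed_pos))
    x[free] <- solve(A, b)
  }
  setNames(x, as.character(ids))
}

# Random mixed-sign graph for property tests. Uses custom relation types
# with their own polarities so signed weights pass the config check.
random_kg <- function(n_nodes, n_edges, p_negative = 0.3) {
  kg <- kg_new(
    concepts = c("disease", "symptom", "drug"),
    weights = weight_config(pos = 1, neg = -1)
  )
  concepts <- sample(c("disease", "symptom", "drug"), n_nodes, replace = TRUE)
  for (i in seq_len(n_nodes)) {
    kg <- kg_add_entity(kg, paste0("n", i), concepts[i])
  }
  pairs <- expand.grid(src = seq_len(n_nodes), dst = seq_len(n_nodes))
  pairs <- pairs[pairs$src != pairs$dst, ]
  pairs <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  for (k in seq_len(nrow(pairs))) {
    negative <- stats::runif(1) < p_negative
    mag <- stats::runif(1, 0.2, 1)
    kg <- kg_add_relation(
      kg, pairs$src[k], pairs$dst[k],
      rel_type = if (negative) "neg" else "pos",
      weight = if (negative) -mag else mag
    )
  }
  kg
}
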