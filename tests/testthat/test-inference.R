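test_that("a seed with no edges keeps score 1.0 and converges immediately", {
  kg <- kg_new() |>
    kg_add_entity("s", "symptom") |>
    kg_add_entity("x", "disease") |>
    kg_add_entity("y", "drug")
  sv <- weighted_path_rank(kg, "s")
  expect_equal(sv$scores$score, c(1, 0, 0))
  expect_equal(sv$iterations, 1L)
  expect_true(sv$converged)
  expect_error(weighted_path_rank(kg, character()), "non-empty")
  expect_error(weighted_path_rank(kg, "nope"), "unknown entity")
  expect_error(weighted_path_rank(kg, "s", alpha = 1.2), "alpha")
})

test_that("the chain recurrence hits its closed-form fixed point", {
  kg <- kg_new() |>
    kg_add_entity("s", "symptom") |>
    kg_add_entity("d", "disease") |>
    kg_add_entity("r", "drug") |>
    kg_add_relation("s", "d", "main_symptom") |>
    kg_add_relation("d", "r", "indication")
  sv <- weighted_path_rank(kg, "s", alpha = 0.85)
  sc <- setNames(sv$scores$score, sv$scores$name)
  expect_identical(unname(sc["s"]), 1.0)
  expect_equal(unname(sc["d"]), 0.1275, tolerance = 1e-15)
  expect_equal(unname(sc["r"]), 0.01625625, tolerance = 1e-15)
})

test_that("iterated scores match the direct linear-system oracle", {
  set.seed(7)
  for (rep in 1:20) {
    kg <- random_kg(sample(5:30, 1), sample(8:60, 1))
    ids <- kg_entities(kg)$id
    seeds <- sample(ids, sample(1:3, 1))
    sv <- weighted_path_rank(kg, seeds, threshold = 1e-8)
    exact <- oracle_scores(kg, seeds)
    expect_lt(max(abs(sv$scores$score - exact)), 10 * 1e-8)
  }
})

test_that("positive-weight graphs give non-negative scores and geometric convergence", {
  set.seed(21)
  bound <- ceiling(log(1e-6) / log((1 - 0.85) * 0.85)) + 1
  for (rep in 1:10) {
    kg <- random_kg(sample(5:25, 1), sample(8:50, 1), p_negative = 0)
    ids <- kg_entities(kg)$id
    sv <- weighted_path_rank(kg, sample(ids, 2))
    expect_true(all(sv$scores$score >= 0))
    expect_identical(sv$scores$score[match(sv$seeds, sv$scores$id)], c(1, 1))
    expect_true(sv$converged)
    expect_lte(sv$iterations, bound)
  }
})

test_that("candidate selection restricts to the concept and ranks deterministically", {
  fx <- worked_example_fixtures()$diagnosis
  seeds <- c(
    kg_entity_id(fx$kg, "cough"), kg_entity_id(fx$kg, "pectoralgia"),
    kg_entity_id(fx$kg, "shiver"), kg_entity_id(fx$kg, "fever")
  )
  sv <- weighted_path_rank(fx$kg, seeds, symmetrize = TRUE)
  ranked <- select_candidates(sv, fx$kg, "disease")
  expect_equal(ranked$name[1], "Pneumonia")
  expect_true(all(diff(ranked$score) <= 0))
  expect_true(all(!ranked$id %in% seeds))

  # single-disease graph: that disease ranks first trivially
  ckg <- worked_example_fixtures()$cold$kg
  sv2 <- weighted_path_rank(ckg, "cough", symmetrize = TRUE)
  expect_equal(select_candidates(sv2, ckg, "disease")$name[1], "cold")

  # no positive-scored entity of the concept -> explicit no-answer error
  expect_error(
    select_candidates(sv2, ckg, "drug"),
    "no answer", class = "medkgqa_no_answer"
  )
})

test_that("diseases with identical neighborhoods tie exactly, broken by id", {
  kg <- kg_new() |>
    kg_add_entity("d1", "disease") |>
    kg_add_entity("d2", "disease") |>
    kg_add_entity("s1", "symptom") |>
    kg_add_entity("s2", "symptom") |>
    kg_add_relation("d1", "s1", "main_symptom") |>
    kg_add_relation("d1", "s2", "main_symptom") |>
    kg_add_relation("d2", "s1", "main_symptom") |>
    kg_add_relation("d2", "s2", "main_symptom")
  seeds <- c(kg_entity_id(kg, "s1"), kg_entity_id(kg, "s2"))
  sv <- weighted_path_rank(kg, seeds, symmetrize = TRUE)
  ranked <- select_candidates(sv, kg, "disease")
  expect_equal(ranked$score[1], ranked$score[2])
  expect_equal(ranked$name, c("d1", "d2"))
  # symmetry verified against the exact solve
  exact <- oracle_scores(kg, seeds, symmetrize = TRUE)
  expect_equal(unname(exact[as.character(ranked$id[1])]),
               unname(exact[as.character(ranked$id[2])]))
})

test_that("a wider seed neighborhood never scores below a contained one", {
  # disease A receives from seeds s1, s2, s3; disease B only from s1, s2;
  # s3 also feeds a dummy so all seeds have equal out-weight totals
  kg <- kg_new() |>
    kg_add_entity("A", "disease") |>
    kg_add_entity("B", "disease") |>
    kg_add_entity("D", "disease") |>
    kg_add_entity("s1", "symptom") |>
    kg_add_entity("s2", "symptom") |>
    kg_add_entity("s3", "symptom") |>
    kg_add_relation("s1", "A", "main_symptom") |>
    kg_add_relation("s1", "B", "main_symptom") |>
    kg_add_relation("s2", "A", "main_symptom") |>
    kg_add_relation("s2", "B", "main_symptom") |>
    kg_add_relation("s3", "A", "main_symptom") |>
    kg_add_relation("s3", "D", "main_symptom")
  seeds <- c(kg_entity_id(kg, "s1"), kg_entity_id(kg, "s2"), kg_entity_id(kg, "s3"))
  sv <- weighted_path_rank(kg, seeds)
  sc <- setNames(sv$scores$score, sv$scores$name)
  expect_gte(unname(sc["A"]), unname(sc["B"]))
})

test_that("a taboo edge from a seed strictly lowers the drug's score", {
  base <- kg_new() |>
    kg_add_entity("sym", "symptom") |>
    kg_add_entity("pop", "population") |>
    kg_add_entity("drug1", "drug") |>
    kg_add_relation("sym", "drug1", "indication")
  seeds <- c(kg_entity_id(base, "sym"), kg_entity_id(base, "pop"))
  with_taboo <- kg_add_relation(base, "pop", "drug1", "taboo_population")
  s0 <- weighted_path_rank(base, seeds)
  s1 <- weighted_path_rank(with_taboo, seeds)
  d0 <- s0$scores$score[s0$scores$name == "drug1"]
  d1 <- s1$scores$score[s1$scores$name == "drug1"]
  expect_lt(d1, d0)
})

test_that("property lookup reads properties, falls back to typed neighbors", {
  ckg <- worked_example_fixtures()$cold$kg
  # relation fallback: symptom neighbors of cold
  expect_equal(property_lookup(ckg, "cold", "symptom"), c("cough", "fever"))
  # direct property retrieval
  expect_equal(
    property_lookup(ckg, "cold", "prevention"),
    "wash hands often and rest well"
  )
  # nothing stored -> explicit unknown
  expect_error(
    property_lookup(ckg, "cold", "diet"),
    "unknown", class = "medkgqa_unknown"
  )
})

test_that("score vectors dump to a ranked tab-separated file", {
  kg <- tiny_kg()
  sv <- weighted_path_rank(kg, "cough", symmetrize = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(sv, path)
  lines <- readLines(path)
  expect_equal(lines[1], "entity\tconcept\tscore")
  expect_equal(length(lines), nrow(kg_entities(kg)) + 1L)
  expect_match(lines[2], "^cough\tsymptom\t1")
})
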