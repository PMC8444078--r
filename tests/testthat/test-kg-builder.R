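# Worked gastritis instruction: free text naming three main symptoms and
# two complications, matched against a five-symptom dictionary.

test_that("template rules extract dictionary symptoms from enumeration spans", {
  fx <- worked_example_fixtures()$gastritis
  main_rule <- default_template_rules()[[1]]
  comp_rule <- default_template_rules()[[2]]
  expect_equal(
    apply_template_rule(fx$text, main_rule, fx$dictionary),
    c("Upper abdominal pain", "Nausea", "Vomiting")
  )
  expect_equal(
    apply_template_rule(fx$text, comp_rule, fx$dictionary),
    c("Bleeding", "Stomach ulcers")
  )
  # no anchor phrase -> nothing extracted
  expect_equal(
    apply_template_rule("A dull paragraph about the stomach.", main_rule, fx$dictionary),
    character()
  )
  # non-dictionary items in the enumeration are dropped
  expect_equal(
    apply_template_rule(
      "the common is nausea, mild malaise, vomiting.", main_rule, fx$dictionary
    ),
    c("Nausea", "Vomiting")
  )
})

test_that("parsing the gastritis instruction yields the worked extraction", {
  fx <- worked_example_fixtures()$gastritis
  parsed <- parse_instruction(fx$record, dictionary = fx$dictionary)
  expect_equal(
    parsed$entities$name,
    c("Gastritis", "Upper abdominal pain", "Nausea", "Vomiting",
      "Bleeding", "Stomach ulcers")
  )
  expect_equal(parsed$entities$concept, c("disease", rep("symptom", 5)))
  rel <- parsed$relations
  expect_equal(nrow(rel), 5L)
  expect_equal(
    rel$weight[rel$dst_name == "Upper abdominal pain"], 1.0
  )
  expect_equal(rel$weight[rel$rel_type == "complication"], c(0.5, 0.5))
  # the alternative reading scores complications like main symptoms
  parsed2 <- parse_instruction(
    fx$record, dictionary = fx$dictionary,
    weights = weight_config(complication = 1.0)
  )
  expect_equal(unique(parsed2$relations$weight), 1.0)
})

test_that("structured field lists map directly to relations without rules", {
  rec <- instruction_record("drug", "Tetracyclines", fields = list(
    adaptation_disease = "acne",
    taboo_population = c("pregnant woman", "infant")
  ))
  parsed <- parse_instruction(rec)
  expect_equal(nrow(parsed$relations), 3L)
  expect_equal(
    parsed$relations$weight[parsed$relations$rel_type == "taboo_population"],
    c(-1, -1)
  )
  # free text without any anchor: head entity only, zero relations
  rec2 <- instruction_record("disease", "Colitis", fields = list(
    description = "Colitis affects the large intestine."
  ))
  parsed2 <- parse_instruction(rec2, dictionary = c(cramp = "symptom"))
  expect_equal(parsed2$entities$name, "Colitis")
  expect_equal(nrow(parsed2$relations), 0L)
  # records validate their field vocabulary up front
  expect_error(instruction_record("disease", "X", fields = list(flavor = "sweet")), "unknown instruction field")
  expect_error(instruction_record("disease", ""), "common name")
})

test_that("graph building merges entities and is deterministic and idempotent", {
  fx <- worked_example_fixtures()$gastritis
  kg <- build_graph(list(fx$record), dictionary = fx$dictionary)
  expect_equal(nrow(kg_entities(kg)), 6L)
  expect_equal(nrow(kg_relations(kg)), 5L)

  # the same record twice builds the identical graph
  kg2 <- build_graph(list(fx$record, fx$record), dictionary = fx$dictionary)
  expect_equal(kg_entities(kg2), kg_entities(kg))
  expect_equal(kg_relations(kg2), kg_relations(kg))

  # two diseases sharing a symptom share one symptom node with 2 in-edges
  recs <- list(
    instruction_record("disease", "cold", fields = list(main_symptom = c("cough", "fever"))),
    instruction_record("disease", "flu", fields = list(main_symptom = c("fever", "chill")))
  )
  kg3 <- build_graph(recs)
  expect_equal(sum(kg_entities(kg3)$concept == "symptom"), 3L)
  expect_equal(nrow(kg_neighbors(kg3, "fever", "in")), 2L)

  # determinism across runs
  kg4 <- build_graph(recs)
  expect_identical(kg_relations(kg4), kg_relations(kg3))

  # every stored weight comes from the weight configuration
  w <- weight_config()
  rel <- kg_relations(kg3)
  expect_true(all(rel$weight == unlist(w)[rel$rel_type]))
})

test_that("instruction files and rule configs round-trip", {
  recs <- list(
    instruction_record("disease", "cold", fields = list(
      main_symptom = c("cough", "fever"), treatment = "rest"
    )),
    instruction_record("drug", "Aspirin", fields = list(adaptation_disease = "cold"))
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_instructions(recs, path)
  back <- read_instructions(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$fields$main_symptom, c("cough", "fever"))
  expect_equal(back[[2]]$kind, "drug")

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "weights:",
    "  complication: 1.0",
    "rules:",
    "  - id: ms",
    "    head_concept: disease",
    "    tail_concept: symptom",
    "    rel_type: main_symptom",
    "    anchors: ['the common is']"
  ), cfg_path)
  cfg <- read_kg_config(cfg_path)
  expect_equal(cfg$weights$complication, 1.0)
  expect_equal(cfg$weights$main_symptom, 1.0)
  expect_equal(cfg$rules[[1]]$anchors, "the common is")
})
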