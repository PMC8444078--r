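# The 4-question corpus used throughout: two categories A/B with equal
# priors; feature "f" occurs in both A questions and no B question.
# Hand evaluation of the score: p(f|A) = 1, p(f) = 1/2, p(A) = 1/2, so
# IG(f, A) = 1 * ln(1 / (1/2 * 1/2)) = ln 4; IG(f, B) = 0.
toy_corpus <- function() {
  tibble::tibble(
    features = list(
      c("f", "u"), c("f", "v"),
      c("g", "u"), c("g", "w")
    ),
    category = c("A", "A", "B", "B")
  )
}

test_that("entity extraction reproduces the case-study question", {
  fx <- worked_example_fixtures()$diagnosis
  sq <- extract_entities(fx$question, fx$kg)
  expect_setequal(
    unique(sq$matched$surface),
    c("child", "cough", "pectoralgia", "shiver", "fever", "disease")
  )
  sq <- generalize(sq)
  expect_equal(
    sq$features,
    c("@population", "has", "@symptom", "@symptom", "@symptom", "@symptom",
      "recently", "what", "disease", "@population", "have")
  )
})

test_that("generalization handles the prevention example and empty matches", {
  fx <- worked_example_fixtures()$cold
  sq <- generalize(extract_entities("How to prevent a cold?", fx$kg))
  expect_equal(sq$features, c("how", "prevent", "@disease"))
  # question with no graph terms
  sq2 <- generalize(extract_entities("Why is the sky blue?", fx$kg))
  expect_equal(nrow(sq2$matched), 0L)
  expect_equal(sq2$features, c("why", "sky", "blue"))
})

test_that("multi-word names win by longest match over their parts", {
  kg <- kg_new() |>
    kg_add_entity("pain", "symptom") |>
    kg_add_entity("upper abdominal pain", "symptom")
  sq <- extract_entities("I feel upper abdominal pain today", kg)
  expect_equal(sq$matched$surface, "upper abdominal pain")
  expect_equal(nrow(sq$matched), 1L)
})

test_that("information gain matches the hand-computed corpus values", {
  model <- train_intent_classifier(toy_corpus())
  expect_equal(information_gain("f", "A", model), log(4))
  expect_equal(information_gain("f", "B", model), 0) # p(f|B) = 0 convention
  expect_equal(information_gain("u", "A", model), 0.5 * log(0.5 / (0.5 * 0.5)))
  # unknown feature or category contributes nothing
  expect_equal(information_gain("zzz", "A", model), 0)
  expect_equal(information_gain("f", "Z", model), 0)
})

test_that("training is invariant to duplication and example order", {
  base <- toy_corpus()
  m1 <- train_intent_classifier(base)
  m2 <- train_intent_classifier(dplyr::bind_rows(base, base))
  expect_equal(m1$ig, m2$ig)
  expect_equal(m1$priors, m2$priors)
  m3 <- train_intent_classifier(base[c(3, 1, 4, 2), ])
  expect_equal(m1$ig, m3$ig)
  expect_error(train_intent_classifier(base[0, ]), "empty")
})

test_that("classification takes the arg-max with documented tie and threshold rules", {
  model <- train_intent_classifier(toy_corpus())
  res <- classify_intent(c("f"), model)
  expect_equal(res$category, "A")
  expect_equal(res$values$value[res$values$category == "A"], log(4))
  # feature order and repetition do not change the value vector (one-hot)
  r2 <- classify_intent(c("u", "f", "f", "u"), model)
  r3 <- classify_intent(c("f", "u"), model)
  expect_equal(r2$values, r3$values)
  # only unknown words -> zero value everywhere -> unsupported
  expect_equal(classify_intent(c("xyzzy", "qwert"), model)$category, "unsupported")
  # symmetric evidence ties break to the lexicographically smaller label
  tie <- classify_intent(c("u"), train_intent_classifier(tibble::tibble(
    features = list("u", "u"), category = c("B", "A")
  )))
  expect_equal(tie$category, "A")
})

test_that("a single-category training set classifies everything to it", {
  one <- tibble::tibble(features = list(c("f"), c("g")), category = c("A", "A"))
  model <- suppressWarnings(train_intent_classifier(one))
  expect_equal(classify_intent("f", model)$category, "A")
  expect_equal(classify_intent("g", model)$category, "A")
})

test_that("joint variant sends independent features to (near) zero IG", {
  # "x" occurs in exactly half the questions of each category: independent
  corpus <- tibble::tibble(
    features = list(
      c("x", "ka"), c("ka"), c("x", "kb"), c("kb")
    ),
    category = c("A", "A", "B", "B")
  )
  mj <- train_intent_classifier(corpus, variant = "joint")
  expect_lt(abs(information_gain("x", "A", mj)), 1e-9)
  expect_lt(abs(information_gain("x", "B", mj)), 1e-9)
  # the literal form does not have this property (documented conflict)
  ml <- train_intent_classifier(corpus, variant = "literal")
  expect_gt(abs(information_gain("x", "A", ml)), 0.1)
})

test_that("separable corpora are recovered with full training accuracy", {
  set.seed(3)
  cats <- paste0("c", 1:5)
  corpus <- dplyr::bind_rows(purrr::map(cats, function(ck) {
    tibble::tibble(
      features = purrr::map(1:6, ~ c(paste0("key_", ck), sample(letters[1:8], 3))),
      category = ck
    )
  }))
  model <- train_intent_classifier(corpus)
  pred <- vapply(corpus$features, function(f) classify_intent(f, model)$category, "")
  expect_equal(mean(pred == corpus$category), 1.0)
})

test_that("the IG model serializes losslessly", {
  model <- train_intent_classifier(toy_corpus())
  path <- withr::local_tempfile(fileext = ".txt")
  write_ig_model(model, path)
  back <- read_ig_model(path)
  expect_equal(back$ig, model$ig)
  expect_equal(back$priors, model$priors)
  expect_equal(back$p_x, model$p_x)
  expect_equal(back$variant, model$variant)
  expect_equal(
    classify_intent("f", back)$values, classify_intent("f", model)$values
  )
})

test_that("labeled-question files round-trip", {
  tbl <- tibble::tibble(
    question = c("How to prevent a cold?", "What are the symptoms of flu?"),
    category = c("prevention", "symptom"),
    gold = c("cold", "flu")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_questions(tbl, path)
  expect_equal(read_labeled_questions(path), tbl)
  writeLines(character(), path)
  expect_error(read_labeled_questions(path), "no labeled questions")
})
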