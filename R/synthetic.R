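#' Configuration for the synthetic medical corpus
#'
#' The generator emulates the structure of a drug/disease instruction
#' corpus with known ground truth: each disease carries a set of main
#' symptoms (strong, weight-1.0 relations) and a share of complications
#' (weak, 0.5); drugs carry indication links to diseases and
#' taboo-population links; `symptom_overlap` controls how much diseases
#' share symptoms and therefore how ambiguous diagnosis is (0 = disjoint
#' symptom sets, 1 = one shared pool). Everything is fully determined by
#' `seed`.
#'
#' @param n_diseases,n_symptoms,n_drugs Entity counts.
#' @param symptoms_per_disease Main symptoms per disease.
#' @param complication_fraction Complications per disease as a fraction of
#'   `symptoms_per_disease`, in \[0, 1\].
#' @param symptom_overlap Fraction of each disease's main symptoms drawn
#'   from a pool common to all diseases, in \[0, 1\].
#' @param taboo_fraction Fraction of drugs with a taboo-population link.
#' @param questions_per_category Questions generated per category.
#' @param seed Integer RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_diseases = 12, n_symptoms = 80, n_drugs = 12,
                         symptoms_per_disease = 4, complication_fraction = 0.5,
                         symptom_overlap = 0, taboo_fraction = 0.5,
                         questions_per_category = 12, seed = 1) {
  stopifnot(
    n_diseases >= 1, n_symptoms >= 1, n_drugs >= 0, symptoms_per_disease >= 1,
    complication_fraction >= 0, complication_fraction <= 1,
    symptom_overlap >= 0, symptom_overlap <= 1,
    taboo_fraction >= 0, taboo_fraction <= 1, questions_per_category >= 1
  )
  structure(
    list(
      n_diseases = as.integer(n_diseases), n_symptoms = as.integer(n_symptoms),
      n_drugs = as.integer(n_drugs),
      symptoms_per_disease = as.integer(symptoms_per_disease),
      complication_fraction = complication_fraction,
      symptom_overlap = symptom_overlap, taboo_fraction = taboo_fraction,
      questions_per_category = as.integer(questions_per_category),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

synth_name_pools <- function() {
  adjectives <- c(
    "aching", "burning", "dull", "sharp", "persistent", "mild", "severe",
    "chronic", "sudden", "throbbing", "itchy", "swollen"
  )
  nouns <- c(
    "headache", "cough", "rash", "fatigue", "nausea", "dizziness", "cramp",
    "fever", "stiffness", "numbness", "chill", "soreness", "tremor", "wheeze"
  )
  symptoms <- as.vector(outer(adjectives, nouns, paste))
  dis_pre <- c(
    "vel", "dor", "mira", "tal", "quen", "bri", "sor", "fen", "lum", "cra",
    "zet", "pol", "gar", "nex", "tor", "hal"
  )
  dis_suf <- c("itis", "osis", "emia", "algia", "opathy", "oma")
  diseases <- as.vector(outer(dis_pre, dis_suf, paste0))
  drug_pre <- c("vex", "dal", "mor", "qui", "zan", "pir", "lev", "cor", "tam", "fex")
  drug_suf <- c("cillin", "mycin", "zole", "pril", "axine", "mab")
  drugs <- as.vector(outer(drug_pre, drug_suf, paste0))
  populations <- c(
    "pregnant woman", "child", "elderly person", "infant",
    "nursing mother", "teenager"
  )
  body_parts <- c("head", "chest", "stomach", "back", "throat", "skin")
  list(
    symptoms = symptoms, diseases = diseases, drugs = drugs,
    populations = populations, body_parts = body_parts
  )
}

#' Generate a synthetic instruction corpus
#'
#' Produces one disease instruction per disease (main symptoms,
#' complications, treatment/prevention/cause/diet properties, body part)
#' and one drug instruction per drug (indicated disease, optional taboo
#' population). Reproducible under the config seed; the same config run
#' twice yields identical records.
#'
#' @param cfg A [synth_config()].
#' @return List of `medkg_instruction` records (diseases first).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pools <- synth_name_pools()
  spd <- cfg$symptoms_per_disease
  n_shared <- round(cfg$symptom_overlap * spd)
  n_comp <- round(cfg$complication_fraction * spd)
  needed <- n_shared + cfg$n_diseases * (spd - n_shared + n_comp)
  if (cfg$n_symptoms > length(pools$symptoms)) {
    abort(sprintf("n_symptoms exceeds the name pool (%d)", length(pools$symptoms)))
  }
  if (needed > cfg$n_symptoms) {
    abort(sprintf(
      "infeasible config: %d distinct symptoms required but n_symptoms = %d",
      needed, cfg$n_symptoms
    ))
  }
  if (cfg$n_diseases > length(pools$diseases) || cfg$n_drugs > length(pools$drugs)) {
    abort("entity counts exceed the name pools")
  }
  withr::with_seed(cfg$seed, {
    symptoms <- sample(pools$symptoms, cfg$n_symptoms)
    diseases <- sample(pools$diseases, cfg$n_diseases)
    drugs <- if (cfg$n_drugs) sample(pools$drugs, cfg$n_drugs) else character()
    shared <- if (n_shared) symptoms[seq_len(n_shared)] else character()
    rest <- symptoms[setdiff(seq_len(cfg$n_symptoms), seq_len(n_shared))]
    treatments <- c(
      "rest and drink plenty of fluids", "a short course of antibiotics",
      "cold compresses twice daily", "light exercise and physiotherapy"
    )
    preventions <- c(
      "wash hands often and sleep well", "avoid crowded places in winter",
      "keep a balanced daily routine", "get vaccinated every year"
    )
    causes <- c(
      "a viral infection", "a bacterial infection",
      "an allergic reaction", "chronic inflammation"
    )
    diets <- c(
      "warm soup and soft food", "plenty of fresh vegetables",
      "low salt and low fat meals", "small frequent light meals"
    )
    records <- list()
    for (i in seq_len(cfg$n_diseases)) {
      n_unique <- spd - n_shared
      block <- rest[seq_len(n_unique + n_comp) + (i - 1L) * (n_unique + n_comp)]
      mains <- c(shared, block[seq_len(n_unique)])
      comps <- if (n_comp) block[n_unique + seq_len(n_comp)] else character()
      cyc <- function(pool) pool[(i - 1L) %% length(pool) + 1L]
      records[[length(records) + 1L]] <- instruction_record(
        "disease", diseases[i],
        fields = list(
          main_symptom = mains,
          complication_symptom = comps,
          body = cyc(pools$body_parts),
          treatment = cyc(treatments),
          prevention = cyc(preventions),
          cause = cyc(causes),
          diet = cyc(diets)
        )
      )
    }
    has_taboo <- logical(length(drugs))
    for (j in seq_along(drugs)) {
      fields <- list(adaptation_disease = diseases[(j - 1L) %% cfg$n_diseases + 1L])
      # guarantee at least one contraindicated drug whenever the fraction
      # is positive, so taboo-population questions always have a subject
      if (stats::runif(1) < cfg$taboo_fraction ||
          (j == length(drugs) && !any(has_taboo) && cfg$taboo_fraction > 0)) {
        fields$taboo_population <- sample(pools$populations, 1)
        has_taboo[j] <- TRUE
      }
      records[[length(records) + 1L]] <- instruction_record("drug", drugs[j], fields)
    }
    records
  })
}

synth_phrasings <- function() {
  list(
    disease_diagnosis = c(
      "I have %s recently. What disease do I have?",
      "Having %s lately. Which disease could this be?"
    ),
    symptom = c(
      "What are the symptoms of %s?",
      "Which symptoms does %s show?"
    ),
    treatment = c(
      "What treatment helps with %s?",
      "Which treatment is used for %s?"
    ),
    diet = c(
      "What diet suits someone with %s?",
      "Which diet should people with %s follow?"
    ),
    cause = c(
      "What is the cause of %s?",
      "What can cause %s?"
    ),
    drug_recommendation = c(
      "Can you recommend a drug for %s?",
      "Which drug would you recommend against %s?"
    ),
    taboo_population = c(
      "Who is taboo for %s?",
      "Which people are taboo when taking %s?"
    ),
    indication = c(
      "What is the indication of %s?",
      "Which illness is the indication for %s?"
    ),
    prevention = c(
      "How to prevent %s?",
      "What helps prevent %s?"
    )
  )
}

#' Generate labeled questions with known gold answers
#'
#' For each of the nine categories, phrases `questions_per_category`
#' questions from small English template pools, embedding true entity
#' names from the graph. Diagnosis questions list a disease's full main
#' symptom set (gold = that disease); lookup-category questions name
#' their subject entity, with the gold answer read off the graph by
#' construction.
#'
#' @param kg A `medkg` graph built from [generate_corpus()] output.
#' @param cfg The same [synth_config()].
#' @return Tibble with columns `question`, `category`, `gold`.
#' @export
generate_questions <- function(kg, cfg) {
  stopifnot(inherits(kg, "medkg"), inherits(cfg, "synth_config"))
  ent <- kg$entities
  diseases <- ent$id[ent$concept == "disease"]
  drugs <- ent$id[ent$concept == "drug"]
  if (length(diseases) == 0) abort("graph has no disease entities to ask about")
  phr <- synth_phrasings()
  name_of <- function(id) ent$name[match(id, ent$id)]
  rows <- list()
  for (cat in question_categories()) {
    pool <- phr[[cat]]
    subj_ids <- if (cat %in% c("taboo_population", "indication")) drugs else diseases
    if (cat == "drug_recommendation") {
      # only diseases with at least one indicated drug
      subj_ids <- diseases[vapply(diseases, function(d) {
        nrow(kg_neighbors(kg, d, "in", rel_type = "indication")) > 0
      }, logical(1))]
    }
    if (cat == "taboo_population") {
      subj_ids <- drugs[vapply(drugs, function(d) {
        nrow(kg_neighbors(kg, d, "out", rel_type = "taboo_population")) > 0
      }, logical(1))]
    }
    if (length(subj_ids) == 0) {
      abort(paste0("category '", cat, "' has no supporting entities in the graph"))
    }
    for (q in seq_len(cfg$questions_per_category)) {
      subj <- subj_ids[(q - 1L) %% length(subj_ids) + 1L]
      phrase <- pool[(q - 1L) %% length(pool) + 1L]
      if (cat == "disease_diagnosis") {
        mains <- kg_neighbors(kg, subj, "out", rel_type = "main_symptom")$name
        text <- sprintf(phrase, join_prose(mains))
        gold <- name_of(subj)
      } else if (cat == "drug_recommendation") {
        text <- sprintf(phrase, name_of(subj))
        gold <- kg_neighbors(kg, subj, "in", rel_type = "indication")$name[1]
      } else if (cat == "indication") {
        text <- sprintf(phrase, name_of(subj))
        gold <- kg_neighbors(kg, subj, "out", rel_type = "indication")$name[1]
      } else if (cat == "taboo_population") {
        text <- sprintf(phrase, name_of(subj))
        gold <- kg_neighbors(kg, subj, "out", rel_type = "taboo_population")$name[1]
      } else if (cat == "symptom") {
        text <- sprintf(phrase, name_of(subj))
        gold <- paste(
          kg_neighbors(kg, subj, "out", rel_type = c("main_symptom", "complication"))$name,
          collapse = "; "
        )
      } else {
        text <- sprintf(phrase, name_of(subj))
        gold <- paste(kg_property(kg, subj, category_slot(cat)), collapse = "; ")
      }
      rows[[length(rows) + 1L]] <- tibble(question = text, category = cat, gold = gold)
    }
  }
  dplyr::bind_rows(rows)
}

#' Worked-example fixtures
#'
#' Three small fixtures mirroring the classic worked examples of this
#' kind of system: (a) a gastritis instruction whose free text names five
#' symptoms, with its matching dictionary; (b) a two-disease
#' diagnosis graph (Pneumonia with cough, pectoralgia, shiver, fever;
#' Cold with cough and fever, plus a child population entity) and the
#' diagnosis question whose answer is Pneumonia; (c) a single-disease
#' cold graph with symptom relations and a prevention property.
#'
#' @return Named list with elements `gastritis` (`text`, `dictionary`,
#'   `record`), `diagnosis` (`kg`, `question`, `gold`) and `cold`
#'   (`kg`, `questions`).
#' @export
worked_example_fixtures <- function() {
  gastritis_text <- paste0(
    "Gastritis is inflammation of the lining of the stomach, ..., ",
    "the common is upper abdominal pain, nausea, vomiting .... ",
    "Complications may include bleeding, stomach ulcers, ..."
  )
  gastritis_dict <- setNames(
    rep("symptom", 5),
    c("Upper abdominal pain", "Nausea", "Vomiting", "Bleeding", "Stomach ulcers")
  )
  gastritis_record <- instruction_record(
    "disease", "Gastritis", fields = list(description = gastritis_text)
  )

  dkg <- kg_new() |>
    kg_add_entity("Pneumonia", "disease") |>
    kg_add_entity("Cold", "disease") |>
    kg_add_entity("cough", "symptom") |>
    kg_add_entity("pectoralgia", "symptom") |>
    kg_add_entity("shiver", "symptom") |>
    kg_add_entity("fever", "symptom") |>
    kg_add_entity("child", "population") |>
    kg_add_relation("Pneumonia", "cough", "main_symptom") |>
    kg_add_relation("Pneumonia", "pectoralgia", "main_symptom") |>
    kg_add_relation("Pneumonia", "shiver", "main_symptom") |>
    kg_add_relation("Pneumonia", "fever", "main_symptom") |>
    kg_add_relation("Cold", "cough", "main_symptom") |>
    kg_add_relation("Cold", "fever", "main_symptom")

  ckg <- kg_new() |>
    kg_add_entity(
      "cold", "disease",
      properties = list(prevention = "wash hands often and rest well")
    ) |>
    kg_add_entity("cough", "symptom") |>
    kg_add_entity("fever", "symptom") |>
    kg_add_relation("cold", "cough", "main_symptom") |>
    kg_add_relation("cold", "fever", "main_symptom")

  list(
    gastritis = list(
      text = gastritis_text, dictionary = gastritis_dict, record = gastritis_record
    ),
    diagnosis = list(
      kg = dkg,
      question = paste0(
        "My child has a cough, a pectoralgia, a shiver and a fever recently. ",
        "What disease does my child have?"
      ),
      gold = "Pneumonia"
    ),
    cold = list(
      kg = ckg,
      questions = c(
        prevention = "How to prevent a cold?",
        symptom = "What are the symptoms of a cold?"
      )
    )
  )
}
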