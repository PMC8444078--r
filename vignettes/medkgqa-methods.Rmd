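---
title: "Methods: signed-graph construction, intent classification, and path-ranking inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed-graph construction, intent classification, and path-ranking inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medkgqa)
```

`medkgqa` answers medical questions over a knowledge graph built from
drug and disease instruction records. This vignette documents the model,
its assumptions, the tunable parameters, and the numerical and design
choices — including the places where the design was genuinely open and a
choice had to be made.

## The knowledge graph

The graph KG = (E, R, W, S, C) stores typed entities (concepts:
`disease`, `symptom`, `drug`, `sex`, `population`, `body_part`;
extensible), directed relations with signed weights, and per-entity
property maps for narrative fields (treatment, prevention, cause, diet).
Entity identity is the pair (normalized name, concept), where
normalization trims, case-folds, and collapses internal whitespace —
instruction corpora connect entities by their common names, and
"Gastritis" and "gastritis " must resolve to one node.

**Weight scheme.** Weights are relation-type defaults from
`weight_config()`: `main_symptom` 1.0, `complication` 0.5, `indication`
1.0, `taboo_population` −1.0. The half-weight complication encodes that a
complication is weaker diagnostic evidence than a main symptom; the
negative taboo weight lets contraindications actively push a drug down
the ranking rather than merely not supporting it. Worked examples of
this kind of system sometimes score complications at 1.0; the
configuration makes either reading reproducible
(`weight_config(complication = 1.0)`).

**Edge direction.** Relations are stored directed, head → tail as
extracted (disease→symptom, drug→disease, drug→population). Direction is
a modelling choice the data does not force: topology statistics
(`kg_stats()`) therefore use the *undirected simple projection* — each
unordered pair counted once, average neighbors 2E/N, density
2E/(N(N−1)), both 0 for N ≤ 1 — while inference can traverse either
directed or symmetrized views (below).

**Extraction.** Structured fields map one listed name to one edge.
Free text goes through semantic-template rules: a rule fires on literal
anchor phrases ("the common is", "Complications may include"); the
enumeration span after an anchor ends at the next sentence terminator or
the next anchor (the corpus format never states where a list ends, so
the sentence boundary is the conservative choice); items are split on
separators and kept only when the longest case-insensitive dictionary
match of the rule's tail concept succeeds. This is deliberately a
high-precision, hand-crafted-rule engine — no statistical extraction —
because the graph is built once, offline, and errors in it poison every
downstream answer. Duplicate (src, dst, type) edges keep the
maximum-magnitude weight, treating repeated evidence as confirmation
rather than accumulation.

## Question understanding

Questions are tokenized (lower-cased, split on punctuation), stop words
removed, and entity mentions found by longest-match-first scanning of
token n-grams against the graph's name index (left to right,
non-overlapping, so "upper abdominal pain" beats "pain"). Matched
mentions are generalized to concept placeholders (`@disease`,
`@symptom`), which is what lets a classifier trained on questions about
one disease transfer to questions about any disease. A bare concept
label used as a word ("what *disease* do I have") is recorded as a match
but kept literal — the word itself is a strong intent cue and
generalizing it away would discard it; `match_concept_names = FALSE`
disables this. The default stop-word list keeps auxiliaries such as
"has"/"have": they survive into structured question text and carry mild
intent signal.

**Intent model.** For feature x and category c,

$$IG(x, c) = p(x \mid c)\,\ln\!\frac{p(x \mid c)}{p(x)\,p(c)}$$

with probabilities estimated as question frequencies (presence-based,
one-hot: repeating a word changes nothing), and IG ≔ 0 whenever
p(x|c) = 0. A question's value for c is the sum of IG over its present
features; the arg-max category is returned.

Two variants exist because the conditional form above, taken literally,
does *not* vanish for a feature independent of the categories (the log
term tends to ln(1/p(c)) > 0). The default `variant = "literal"` keeps
the conditional form; `variant = "joint"` substitutes the joint
probability p(x, c), under which independent features score exactly zero
on exact-count corpora — the property the pointwise-mutual-information
reading promises. Fidelity to the stated formula is the default;
correctness is an option.

**Decision rule.** Unsupported questions: a question is refused when it
contains no feature the model knows, or when its best value is negative.
A best value of exactly zero on *known* features still resolves by
arg-max — this keeps the degenerate one-category model classifying
everything into its only category (where every value is identically 0
since p(c) = 1) while still refusing pure gibberish. Ties break to the
lexicographically smallest label, making classification independent of
feature and training order. Optional add-one smoothing exists
(`smoothing`, default 0 = off).

## Path-ranking inference

For diagnosis and drug recommendation, the question's matched entities
are *seeds*, clamped at score 1.0; all other scores start at 0 and are
updated synchronously:

$$WScore(e_i) = (1-\alpha)\,\alpha \sum_{e_j \in In(e_i)}
  \frac{w_{j,i}}{\sum_{e_k \in Out(e_j)} |w_{j,k}|}\; WScore(e_j)$$

- **Clamping.** The recurrence has no restart/source term, so without
  clamping the unique fixed point is identically zero. Pinning seeds at
  1.0 (a personalized-PageRank reading of "initially assign 1.0 to the
  question's entities") is the only reading that produces a useful
  ranking; it is what `weighted_path_rank()` implements.
- **Normalization by** $\sum |w|$. With mixed-sign out-edges a plain sum
  can be zero or negative; magnitudes in the denominator keep it
  positive while signs stay in the numerator. The two coincide on
  all-positive graphs.
- **Synchronous sweeps** replace random single-entity updates: the fixed
  point is the same, the run is reproducible.
- **Convergence.** Total L1 change below `threshold` (default 1e-6),
  cap `max_iter = 100`. The damped coefficient matrix has spectral
  radius at most (1−α)·α = 0.1275 at α = 0.85, so convergence is
  geometric and typically takes well under ten sweeps; tests verify the
  bound ⌈ln t / ln((1−α)α)⌉ + 1 on positive graphs, and verify the
  iterate against a direct linear solve of the clamped system
  (I − M)x = M·1 on random mixed-sign graphs up to 50 nodes.
- **Direction.** The default is directed traversal along stored edges —
  this is what the chain fixture's closed form (score 0.1275 one hop
  from a seed, 0.01625625 two hops) assumes. The answering pipeline
  calls `weighted_path_rank(..., symmetrize = TRUE)`, making every edge
  traversable both ways at its weight: symptom seeds must reach the
  disease nodes that point at them, which directed disease→symptom
  storage alone cannot do. The dual convention is deliberate: typed
  directed storage for semantics and serialization, symmetric traversal
  for diagnosis.

Candidates are then restricted to the question's target concept (seeds
excluded), ranked by score with ties broken by entity id, and the top
entity fills the answer template. The other seven categories route to
`property_lookup()`: a stored property first, typed out-neighbors as
fallback. Drug recommendation uses the same ranking toward the `drug`
concept; taboo edges *down-rank* a contraindicated drug (strictly, by
the sign-carrying numerator) rather than hard-excluding it — exclusion
can be layered on by filtering negative-scored candidates, but
down-ranking preserves an answer when every candidate carries some
contraindication.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.85 | damping per hop (dimensionless, (0,1)); higher spreads more score to distant entities |
| `threshold` | 1e-6 | L1 convergence tolerance on scores |
| `max_iter` | 100 | sweep cap (far above the geometric bound ≈ 8 at defaults) |
| `weight_config()` | 1.0 / 0.5 / 1.0 / −1.0 | relation-type weights (see above) |
| `variant` | `"literal"` | IG form; `"joint"` for the independence-correct variant |
| `smoothing` | 0 | add-one pseudo-count on feature presence |
| `match_concept_names` | `TRUE` | bare concept labels kept as literal intent words |

## The synthetic generator

Real instruction corpora of this kind are proprietary, so
`generate_corpus()`/`generate_questions()` emulate one with ground truth
known by construction: `n_diseases = 12` diseases with
`symptoms_per_disease = 4` main symptoms each, a `complication_fraction
= 0.5` share of complications, `n_drugs = 12` drugs with indication
links and (for `taboo_fraction = 0.5` of them, at least one always) a
taboo population, and `questions_per_category = 12` English questions
per category phrased from small template pools — sizes chosen so the
nine-category training set (108 questions over a ~100-node graph) is
comfortably larger than the vocabulary it must separate while the whole
suite builds in seconds. `symptom_overlap` moves diseases from fully
disjoint symptom sets (0, diagnosis unambiguous: the true disease is
the unique entity adjacent to all seeds, so top-1 accuracy is forced to
100%) to one shared pool (1, maximally confusable). Generation is fully
determined by `seed`.

Each category's phrasings share a distinguishing keyword ("disease",
"symptoms", "treatment", "diet", "cause", "recommend", "taboo",
"indication", "prevent"), and entity names include multi-word symptoms
so the generator exercises stop-word removal and longest-match
extraction. What the generator does *not* emulate: colloquial or
misspelled phrasing, category imbalance (real question logs are heavily
skewed), multi-intent questions, noisy or contradictory instruction
text, and non-English tokenization. Perfect scores on the synthetic
corpus therefore certify the machinery — extraction, generalization,
training, ranking, routing — not performance on real user questions.

## Degenerate inputs and conventions

- Empty entity names, unknown concepts, self-loops, zero weights, and
  sign/polarity conflicts are rejected at insertion.
- Statistics of graphs with N ≤ 1 are defined as 0.
- An unknown feature contributes IG 0; 0·ln 0 ≔ 0.
- `select_candidates()` signals an explicit no-answer condition when no
  entity of the target concept scores positively; `property_lookup()`
  signals unknown when neither property nor typed neighbors exist;
  ungroundable questions (no matched entity) are an error distinct from
  the unsupported-intent refusal.
- Serialization (`kg_write`/`kg_read`, `write_ig_model`) uses 17
  significant digits, so round-trips are bit-exact and repeated CLI runs
  are byte-identical.

## Known limitations

Single-intent questions only; one answer per run. The rule engine trades
recall for precision and will miss paraphrases its anchors do not cover.
The literal IG variant inflates scores of common function words in small
corpora (the joint variant or smoothing mitigates this). Lookup answers
are only as complete as the stored properties. Graph validation —
detecting wrong or inconsistent edges — is out of scope.
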