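# Keyword matching, context exclusions, age filter, sentence extraction.

lex <- build_lexicon(list(misspellings = list(marijuana = "marijuahana")))

test_that("keyword hits are whole-token, case-insensitive, longest-wins", {
  h <- find_keyword_hits("Pt admits to smoking marijuana daily", lex)
  expect_equal(nrow(h), 1L)
  expect_equal(h$canonical_seed, "marijuana")
  expect_equal(substr("Pt admits to smoking marijuana daily",
                      h$start, h$end), "marijuana")

  expect_equal(nrow(find_keyword_hits("The seaweed salad was fresh", lex)), 0L)
  expect_equal(nrow(find_keyword_hits("no relevant history", lex)), 0L)

  h2 <- find_keyword_hits("MJ: + and RX: DRONABINOL (MARINOL(2.5MG/TAB", lex)
  expect_setequal(h2$matched_term, c("mj", "dronabinol", "marinol"))

  # misspelling maps to its canonical seed
  h3 <- find_keyword_hits("smokes MARIJUAHANA sometimes", lex)
  expect_equal(h3$matched_term, "marijuahana")
  expect_equal(h3$canonical_seed, "marijuana")
})

test_that("mj requires uppercase or template-field context", {
  expect_equal(nrow(find_keyword_hits("patient initials mj noted", lex)), 0L)
  expect_equal(nrow(find_keyword_hits("mj: +", lex)), 1L)
  expect_equal(nrow(find_keyword_hits("Uses MJ on weekends", lex)), 1L)
})

test_that("context exclusions fire only for ambiguous-seed-only notes", {
  note_bile <- list(note_id = "n1",
                    text = "CBD dilated to 9mm, gallbladder wall thickened")
  d1 <- apply_context_exclusions(note_bile,
                                 find_keyword_hits(note_bile$text, lex), lex)
  expect_equal(d1$status, "excluded_bile_duct")

  note_all <- list(note_id = "n2",
                   text = "allergy panel positive for ragweed and weed pollen")
  d2 <- apply_context_exclusions(note_all,
                                 find_keyword_hits(note_all$text, lex), lex)
  expect_equal(d2$status, "excluded_allergy")

  note_mixed <- list(note_id = "n3",
                     text = "CBD noted; also smokes marijuana; gallbladder normal")
  d3 <- apply_context_exclusions(note_mixed,
                                 find_keyword_hits(note_mixed$text, lex), lex)
  expect_equal(d3$status, "screened_in")

  note_none <- list(note_id = "n4", text = "ankle sprain, RICE advised")
  d4 <- apply_context_exclusions(note_none,
                                 find_keyword_hits(note_none$text, lex), lex)
  expect_equal(d4$status, "no_mention")
})

test_that("age filter keeps age >= 7 at note date, boundary inclusive", {
  expect_false(passes_age_filter("2010-01-01", "2016-12-31"))
  expect_true(passes_age_filter("2010-01-01", "2017-01-01"))
  expect_error(passes_age_filter("2018-01-01", "2017-01-01"),
               "birth date after note date")
})

test_that("sentence extraction returns exactly the keyword-bearing sentences", {
  note <- list(note_id = "n1", text = paste(
    "Ankle films negative.",
    "Patient admits to smoking marijuana weekly.",
    "Follow up in 2 weeks."))
  s <- extract_cannabis_sentences(note, lex)
  expect_equal(nrow(s), 1L)
  expect_equal(s$sentence_index, 1L)
  # hits re-based to sentence offsets
  h <- s$hits[[1]]
  expect_equal(substr(s$sentence_text, h$start, h$end), "marijuana")

  note2 <- list(note_id = "n2", text = paste(
    'Denies drugs or alcohol; states used marijuana "one year ago".',
    "Urine tox screen: positive for amphetamines and cannabis."))
  expect_equal(nrow(extract_cannabis_sentences(note2, lex)), 2L)

  note3 <- list(note_id = "n3", text = "Uses cannabis. Smokes marijuana.")
  expect_equal(nrow(extract_cannabis_sentences(note3, lex)), 2L)

  dec <- structure(list(note_id = "n1", status = "excluded_allergy",
                        hits = NULL), class = "screen_decision")
  expect_error(extract_cannabis_sentences(note, lex, dec), "status")
})

test_that("screen_notes partitions notes across mutually exclusive statuses", {
  notes <- make_notes(c(
    "Pt admits to smoking marijuana daily.",
    "CBD dilated to 9mm, gallbladder wall thickened.",
    "allergy testing positive for weed pollen.",
    "Routine fracture follow-up, cast removed.",
    "Exposed to maternal THC in utero."),
    patient_id = c("P1", "P1", "P1", "P1", "P2"))
  pats <- make_patients(c("P1", "P2"), birth_date = c("2000-01-01",
                                                      "2017-10-01"))
  sc <- screen_notes(notes, lex, pats)
  expect_equal(nrow(sc$decisions), nrow(notes))
  expect_equal(sort(sc$decisions$status),
               sort(c("screened_in", "excluded_bile_duct",
                      "excluded_allergy", "no_mention",
                      "excluded_underage")))
  # extraction output only for screened-in notes, hit counts conserved
  expect_true(all(sc$sentences$note_id %in%
                  sc$decisions$note_id[sc$decisions$status == "screened_in"]))
  n_hits_sent <- sum(vapply(sc$sentences$hits, nrow, 0L))
  n_hits_dec <- sum(sc$decisions$n_hits[sc$decisions$status == "screened_in"])
  expect_equal(n_hits_sent, n_hits_dec)
})

test_that("keyword histogram counts distinct notes per seed", {
  notes <- make_notes(c(
    "marijuana and more marijuana",
    "marijuana plus THC today",
    "nothing relevant"))
  sc <- screen_notes(notes, lex)
  h <- keyword_histogram(sc$decisions)
  expect_equal(h[["marijuana"]], 2L)
  expect_equal(h[["thc"]], 1L)
  empty <- keyword_histogram(sc$decisions[0, , drop = FALSE])
  expect_length(empty, 0L)
})

test_that("synthetic corpus: recall and filter soundness hold by construction", {
  sim <- generate_cohort(sim_config(n_patients = 150, seed = 303))
  base <- build_lexicon()
  lex2 <- add_misspellings(base,
                           expand_misspellings(corpus_vocabulary(sim$notes$text),
                                               base))
  sc <- screen_notes(sim$notes, lex2, sim$patients)
  gc <- gold_confusion(sc$decisions, sim$gold, lex2)
  expect_equal(gc$screening_recall, 1.0)
  expect_equal(gc$filter_soundness, 1.0)
  expect_equal(gc$true_use_retention, 1.0)
  # decision statuses partition the notes
  expect_equal(sum(table(sc$decisions$status)), nrow(sim$notes))
})
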