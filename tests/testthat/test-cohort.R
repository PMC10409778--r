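# Patient aggregation, trends, diagnostic-code cross-check.

lex <- build_lexicon()

test_that("patient status aggregates any-positive with first-positive date", {
  notes <- make_notes(c("Patient denies marijuana use today.",
                        "Pt admits to smoking marijuana daily.",
                        "CBD dilated, gallbladder wall thickened.",
                        "Nothing of note."),
                      patient_id = c("P1", "P1", "P2", "P3"),
                      date = c("2015-02-01", "2016-09-01", "2015-01-01",
                               "2015-01-01"))
  pats <- make_patients(c("P1", "P2", "P3"), birth_date = "2000-01-01")
  sc <- screen_notes(notes, lex, pats)
  labs <- label_sentences(sc$sentences, lex)
  st <- aggregate_patient_status(notes, sc$decisions, labs, pats)

  expect_equal(st$status[st$patient_id == "P1"], "positive")
  expect_equal(st$first_positive_date[st$patient_id == "P1"],
               as.Date("2016-09-01"))
  expect_equal(st$age_at_first_positive[st$patient_id == "P1"],
               as.numeric(as.Date("2016-09-01") - as.Date("2000-01-01")) /
                 365.25)
  # excluded-context-only note leaves the patient undocumented
  expect_equal(st$status[st$patient_id == "P2"], "undocumented")
  expect_equal(st$status[st$patient_id == "P3"], "undocumented")
  # statuses partition the patients
  expect_equal(nrow(st), 3L)
  expect_true(all(st$status %in% c("positive", "negative_documented",
                                   "undocumented")))

  bad <- labs; bad$note_id <- "NOPE"
  expect_error(aggregate_patient_status(notes, sc$decisions, bad, pats),
               "unknown notes")
})

test_that("trend table computes per-year percentages and first-year counting", {
  texts <- c("Pt admits to smoking marijuana daily.",
             "Patient denies marijuana use.",
             rep("Routine cast check.", 8))
  notes <- make_notes(texts, patient_id = sprintf("P%d", 1:10),
                      date = "2015-06-01")
  pats <- make_patients(sprintf("P%d", 1:10), birth_date = "2000-01-01")
  sc <- screen_notes(notes, lex, pats)
  labs <- label_sentences(sc$sentences, lex)
  st <- aggregate_patient_status(notes, sc$decisions, labs, pats)
  tr <- trend_table(notes, sc$decisions, labs, pats, st)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$pct_documented_all_notes, 20)
  expect_equal(tr$pct_positive_all_notes, 10)
  expect_equal(tr$n_new_positive_patients, 1L)

  # positive in 2015 and 2018 counts as new only in 2015
  notes2 <- make_notes(c("Pt admits to smoking marijuana daily.",
                         "Uses cannabis still.",
                         "Routine visit."),
                       patient_id = c("P1", "P1", "P2"),
                       date = c("2015-06-01", "2018-06-01", "2018-07-01"))
  pats2 <- make_patients(c("P1", "P2"), birth_date = "2000-01-01")
  sc2 <- screen_notes(notes2, lex, pats2)
  labs2 <- label_sentences(sc2$sentences, lex)
  st2 <- aggregate_patient_status(notes2, sc2$decisions, labs2, pats2)
  tr2 <- trend_table(notes2, sc2$decisions, labs2, pats2, st2)
  expect_equal(tr2$n_new_positive_patients[tr2$year == 2015], 1L)
  expect_equal(tr2$n_new_positive_patients[tr2$year == 2018], 0L)
  # sum over years equals number of positive patients
  expect_equal(sum(tr2$n_new_positive_patients),
               sum(st2$status == "positive"))

  # OSM percentages use OSM denominators only
  notes3 <- make_notes(c("Pt admits to smoking marijuana daily.",
                         "Routine visit.", "Routine visit.",
                         "Routine visit."),
                       patient_id = sprintf("P%d", 1:4), date = "2015-06-01")
  notes3$is_osm <- c(TRUE, TRUE, FALSE, FALSE)
  sc3 <- screen_notes(notes3, lex)
  labs3 <- label_sentences(sc3$sentences, lex)
  st3 <- aggregate_patient_status(notes3, sc3$decisions, labs3,
                                  make_patients(sprintf("P%d", 1:4)))
  tr3 <- trend_table(notes3, sc3$decisions, labs3,
                     make_patients(sprintf("P%d", 1:4)), st3)
  expect_equal(tr3$pct_documented_osm, 50)
  expect_equal(tr3$pct_documented_all_notes, 25)
})

test_that("diagnosis matching follows the ICD dot hierarchy, SNOMED exact", {
  mk <- function(code, vocab) data.frame(patient_id = "P1", code = code,
                                         vocabulary = vocab,
                                         date = as.Date("2018-01-01"),
                                         stringsAsFactors = FALSE)
  expect_equal(match_diagnosis_codes(mk("F12.20", "ICD-10-CM")), "P1")
  expect_equal(match_diagnosis_codes(mk("F12", "ICD-10-CM")), "P1")
  expect_equal(match_diagnosis_codes(mk("T40.7X1A", "ICD-10-CM")), "P1")
  expect_equal(match_diagnosis_codes(mk("305.2", "ICD-9-CM")), "P1")
  expect_equal(match_diagnosis_codes(mk("305.20", "ICD-9-CM")), "P1")
  expect_length(match_diagnosis_codes(mk("305.1", "ICD-9-CM")), 0L)
  expect_length(match_diagnosis_codes(mk("F11.20", "ICD-10-CM")), 0L)
  expect_equal(match_diagnosis_codes(mk("7344009", "SNOMED-CT")), "P1")
  expect_length(match_diagnosis_codes(mk("7344009123", "SNOMED-CT")), 0L)
  expect_error(match_diagnosis_codes(mk("F12", "READ")), "unknown vocabulary")
})

test_that("ICD prefix matching equals a string-normalization oracle on fuzz codes", {
  set.seed(21)
  cb <- default_codebook()
  codes <- c(
    paste0("F12.", sprintf("%02d", sample(0:99, 30, TRUE))),
    paste0("F", sample(10:19, 20, TRUE), ".",
           sprintf("%02d", sample(0:99, 20, TRUE))),
    paste0("T40.", sample(0:9, 20, TRUE), "X", sample(1:4, 20, TRUE), "A"),
    paste0(sample(300:310, 30, TRUE), ".", sample(0:9, 30, TRUE)))
  codes <- codes[seq_len(100)]
  vocab <- c(rep("ICD-10-CM", 70), rep("ICD-9-CM", 30))
  for (i in seq_along(codes)) {
    rec <- data.frame(patient_id = "P1", code = codes[i],
                      vocabulary = vocab[i], date = as.Date("2018-01-01"),
                      stringsAsFactors = FALSE)
    prefixes <- if (vocab[i] == "ICD-10-CM") cb$icd10_prefixes else
      cb$icd9_prefixes
    expect_equal(length(match_diagnosis_codes(rec)) == 1L,
                 oracle_icd_match(codes[i], prefixes),
                 label = paste(vocab[i], codes[i]))
  }
})

test_that("crosscheck fraction reproduces printed-count arithmetic", {
  got <- crosscheck_fraction(as.character(seq_len(13556)),
                             as.character(seq_len(1971)))
  expect_equal(got$overlap, 1971L)
  expect_equal(got$percent, 14.5)
  expect_equal(crosscheck_fraction(c("a", "b"), c("a", "b"))$percent, 100.0)
  expect_equal(crosscheck_fraction(c("a", "b"), c("c"))$percent, 0.0)
  expect_error(crosscheck_fraction(character(0), "a"), "undefined")
})

test_that("procedure distributions sum to 100 and recover equal planted mixes", {
  st <- data.frame(patient_id = sprintf("P%04d", 1:1000),
                   status = rep(c("positive", "undocumented"), 500),
                   stringsAsFactors = FALSE)
  set.seed(31)
  groups <- c("cast_splint", "fracture_repair", "arthroscopy", "injection")
  probs <- c(0.5, 0.25, 0.15, 0.1)
  procs <- data.frame(
    patient_id = sample(st$patient_id, 5000, TRUE),
    group = sample(groups, 5000, TRUE, probs),
    stringsAsFactors = FALSE)
  dist <- procedure_group_distribution(procs, st)
  expect_equal(sum(dist$pct_positive), 100)
  expect_equal(sum(dist$pct_negative), 100)
  expect_lt(max(abs(dist$pct_positive - dist$pct_negative)), 3)

  one <- procedure_group_distribution(
    data.frame(patient_id = "P0001", group = "cast_splint"), st)
  expect_equal(one$pct_positive, 100)
})
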