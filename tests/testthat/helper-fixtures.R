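# Shared fixtures and independent oracles.

# The eight published example sentences (four positive, four negative use).
example_sentences <- function() {
  data.frame(
    sentence_text = c(
      "Pt admits to smoking marijuana daily",
      "MJ: +",
      paste("agreed to try marinol with relief, continued scopolamine patch",
            "and all other antiemetics changed to prn. Be aware you may be",
            "light-headed or dizzy while using marinol"),
      "RX: DRONABINOL (MARINOL(2.5MG/TAB",
      paste("He has not tried any other drugs and denies any use of",
            "marijuana, cocaine, heroine, or other drug abuse."),
      paste("Labs. Urine tox sent, negative for amphetamines, barbiturates,",
            "benzos, cannabis, cocaine, opiates, PCP"),
      paste("I discussed the interactions of stimulant medications with",
            "alcohol, which increases the concentration of the stimulant,",
            "and marijuana, which increases the heart rate with the use of",
            "stimulant medication."),
      paste("CRAFFT score is 1; he has been in the car when his brother has",
            "been smoking marijuana and driving, but his brothers will not",
            "allow him to do this.")),
    label = rep(c("positive", "negative"), each = 4L),
    stringsAsFactors = FALSE)
}

# Household-exposure phrasings typical of notes for patients under 7.
underage_sentences <- function() {
  c(paste("Other tobacco history: Mother smoked but has quit, also use of",
          "MJ during pregnancy but has quit as well."),
    "Birth Hx: Exposed to maternal THC in utero.",
    paste("Pregnancy is complicated by late care, inconsistent prenatal",
          "care, marijuana use, and viral illness 5 days prior to delivery."),
    paste("He lives with his mother and occasionally with his grandmother",
          "in the housing projects where she says he is exposed to",
          "cigarette and marijuana smoke in the hallways."))
}

# note table wrapper for a vector of texts
make_notes <- function(texts, patient_id = "P1", date = "2018-06-01",
                       is_osm = FALSE) {
  data.frame(note_id = sprintf("N%03d", seq_along(texts)),
             patient_id = patient_id, date = as.Date(date),
             is_osm = is_osm, text = texts, stringsAsFactors = FALSE)
}

make_patients <- function(ids, sex = "male", race = "white",
                          birth_date = "2000-01-01", svi = 0.3) {
  data.frame(patient_id = ids, sex = sex, race = race,
             birth_date = as.Date(birth_date), svi = svi,
             stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# brute-force cosine over explicitly enumerated substrings
oracle_cosine <- function(tok_a, tok_b, n_min = 1L, n_max = 3L) {
  enum <- function(tok) {
    tok <- gsub("[^a-z]", "", tolower(tok))
    out <- character(0)
    for (n in n_min:n_max) {
      if (nchar(tok) < n) next
      for (i in seq_len(nchar(tok) - n + 1L)) {
        out <- c(out, substr(tok, i, i + n - 1L))
      }
    }
    out
  }
  a <- table(enum(tok_a)); b <- table(enum(tok_b))
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), as.numeric(a[keys]), 0)
  bv <- ifelse(keys %in% names(b), as.numeric(b[keys]), 0)
  if (sum(av * bv) == 0) return(0)
  sum(av * bv) / sqrt(sum(av^2) * sum(bv^2))
}

# brute-force confusion-matrix metrics
oracle_metrics <- function(pred_labels, gold_labels) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(gold_labels)) {
    if (pred_labels[i] == "positive" && gold_labels[i] == "positive") tp <- tp + 1L
    if (pred_labels[i] == "positive" && gold_labels[i] == "negative") fp <- fp + 1L
    if (pred_labels[i] == "negative" && gold_labels[i] == "negative") tn <- tn + 1L
    if (pred_labels[i] == "negative" && gold_labels[i] == "positive") fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(gold_labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# string-normalization oracle for ICD prefix matching
oracle_icd_match <- function(code, prefixes) {
  strip <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))
  any(vapply(prefixes, function(p) {
    cs <- strip(code); ps <- strip(p)
    nchar(cs) >= nchar(ps) && substr(cs, 1, nchar(ps)) == ps
  }, TRUE))
}
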