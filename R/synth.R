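# Synthetic note-corpus generator with planted ground truth.
#
# Emulates the statistical structure the pipeline assumes: heterogeneous
# note templates for positive/negative phrasings, household-exposure notes,
# bile-duct and allergy confounders using the ambiguous terms, injected
# misspellings, demographic covariates with planted documentation/positivity
# odds, and yearly volume/documentation steps at legalization-style cutover
# years. No real patient text is used anywhere.

# orthopedic-flavored filler sentences; deliberately free of cannabis terms
# and of every context-exclusion keyword
.filler_bank <- c(
  "Patient presents with left distal radius fracture after a fall.",
  "Cast applied today; follow up in 3 weeks for repeat films.",
  "Right knee exam shows mild effusion with full range of motion.",
  "X-ray of the ankle shows no acute fracture or dislocation.",
  "Recommended rest, ice, compression, and elevation.",
  "Physical therapy referral placed for quadriceps strengthening.",
  "Splint removed; healing callus visible on imaging.",
  "Patient reports pain improved since the last visit.",
  "Cleared to return to sports in 4 weeks pending recheck.",
  "Post-op incision clean, dry, and intact with no erythema."
)

.templates <- list(
  affirmation = c(
    "Pt admits to smoking {TERM} daily.",
    "Patient reports using {TERM} on weekends.",
    "He states used {TERM} about a year ago.",
    "Patient endorses smoking {TERM} socially with friends.",
    "She admits to using {TERM} most evenings."
  ),
  denial = c(
    "Denies any use of {TERM}, cocaine, heroine, or other drugs.",
    "Patient denies {TERM} use at this time.",
    "He has never used {TERM} or other substances.",
    "She denied smoking {TERM} when asked directly."
  ),
  tox_positive = c(
    "Urine tox screen: positive for amphetamines and {TERM}.",
    "Tox screen positive for {TERM} on admission labs.",
    "Urine drug screen returned positive for {TERM}."
  ),
  tox_negative = c(
    "Urine tox sent, negative for amphetamines, barbiturates, benzos, {TERM}, cocaine.",
    "Tox screen negative for {TERM} and opiates.",
    "Urine drug screen negative for {TERM}."
  ),
  rx_medical = c(
    "RX: DRONABINOL (MARINOL(2.5MG/TAB",
    "Agreed to try marinol with relief, continued all other antiemetics prn.",
    "Prescribed epidiolex for refractory seizures, tolerating well.",
    "RX: CESAMET 1MG CAP, take as directed for nausea."
  ),
  counseling = c(
    "I discussed the risks of {TERM} use and its interactions with stimulant medication.",
    "Counseled regarding {TERM} and alcohol ahead of surgery.",
    "Provided education about {TERM} and driving safety."
  ),
  family_use = c(
    "He has been in the car when his brother has been smoking {TERM}.",
    "Mother reports {TERM} use in the household but not by the patient.",
    "Exposed to maternal {TERM} in utero per birth history.",
    "Pregnancy was complicated by {TERM} use and late prenatal care."
  ),
  bile_duct_confounder = c(
    "CBD dilated to 9 mm, gallbladder wall thickened on abdominal ultrasound.",
    "Abdominal imaging: CBD measures 4 mm, pancreas unremarkable.",
    "Ultrasound shows CBD within normal limits, no gallbladder stones."
  ),
  allergy_confounder = c(
    "Allergy panel positive for tree pollen and weed pollen.",
    "Skin testing notable for weed and grass allergens.",
    "Seasonal allergies triggered by weed pollen in late summer."
  )
)

.positive_templates <- c("affirmation", "tox_positive", "rx_medical")
.negative_templates <- c("denial", "tox_negative", "counseling", "family_use")

# term pools substituted into {TERM}
.use_terms <- c("marijuana", "cannabis", "thc", "weed")
.family_terms <- c("marijuana", "thc")

#' Simulation configuration for the synthetic corpus
#'
#' Defaults encode the study conditions the generator emulates: a pediatric
#' and young-adult orthopedic population with the documentation and
#' positive-use odds structure, class balance (73% positive among documented
#' notes), yearly volume growth with documentation step increases at the 2012
#' and 2016 cutover years, and a 14.5%-style diagnostic-code rate among
#' positive patients.
#'
#' @param n_patients Number of patients (default 1000).
#' @param years Integer vector `c(start, end)` (default 2000-2021).
#' @param notes_per_patient Poisson mean of notes per patient (default 6,
#'   minimum one note each).
#' @param sex_probs,race_probs Named sampling probabilities.
#' @param svi_beta Beta-distribution shape parameters for SVI (default
#'   `c(0.63, 1.69)`, mean 0.27).
#' @param svi_missing_rate Fraction of patients with missing SVI (default
#'   0.02).
#' @param doc_intercept Baseline log-odds that a note documents cannabis
#'   (default `qlogis(0.02)`).
#' @param doc_log_or Named planted log odds ratios for documentation:
#'   `sex_female`, `race_asian`, `race_black`, `race_hispanic`, `race_other`,
#'   `svi_per_0.01` (per 0.01 SVI).
#' @param year_steps Named numeric: additive log-odds step applied to all
#'   years >= the cutover year (default `c("2012" = log(2), "2016" =
#'   log(1.5))`).
#' @param pos_intercept Log-odds that a documented note is positive (default
#'   `qlogis(0.73)`).
#' @param pos_log_or Planted log odds ratios for positivity (same names as
#'   `doc_log_or`).
#' @param template_weights_positive,template_weights_negative Named sampling
#'   weights over positive / negative templates.
#' @param confounder_rates Named fractions of undocumented notes rendered as
#'   `c(bile_duct=, allergy=)` confounders.
#' @param misspelling_rate Probability that a substituted term is injected
#'   with one random spelling edit (default 0.05; only terms of >= 4
#'   characters are edited).
#' @param label_noise Probability of flipping a gold sentence label in
#'   [generate_labeled_sentences()] (default 0).
#' @param dx_code_rate Fraction of positive patients who also receive a
#'   cannabis diagnostic code (default 0.145).
#' @param osm_frac Fraction of notes flagged as orthopedic/sports-medicine
#'   (default 0.5; the synthetic clinic mixes OSM and non-OSM notes).
#' @param volume_growth Yearly multiplicative note-volume growth (default
#'   1.05).
#' @param birth_years Range of patient birth years (default 1985-2014).
#' @param seed Integer RNG seed (default 1).
#' @return List of class `sim_config` (validated).
#' @export
sim_config <- function(n_patients = 1000L,
                       years = c(2000L, 2021L),
                       notes_per_patient = 6,
                       sex_probs = c(female = 0.526, male = 0.473,
                                     unknown = 0.001),
                       race_probs = c(asian = 0.022, black = 0.048,
                                      hispanic = 0.067, other = 0.048,
                                      white = 0.561, unavailable = 0.254),
                       svi_beta = c(0.63, 1.69),
                       svi_missing_rate = 0.02,
                       doc_intercept = stats::qlogis(0.02),
                       doc_log_or = c(sex_female = log(1.074),
                                      race_asian = log(0.829),
                                      race_black = log(3.400),
                                      race_hispanic = log(2.245),
                                      race_other = log(1.164),
                                      svi_per_0.01 = log(1.001)),
                       year_steps = c("2012" = log(2), "2016" = log(1.5)),
                       pos_intercept = stats::qlogis(0.73),
                       pos_log_or = c(sex_female = log(0.957),
                                      race_asian = log(0.651),
                                      race_black = log(3.222),
                                      race_hispanic = log(2.131),
                                      race_other = log(1.007),
                                      svi_per_0.01 = log(1.002)),
                       template_weights_positive =
                         c(affirmation = 0.55, tox_positive = 0.25,
                           rx_medical = 0.20),
                       template_weights_negative =
                         c(denial = 0.55, tox_negative = 0.20,
                           counseling = 0.15, family_use = 0.10),
                       confounder_rates = c(bile_duct = 0.02, allergy = 0.02),
                       misspelling_rate = 0.05,
                       label_noise = 0,
                       dx_code_rate = 0.145,
                       osm_frac = 0.5,
                       volume_growth = 1.05,
                       birth_years = c(1985L, 2014L),
                       seed = 1L) {
  cfg <- mget(names(formals()))
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$n_patients >= 1, "n_patients must be >= 1")
  chk(length(cfg$years) == 2 && cfg$years[1] <= cfg$years[2],
      "years must be c(start, end) with start <= end")
  chk(abs(sum(cfg$sex_probs) - 1) < 1e-6, "sex_probs must sum to 1")
  chk(abs(sum(cfg$race_probs) - 1) < 1e-6, "race_probs must sum to 1")
  chk(all(cfg$svi_beta > 0), "svi_beta shapes must be positive")
  chk(cfg$misspelling_rate >= 0 && cfg$misspelling_rate <= 1,
      "misspelling_rate must lie in [0,1]")
  chk(cfg$label_noise >= 0 && cfg$label_noise <= 1,
      "label_noise must lie in [0,1]")
  chk(cfg$dx_code_rate >= 0 && cfg$dx_code_rate <= 1,
      "dx_code_rate must lie in [0,1]")
  chk(all(cfg$confounder_rates >= 0) && sum(cfg$confounder_rates) <= 1,
      "confounder_rates must be non-negative and sum to <= 1")
  chk(abs(sum(cfg$template_weights_positive) - 1) < 1e-6,
      "template_weights_positive must sum to 1")
  chk(abs(sum(cfg$template_weights_negative) - 1) < 1e-6,
      "template_weights_negative must sum to 1")
  if (length(problems)) {
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "sim_config")
}

#' Inject one random spelling edit into a term
#'
#' With probability `rate`, applies one edit chosen uniformly among character
#' duplication, adjacent transposition, and vowel(+h) insertion (e.g.
#' marijuana -> marijuahana). Terms shorter than 4 characters are returned
#' unchanged.
#'
#' @param term Character scalar.
#' @param rate Edit probability in \[0,1\].
#' @param seed Optional seed; when `NULL` uses the current RNG stream.
#' @return The (possibly edited) term.
#' @export
inject_misspellings <- function(term, rate, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  if (nchar(term) < 4L || stats::runif(1) >= rate) return(term)
  n <- nchar(term)
  ch <- strsplit(term, "")[[1]]
  # short tokens only get duplications: transpositions/insertions on a
  # 4-5 letter word distort its n-gram profile beyond what a plausible
  # typo of a recognizable term looks like
  ops <- if (n >= 6L) c("duplicate", "transpose", "insert") else "duplicate"
  op <- if (length(ops) > 1L) sample(ops, 1L) else ops
  if (op == "duplicate") {
    i <- sample.int(n, 1L)
    paste0(paste(ch[seq_len(i)], collapse = ""),
           ch[i], paste(ch[seq_len(n) > i], collapse = ""))
  } else if (op == "transpose") {
    i <- sample.int(n - 1L, 1L)
    ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
    paste(ch, collapse = "")
  } else {
    i <- sample(seq(2L, n), 1L)    # never before the first character
    ins <- sample(c("a", "e", "i", "o", "u", "ha"), 1L)
    paste0(substr(term, 1L, i - 1L), ins, substr(term, i, n))
  }
}

# planted linear predictor for one patient at one note
.plant_eta <- function(intercept, log_or, sex, race, svi, year_off) {
  eta <- intercept + year_off
  if (sex == "female") eta <- eta + log_or[["sex_female"]]
  key <- paste0("race_", race)
  if (key %in% names(log_or)) eta <- eta + log_or[[key]]
  if (!is.na(svi)) eta <- eta + 100 * svi * log_or[["svi_per_0.01"]]
  eta
}

#' Generate a synthetic cohort: patients, notes, diagnoses, gold labels
#'
#' Draws patient covariates from the configured distributions; for each note,
#' documentation and (conditional) positivity from the planted logistic
#' models; renders each note as filler sentences plus, when documented, one
#' template sentence with a cannabis term (optionally misspelled). A
#' configurable fraction of undocumented notes become bile-duct or allergy
#' confounder notes. Positive patients receive a cannabis diagnostic code
#' with probability `dx_code_rate`. Everything is deterministic given
#' `config$seed`.
#'
#' @param config `sim_config` object.
#' @return List with data frames `patients`, `notes`, `diagnoses`, `gold`,
#'   plus attribute `year_expected` (per-year mean planted documentation and
#'   positivity probabilities over the generated notes).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_patients
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = sample(names(config$sex_probs), n, TRUE, config$sex_probs),
    race = sample(names(config$race_probs), n, TRUE, config$race_probs),
    birth_date = as.Date(sprintf(
      "%d-%02d-%02d",
      sample(seq(config$birth_years[1], config$birth_years[2]), n, TRUE),
      sample(12L, n, TRUE), sample(28L, n, TRUE))),
    svi = round(stats::rbeta(n, config$svi_beta[1], config$svi_beta[2]), 3),
    stringsAsFactors = FALSE)
  patients$svi[stats::runif(n) < config$svi_missing_rate] <- NA_real_

  yrs <- seq(config$years[1], config$years[2])
  year_w <- config$volume_growth^(yrs - yrs[1])
  year_off <- stats::setNames(rep(0, length(yrs)), yrs)
  for (cut in names(config$year_steps)) {
    year_off[yrs >= as.integer(cut)] <-
      year_off[yrs >= as.integer(cut)] + config$year_steps[[cut]]
  }

  notes <- list(); gold <- list()
  note_no <- 0L
  for (i in seq_len(n)) {
    k <- max(1L, stats::rpois(1L, config$notes_per_patient))
    birth_year <- as.integer(format(patients$birth_date[i], "%Y"))
    alive <- yrs >= birth_year
    if (!any(alive)) alive[length(alive)] <- TRUE
    note_years <- sample(yrs[alive], k, TRUE, prob = year_w[alive])
    for (y in note_years) {
      note_no <- note_no + 1L
      note_id <- sprintf("N%07d", note_no)
      date <- as.Date(sprintf("%d-%02d-%02d", y, sample(12L, 1L),
                              sample(28L, 1L)))
      if (date < patients$birth_date[i]) date <- patients$birth_date[i]
      svi_i <- patients$svi[i]
      eta_d <- .plant_eta(config$doc_intercept, config$doc_log_or,
                          patients$sex[i], patients$race[i],
                          svi_i, year_off[[as.character(y)]])
      p_doc <- stats::plogis(eta_d)
      documented <- stats::runif(1) < p_doc
      eta_p <- .plant_eta(config$pos_intercept, config$pos_log_or,
                          patients$sex[i], patients$race[i], svi_i, 0)
      p_pos <- stats::plogis(eta_p)

      injected_terms <- character(0)
      injected_mis <- character(0)
      if (documented) {
        positive <- stats::runif(1) < p_pos
        tmpl_class <- if (positive) {
          sample(names(config$template_weights_positive), 1L,
                 prob = config$template_weights_positive)
        } else {
          sample(names(config$template_weights_negative), 1L,
                 prob = config$template_weights_negative)
        }
        tmpl <- sample(.templates[[tmpl_class]], 1L)
        if (grepl("{TERM}", tmpl, fixed = TRUE)) {
          pool <- if (tmpl_class == "family_use") .family_terms else .use_terms
          term <- sample(pool, 1L)
          rendered <- inject_misspellings(term, config$misspelling_rate)
          if (rendered != term) injected_mis <- rendered
          injected_terms <- rendered
          tmpl <- sub("{TERM}", rendered, tmpl, fixed = TRUE)
        } else {
          # fixed-text templates carry their own terms (rx_medical, some
          # family_use); record the lexicon terms they contain
          injected_terms <- tolower(regmatches(
            tmpl, gregexpr(paste0(
              "(?i)\\b(marinol|dronabinol|epidiolex|cesamet|thc|cbd)\\b"),
              tmpl, perl = TRUE))[[1]])
        }
        status <- if (!positive) {
          if (tmpl_class == "family_use") "family_use_negative" else
            "documented_negative"
        } else if (tmpl_class == "rx_medical") "medical_rx_positive" else
          "documented_positive"
      } else {
        u <- stats::runif(1)
        cr <- config$confounder_rates
        if (u < cr[["bile_duct"]]) {
          tmpl <- sample(.templates$bile_duct_confounder, 1L)
          status <- "confounder_bile_duct"
          injected_terms <- "cbd"
        } else if (u < sum(cr)) {
          tmpl <- sample(.templates$allergy_confounder, 1L)
          status <- "confounder_allergy"
          injected_terms <- "weed"
        } else {
          tmpl <- NULL
          status <- "no_mention"
        }
      }
      filler <- sample(.filler_bank, sample(2:4, 1L))
      body <- if (is.null(tmpl)) filler else {
        pos_at <- sample(length(filler) + 1L, 1L)
        append(filler, tmpl, after = pos_at - 1L)
      }
      notes[[note_no]] <- data.frame(
        note_id = note_id, patient_id = patients$patient_id[i],
        date = date, is_osm = stats::runif(1) < config$osm_frac,
        text = paste(body, collapse = " "), stringsAsFactors = FALSE)
      g <- data.frame(note_id = note_id, true_status = status,
                      year = y, plant_p_doc = p_doc,
                      plant_p_pos_note = p_doc * p_pos,
                      stringsAsFactors = FALSE)
      g$injected_terms <- list(injected_terms)
      g$injected_misspellings <- list(injected_mis)
      gold[[note_no]] <- g
    }
  }
  notes <- do.call(rbind, notes)
  gold <- do.call(rbind, gold)

  # diagnosis codes: planted for a fraction of gold-positive patients
  pos_status <- c("documented_positive", "medical_rx_positive")
  pos_pat <- unique(notes$patient_id[gold$true_status %in% pos_status])
  dx_rows <- list()
  cannabis_codes <- data.frame(
    code = c("F12.20", "F12.10", "F12.90", "305.20", "304.30", "T40.7X1A",
             "7344009", "28823006"),
    vocabulary = c("ICD-10-CM", "ICD-10-CM", "ICD-10-CM", "ICD-9-CM",
                   "ICD-9-CM", "ICD-10-CM", "SNOMED-CT", "SNOMED-CT"),
    stringsAsFactors = FALSE)
  other_codes <- data.frame(
    code = c("S52.501A", "M25.561", "716.90", "195967001"),
    vocabulary = c("ICD-10-CM", "ICD-10-CM", "ICD-9-CM", "SNOMED-CT"),
    stringsAsFactors = FALSE)
  for (p in patients$patient_id) {
    picks <- other_codes[sample(nrow(other_codes), 1L), , drop = FALSE]
    if (p %in% pos_pat && stats::runif(1) < config$dx_code_rate) {
      picks <- rbind(picks,
                     cannabis_codes[sample(nrow(cannabis_codes), 1L), ,
                                    drop = FALSE])
    }
    picks$patient_id <- p
    picks$date <- as.Date(sprintf("%d-%02d-%02d",
                                  sample(yrs, nrow(picks), TRUE),
                                  sample(12L, nrow(picks), TRUE),
                                  sample(28L, nrow(picks), TRUE)))
    dx_rows[[length(dx_rows) + 1L]] <- picks
  }
  diagnoses <- do.call(rbind, dx_rows)
  diagnoses <- diagnoses[, c("patient_id", "code", "vocabulary", "date")]
  rownames(diagnoses) <- NULL

  yu <- sort(unique(gold$year))
  ye <- data.frame(
    year = yu,
    expected_pct_documented = 100 * vapply(
      yu, function(y) mean(gold$plant_p_doc[gold$year == y]), 0),
    expected_pct_positive = 100 * vapply(
      yu, function(y) mean(gold$plant_p_pos_note[gold$year == y]), 0),
    n_notes = as.integer(table(factor(gold$year, levels = yu))))
  out <- list(patients = patients, notes = notes, diagnoses = diagnoses,
              gold = gold)
  attr(out, "year_expected") <- ye
  out
}

#' Generate a labeled-sentence set for classifier training
#'
#' Samples template sentences with the configured positive fraction, assigns
#' one synthetic note id per sentence, and flips labels with probability
#' `noise` (planted annotation noise). Deterministic given `seed`.
#'
#' @param n Number of sentences.
#' @param positive_frac Fraction positive (default 0.73, the documented-note
#'   class balance).
#' @param noise Label-flip probability (default 0).
#' @param seed RNG seed.
#' @return Data frame: `note_id`, `sentence_text`, `label`.
#' @export
generate_labeled_sentences <- function(n, positive_frac = 0.73, noise = 0,
                                       seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    positive <- stats::runif(1) < positive_frac
    cls <- if (positive) sample(.positive_templates, 1L) else
      sample(.negative_templates, 1L)
    tmpl <- sample(.templates[[cls]], 1L)
    if (grepl("{TERM}", tmpl, fixed = TRUE)) {
      pool <- if (cls == "family_use") .family_terms else .use_terms
      tmpl <- sub("{TERM}", sample(pool, 1L), tmpl, fixed = TRUE)
    }
    label <- if (positive) "positive" else "negative"
    if (stats::runif(1) < noise) {
      label <- if (label == "positive") "negative" else "positive"
    }
    data.frame(note_id = sprintf("S%06d", i), sentence_text = tmpl,
               label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate patient-level outcomes for disparity parameter-recovery checks
#'
#' A patient-level shortcut past note rendering: draws covariates as in
#' [generate_cohort()] and a binary outcome directly from a logistic model
#' with the supplied planted log odds ratios, returning a status table
#' compatible with [build_design()].
#'
#' @param n Number of patients.
#' @param intercept Baseline log-odds.
#' @param log_or Named planted log ORs (`sex_female`, `race_*`,
#'   `svi_per_0.01`), any subset; omitted effects are 0.
#' @param seed RNG seed.
#' @return List with `patients` and `statuses` (outcome mapped to
#'   `positive` / `undocumented`).
#' @export
generate_disparity_cohort <- function(n, intercept = stats::qlogis(0.1),
                                      log_or = c(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  full <- c(sex_female = 0, race_asian = 0, race_black = 0,
            race_hispanic = 0, race_other = 0, svi_per_0.01 = 0)
  full[names(log_or)] <- log_or
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = sample(c("female", "male"), n, TRUE, c(0.5, 0.5)),
    race = sample(c("white", "asian", "black", "hispanic", "other"), n, TRUE,
                  c(0.6, 0.05, 0.1, 0.15, 0.1)),
    birth_date = as.Date("2000-06-15"),
    svi = round(stats::rbeta(n, 0.63, 1.69), 3),
    stringsAsFactors = FALSE)
  eta <- vapply(seq_len(n), function(i) {
    .plant_eta(intercept, full, patients$sex[i], patients$race[i],
               patients$svi[i], 0)
  }, 0)
  y <- stats::runif(n) < stats::plogis(eta)
  statuses <- data.frame(
    patient_id = patients$patient_id,
    status = ifelse(y, "positive", "undocumented"),
    first_positive_date = as.Date(ifelse(y, "2015-06-01", NA)),
    age_at_first_positive = ifelse(y, 15, NA_real_),
    stringsAsFactors = FALSE)
  list(patients = patients, statuses = statuses)
}

#' Stage-wise confusion tables of pipeline output against gold
#'
#' Compares screening decisions and patient statuses with the generator's
#' gold records: a screening table (gold status x decision status), plus
#' summary rates. Screening recall is computed over gold documented/confounder
#' notes whose injected terms are detectable by the supplied lexicon (an
#' injected misspelling the lexicon did not accept cannot be found by
#' construction and is reported separately).
#'
#' @param decisions Decision table from [screen_notes()].
#' @param gold Gold table from [generate_cohort()].
#' @param lexicon `cannabis_lexicon` used for screening.
#' @return List: `screening_table` (contingency table), `screening_recall`,
#'   `filter_soundness` (fraction of confounder notes excluded),
#'   `true_use_retention` (fraction of detectable true-use notes screened
#'   in), `n_undetectable` (documented notes whose only term was an
#'   unaccepted misspelling).
#' @export
gold_confusion <- function(decisions, gold, lexicon) {
  m <- merge(gold, decisions, by = "note_id")
  known <- lexicon_terms(lexicon)$term
  detectable <- vapply(seq_len(nrow(m)), function(i) {
    terms <- m$injected_terms[[i]]
    !length(terms) || any(tolower(terms) %in% known)
  }, TRUE)

  tab <- table(gold = m$true_status, decision = m$status)
  doc_status <- c("documented_positive", "documented_negative",
                  "medical_rx_positive", "family_use_negative")
  conf_status <- c("confounder_bile_duct", "confounder_allergy")

  doc <- m$true_status %in% doc_status
  mention <- m$true_status %in% c(doc_status, conf_status)
  recall <- mean(m$status[mention & detectable] != "no_mention")
  conf <- m$true_status %in% conf_status
  soundness <- if (any(conf)) {
    mean(m$status[conf] %in% c("excluded_bile_duct", "excluded_allergy"))
  } else NA_real_
  retention <- if (any(doc & detectable)) {
    mean(m$status[doc & detectable] %in% c("screened_in",
                                           "excluded_underage"))
  } else NA_real_
  list(screening_table = tab,
       screening_recall = recall,
       filter_soundness = soundness,
       true_use_retention = retention,
       n_undetectable = sum(doc & !detectable))
}
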