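# End-to-end pipeline driver and run manifest.

#' Run the full screening/classification/analytics pipeline
#'
#' Executes, in order: lexicon construction with corpus-driven misspelling
#' expansion, note screening (keyword match, context exclusions, age
#' filter), sentence-level use classification, patient-status aggregation,
#' yearly trend computation, diagnostic-code cross-check, and the two
#' disparity model settings. Any stage failure aborts with the stage name.
#'
#' @param notes,patients,diagnoses Input tables (as from [read_notes()],
#'   [read_patients()], [read_diagnoses()] or [generate_cohort()]).
#' @param lexicon_config Optional lexicon configuration for
#'   [build_lexicon()].
#' @param classifier `"rule"` (default, deterministic baseline) or a trained
#'   `use_classifier` used via [predict_scores()].
#' @param expand Expand misspellings from the corpus vocabulary before
#'   screening (default `TRUE`).
#' @param min_age_years Age filter cutoff (default 7).
#' @param seed Seed recorded in the manifest (the rule pipeline itself is
#'   deterministic).
#' @param out_dir Optional directory; when given, intermediates are persisted
#'   (`lexicon.json`, `decisions.jsonl`, `sentences.jsonl`, `status.csv`,
#'   `trend_table.csv`, `crosscheck.json`, `disparity.json`,
#'   `manifest.json`).
#' @return List of class `pipeline_result`: `lexicon`, `decisions`,
#'   `sentences` (labeled), `statuses`, `trend`, `crosscheck`,
#'   `disparity_documentation`, `disparity_positive_use`, `manifest`.
#' @export
run_pipeline <- function(notes, patients, diagnoses = NULL,
                         lexicon_config = NULL, classifier = "rule",
                         expand = TRUE, min_age_years = 7, seed = 1L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lexicon <- stage("build-lexicon", {
    lex <- build_lexicon(lexicon_config)
    if (expand) {
      vocab <- corpus_vocabulary(notes$text)
      lex <- add_misspellings(lex, expand_misspellings(vocab, lex))
    }
    lex
  })

  screened <- stage("screen", screen_notes(notes, lexicon, patients,
                                           min_age_years))
  decisions <- screened$decisions
  sentences <- stage("classify", {
    if (identical(classifier, "rule")) {
      label_sentences(screened$sentences, lexicon)
    } else if (inherits(classifier, "use_classifier")) {
      predict_scores(classifier, screened$sentences)
    } else stop("classifier must be \"rule\" or a use_classifier")
  })

  statuses <- stage("cohort", aggregate_patient_status(notes, decisions,
                                                       sentences, patients))
  trend <- stage("trend", trend_table(notes, decisions, sentences, patients,
                                      statuses))
  crosscheck <- stage("crosscheck", {
    if (is.null(diagnoses) || !nrow(statuses[statuses$status == "positive", ])) {
      NULL
    } else {
      crosscheck_fraction(
        statuses$patient_id[statuses$status == "positive"],
        match_diagnosis_codes(diagnoses))
    }
  })

  fit_setting <- function(setting) {
    tryCatch(
      fit_disparity_model(build_design(patients, statuses, setting)),
      error = function(e) NULL)
  }
  disp_doc <- stage("disparity", fit_setting("documentation"))
  disp_pos <- stage("disparity", fit_setting("positive_use"))

  tally <- as.list(table(decisions$status))
  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_notes_in = nrow(notes),
    n_patients_in = nrow(patients),
    n_diagnoses_in = if (is.null(diagnoses)) 0L else nrow(diagnoses),
    status_tally = tally,
    n_sentences = nrow(sentences),
    n_positive_patients = sum(statuses$status == "positive"),
    n_documented_patients = sum(statuses$status != "undocumented"),
    lexicon_n_misspellings = sum(lengths(lexicon$misspellings)))
  # conservation check: every note got exactly one decision status
  stopifnot(sum(unlist(tally)) == nrow(notes))

  result <- structure(
    list(lexicon = lexicon, decisions = decisions, sentences = sentences,
         statuses = statuses, trend = trend, crosscheck = crosscheck,
         disparity_documentation = disp_doc,
         disparity_positive_use = disp_pos, manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_lexicon(lexicon, file.path(out_dir, "lexicon.json"))
    write_jsonl(decisions[, c("note_id", "status", "n_hits")],
                file.path(out_dir, "decisions.jsonl"))
    write_jsonl(sentences[, setdiff(names(sentences), "hits")],
                file.path(out_dir, "sentences.jsonl"))
    utils::write.csv(statuses, file.path(out_dir, "status.csv"),
                     row.names = FALSE)
    utils::write.csv(trend[, setdiff(names(trend), "new_positive_by_race")],
                     file.path(out_dir, "trend_table.csv"),
                     row.names = FALSE)
    if (!is.null(crosscheck)) {
      jsonlite::write_json(crosscheck, file.path(out_dir, "crosscheck.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    disp <- list(documentation = disp_doc, positive_use = disp_pos)
    disp <- lapply(Filter(Negate(is.null), disp), function(d) {
      as.data.frame(d)[, c("covariate", "reference_level", "aOR", "ci_low",
                           "ci_high", "p_value")]
    })
    jsonlite::write_json(disp, file.path(out_dir, "disparity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n")
  cat("  notes in:           ", m$n_notes_in, "\n")
  for (s in names(m$status_tally)) {
    cat(sprintf("    %-20s %d\n", s, m$status_tally[[s]]))
  }
  cat("  keyword sentences:  ", m$n_sentences, "\n")
  cat("  documented patients:", m$n_documented_patients, "\n")
  cat("  positive patients:  ", m$n_positive_patients, "\n")
  invisible(x)
}
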