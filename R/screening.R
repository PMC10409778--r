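# Note screening: keyword hits, context exclusions, age filter,
# keyword-anchored sentence extraction.

#' Find cannabis-term hits in note text
#'
#' Case-insensitive whole-token matching of every lexicon term (seeds, medical
#' terms, accepted misspellings). Token boundaries mean "seaweed" never hits
#' "weed". Overlapping matches keep the longest term. The two-letter seed "mj"
#' is matched only when it appears as uppercase "MJ" in the source text or is
#' immediately followed by ":" (template field), which curbs false positives
#' from initials.
#'
#' @param text Character scalar.
#' @param lexicon `cannabis_lexicon`.
#' @return Data frame of hits: `matched_term` (normalized), `canonical_seed`,
#'   `start`, `end` (1-based inclusive offsets into `text`). Zero rows when
#'   nothing matches.
#' @examples
#' lex <- build_lexicon()
#' find_keyword_hits("Pt admits to smoking marijuana daily", lex)
#' @export
find_keyword_hits <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(lexicon, "cannabis_lexicon"))
  empty <- data.frame(matched_term = character(0),
                      canonical_seed = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  terms <- lexicon_terms(lexicon)    # already sorted longest-first
  taken <- logical(nchar(text))
  rows <- list()
  for (k in seq_len(nrow(terms))) {
    term <- terms$term[k]
    pat <- paste0("(?<![A-Za-z0-9])", term, "(?![A-Za-z0-9])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      s <- m[i]; e <- s + attr(m, "match.length")[i] - 1L
      if (any(taken[s:e])) next          # longer term already claimed span
      if (term == "mj") {
        raw <- substr(text, s, e)
        nxt <- substr(text, e + 1L, e + 1L)
        if (raw != "MJ" && nxt != ":") next
      }
      taken[s:e] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        matched_term = term, canonical_seed = terms$canonical_seed[k],
        start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# does any exclusion keyword occur in the note text (case-insensitive,
# token-boundary for single words, substring for multi-word phrases)?
.has_exclusion_keyword <- function(text, keywords) {
  low <- tolower(text)
  for (kw in keywords) {
    pat <- if (grepl(" ", kw)) kw else
      paste0("(?<![a-z0-9])", kw, "(?![a-z0-9])")
    if (grepl(pat, low, perl = TRUE)) return(TRUE)
  }
  FALSE
}

#' Screen one note: exclusion context around ambiguous seeds
#'
#' Produces the screening decision for a note whose keyword hits have been
#' computed. A note whose only hit seeds are ambiguous is excluded when the
#' matching confounder vocabulary co-occurs: CBD-only notes containing
#' bile-duct words (gallbladder, pancreas, ...) are `excluded_bile_duct`;
#' weed-only notes containing allergy words (pollen, allergy, ...) are
#' `excluded_allergy`. Any unambiguous seed (marijuana, thc, a medical term,
#' ...) makes the note `screened_in` regardless of context. Notes with no hits
#' are `no_mention`.
#'
#' @param note One-row note (list or data frame row) with at least `note_id`
#'   and `text`.
#' @param hits Data frame from [find_keyword_hits()] on `note$text`.
#' @param lexicon `cannabis_lexicon`.
#' @return List of class `screen_decision`: `note_id`, `status` (one of
#'   `no_mention`, `excluded_bile_duct`, `excluded_allergy`,
#'   `excluded_underage`, `screened_in`), `hits`.
#' @export
apply_context_exclusions <- function(note, hits, lexicon) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  seeds_hit <- unique(hits$canonical_seed)
  status <- if (nrow(hits) == 0L) {
    "no_mention"
  } else if (identical(seeds_hit, "cbd") &&
             .has_exclusion_keyword(note$text,
                                    lexicon$exclusion_sets$bile_duct)) {
    "excluded_bile_duct"
  } else if (identical(seeds_hit, "weed") &&
             .has_exclusion_keyword(note$text,
                                    lexicon$exclusion_sets$allergy)) {
    "excluded_allergy"
  } else {
    "screened_in"
  }
  structure(list(note_id = note$note_id, status = status, hits = hits),
            class = "screen_decision")
}

#' Patient age filter at note date
#'
#' Age is computed as (note date - birth date) / 365.25 years; a note passes
#' when age is at least `min_age_years` (boundary inclusive).
#'
#' @param birth_date,note_date `Date` scalars (or coercible strings).
#' @param min_age_years Minimum age, default 7.
#' @return Logical scalar.
#' @export
passes_age_filter <- function(birth_date, note_date, min_age_years = 7) {
  birth_date <- as.Date(birth_date); note_date <- as.Date(note_date)
  if (is.na(birth_date) || is.na(note_date)) stop("invalid date")
  if (birth_date > note_date) stop("birth date after note date")
  age <- as.numeric(note_date - birth_date) / 365.25
  age >= min_age_years
}

#' Extract keyword-anchored sentences from a screened-in note
#'
#' Splits the note into sentences and returns exactly those containing at
#' least one lexicon hit, in document order, with hits re-based to sentence
#' offsets. These sentences are the classifier's input unit.
#'
#' @param note One-row note with `note_id` and `text`.
#' @param lexicon `cannabis_lexicon`.
#' @param decision Optional `screen_decision` for the note; if supplied and
#'   the status is not `screened_in`, an error is raised (the contract is that
#'   excluded notes never reach sentence extraction).
#' @return Data frame with columns `note_id`, `sentence_index`,
#'   `sentence_text`, and a `hits` list-column of per-sentence hit frames.
#' @export
extract_cannabis_sentences <- function(note, lexicon, decision = NULL) {
  if (!is.null(decision) && decision$status != "screened_in") {
    stop("extract_cannabis_sentences called on a note with status ",
         decision$status)
  }
  sents <- split_sentences(note$text)
  hits <- if (is.null(decision)) find_keyword_hits(note$text, lexicon) else
    decision$hits
  out <- list()
  for (k in seq_len(nrow(sents))) {
    in_sent <- hits$start >= sents$start[k] & hits$end <= sents$end[k]
    if (!any(in_sent)) next
    h <- hits[in_sent, , drop = FALSE]
    h$start <- h$start - sents$start[k] + 1L
    h$end <- h$end - sents$start[k] + 1L
    row <- data.frame(note_id = note$note_id,
                      sentence_index = sents$sentence_index[k],
                      sentence_text = sents$sentence_text[k],
                      stringsAsFactors = FALSE)
    row$hits <- list(h)
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) {
    return(data.frame(note_id = character(0), sentence_index = integer(0),
                      sentence_text = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Screen a note table end to end
#'
#' Runs the staged screening pipeline over a note table: keyword matching,
#' context exclusion, age filter (when a patient table with birth dates is
#' supplied), then sentence extraction for screened-in notes. A note failing
#' an earlier stage never reaches later stages.
#'
#' @param notes Data frame with `note_id`, `patient_id`, `date`, `text`
#'   (and optionally `is_osm`).
#' @param lexicon `cannabis_lexicon`.
#' @param patients Optional data frame with `patient_id`, `birth_date`;
#'   enables the under-`min_age_years` exclusion.
#' @param min_age_years Age cutoff, default 7.
#' @return List with `decisions` (data frame: `note_id`, `status`, `n_hits`,
#'   `seeds_hit` list-column, `terms_hit` list-column) and `sentences`
#'   (row-bound [extract_cannabis_sentences()] output for screened-in notes).
#' @export
screen_notes <- function(notes, lexicon, patients = NULL, min_age_years = 7) {
  stopifnot(is.data.frame(notes), inherits(lexicon, "cannabis_lexicon"))
  birth <- NULL
  if (!is.null(patients)) {
    birth <- stats::setNames(as.Date(patients$birth_date), patients$patient_id)
  }
  dec_rows <- vector("list", nrow(notes))
  sent_rows <- list()
  for (i in seq_len(nrow(notes))) {
    note <- notes[i, , drop = FALSE]
    hits <- find_keyword_hits(note$text, lexicon)
    d <- apply_context_exclusions(note, hits, lexicon)
    if (d$status == "screened_in" && !is.null(birth) &&
        note$patient_id %in% names(birth) &&
        !passes_age_filter(birth[[note$patient_id]], note$date,
                           min_age_years)) {
      d$status <- "excluded_underage"
    }
    row <- data.frame(note_id = note$note_id, status = d$status,
                      n_hits = nrow(hits), stringsAsFactors = FALSE)
    row$seeds_hit <- list(unique(hits$canonical_seed))
    row$terms_hit <- list(unique(hits$matched_term))
    dec_rows[[i]] <- row
    if (d$status == "screened_in") {
      s <- extract_cannabis_sentences(note, lexicon, d)
      if (nrow(s)) sent_rows[[length(sent_rows) + 1L]] <- s
    }
  }
  decisions <- do.call(rbind, dec_rows)
  sentences <- if (length(sent_rows)) do.call(rbind, sent_rows) else
    data.frame(note_id = character(0), sentence_index = integer(0),
               sentence_text = character(0), stringsAsFactors = FALSE)
  list(decisions = decisions, sentences = sentences)
}

#' Per-seed note counts
#'
#' Number of distinct notes whose hits include each canonical seed; a note
#' with two hits on one seed counts once for that seed but a note can count
#' toward several seeds.
#'
#' @param decisions Decision data frame from [screen_notes()] (uses the
#'   `seeds_hit` list-column).
#' @return Named integer vector seed -> note count (empty for no hits).
#' @export
keyword_histogram <- function(decisions) {
  if (!nrow(decisions)) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(decisions)), function(i) {
    seeds <- decisions$seeds_hit[[i]]
    if (!length(seeds)) return(NULL)
    data.frame(note_id = decisions$note_id[i], seed = seeds,
               stringsAsFactors = FALSE)
  })))
  if (is.null(pairs) || !nrow(pairs)) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(pairs$seed)
  stats::setNames(as.integer(tab), names(tab))
}
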