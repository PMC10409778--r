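# Patient-level aggregation, yearly trend tables, diagnostic-code
# cross-checking, and grouped procedure distributions.

#' Aggregate sentence labels to patient-level cannabis status
#'
#' A patient is `positive` when at least one sentence in any of their notes
#' is labeled positive; `negative_documented` when they have at least one
#' screened-in note but no positive sentence; otherwise `undocumented`.
#' `first_positive_date` is the earliest note date bearing a positive
#' sentence, and the age at that date is reported in years.
#'
#' @param notes Note table (`note_id`, `patient_id`, `date`).
#' @param decisions Decision table from [screen_notes()].
#' @param use_labels Sentence table with `note_id` and `label` (rule or model
#'   output).
#' @param patients Patient table (`patient_id`, `birth_date`).
#' @return Data frame: `patient_id`, `status`, `first_positive_date`,
#'   `age_at_first_positive`.
#' @export
aggregate_patient_status <- function(notes, decisions, use_labels, patients) {
  stopifnot(all(c("note_id", "patient_id", "date") %in% names(notes)))
  if (nrow(use_labels) && !all(use_labels$note_id %in% notes$note_id)) {
    bad <- setdiff(unique(use_labels$note_id), notes$note_id)
    stop("labels reference unknown notes: ", paste(bad, collapse = ", "))
  }
  notes$date <- as.Date(notes$date)
  note_pat <- stats::setNames(notes$patient_id, notes$note_id)
  note_date <- stats::setNames(notes$date, notes$note_id)

  screened <- decisions$note_id[decisions$status == "screened_in"]
  documented_pat <- unique(note_pat[screened])

  pos_notes <- unique(use_labels$note_id[use_labels$label == "positive"])
  pos <- data.frame(patient_id = unname(note_pat[pos_notes]),
                    date = as.Date(unname(note_date[pos_notes])),
                    stringsAsFactors = FALSE)

  out <- data.frame(patient_id = patients$patient_id,
                    stringsAsFactors = FALSE)
  out$status <- "undocumented"
  out$status[out$patient_id %in% documented_pat] <- "negative_documented"
  out$first_positive_date <- as.Date(NA)
  if (nrow(pos)) {
    first <- stats::aggregate(date ~ patient_id, data = pos, FUN = min)
    idx <- match(first$patient_id, out$patient_id)
    keep <- !is.na(idx)
    out$status[idx[keep]] <- "positive"
    out$first_positive_date[idx[keep]] <- first$date[keep]
  }
  birth <- as.Date(patients$birth_date[match(out$patient_id,
                                             patients$patient_id)])
  out$age_at_first_positive <-
    as.numeric(out$first_positive_date - birth) / 365.25
  out
}

#' Yearly documentation and positivity trend table
#'
#' Per calendar year: percentage of all notes with documented cannabis use
#' (screened in) and with positive use; the same two percentages restricted
#' to orthopedic/sports-medicine (OSM) notes over OSM denominators; the
#' number of newly identified positive patients (each positive patient counts
#' once, in the year of their first positive note); new positives by race;
#' percent female among new positives; and mean (95% t-interval) age of new
#' positives. Years with zero notes are omitted.
#'
#' @param notes Note table (`note_id`, `patient_id`, `date`, optional
#'   `is_osm`).
#' @param decisions Decision table from [screen_notes()].
#' @param use_labels Labeled sentence table.
#' @param patients Patient table (`patient_id`, `sex`, `race`, `birth_date`).
#' @param statuses Output of [aggregate_patient_status()].
#' @return Data frame, one row per year, plus a `new_positive_by_race`
#'   list-column of named counts.
#' @export
trend_table <- function(notes, decisions, use_labels, patients, statuses) {
  notes$date <- as.Date(notes$date)
  notes$year <- as.integer(format(notes$date, "%Y"))
  if (is.null(notes$is_osm)) notes$is_osm <- FALSE
  status_of <- stats::setNames(decisions$status, decisions$note_id)
  notes$documented <- unname(status_of[notes$note_id]) == "screened_in"
  pos_notes <- unique(use_labels$note_id[use_labels$label == "positive"])
  notes$positive <- notes$note_id %in% pos_notes

  newpos <- statuses[statuses$status == "positive", , drop = FALSE]
  newpos$year <- as.integer(format(newpos$first_positive_date, "%Y"))
  pinfo <- patients[match(newpos$patient_id, patients$patient_id), ,
                    drop = FALSE]
  newpos$sex <- pinfo$sex
  newpos$race <- pinfo$race

  years <- sort(unique(notes$year))
  rows <- lapply(years, function(y) {
    ny <- notes[notes$year == y, , drop = FALSE]
    osm <- ny[ny$is_osm, , drop = FALSE]
    np <- newpos[!is.na(newpos$year) & newpos$year == y, , drop = FALSE]
    ages <- np$age_at_first_positive[!is.na(np$age_at_first_positive)]
    ci <- c(NA_real_, NA_real_)
    if (length(ages) >= 2L && stats::sd(ages) > 0) {
      tt <- stats::t.test(ages)
      ci <- as.numeric(tt$conf.int)
    }
    row <- data.frame(
      year = y,
      n_notes = nrow(ny),
      pct_documented_all_notes = 100 * mean(ny$documented),
      pct_positive_all_notes = 100 * mean(ny$positive),
      pct_documented_osm = if (nrow(osm)) 100 * mean(osm$documented) else NA_real_,
      pct_positive_osm = if (nrow(osm)) 100 * mean(osm$positive) else NA_real_,
      n_new_positive_patients = nrow(np),
      pct_new_positive_female = if (nrow(np))
        100 * mean(np$sex == "female") else NA_real_,
      mean_age_new_positive = if (length(ages)) mean(ages) else NA_real_,
      age_ci_low = ci[1], age_ci_high = ci[2],
      stringsAsFactors = FALSE)
    row$new_positive_by_race <- list(table(np$race))
    row
  })
  do.call(rbind, rows)
}

#' Default cannabis-misuse diagnostic codebook
#'
#' ICD code families are matched by prefix through the dot hierarchy
#' (F12.20 extends F12); SNOMED CT concepts are matched exactly.
#'
#' @return List with `icd10_prefixes`, `icd9_prefixes`, `snomed_codes`.
#' @export
default_codebook <- function() {
  list(icd10_prefixes = c("F12", "T40.7"),
       icd9_prefixes = c("305.2", "304.3"),
       snomed_codes = c("7344009", "28823006", "85005007", "191837001"))
}

# strip dots and uppercase so F12.20 / f1220 compare equal
.norm_code <- function(code) toupper(gsub("\\.", "", code))

#' Patients carrying a cannabis-related diagnostic code
#'
#' @param records Diagnosis table: `patient_id`, `code`, `vocabulary` (one of
#'   `ICD-9-CM`, `ICD-10-CM`, `SNOMED-CT`; `ICD9/ICD10/SNOMED` synonyms
#'   accepted), `date` (unused for matching).
#' @param codebook Codebook list as from [default_codebook()].
#' @return Character vector of distinct patient ids with at least one
#'   matching record.
#' @export
match_diagnosis_codes <- function(records, codebook = default_codebook()) {
  if (!nrow(records)) return(character(0))
  voc <- toupper(gsub("[^A-Z0-9]", "", toupper(records$vocabulary)))
  matched <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    code <- records$code[i]
    if (voc[i] %in% c("ICD10CM", "ICD10")) {
      matched[i] <- any(startsWith(.norm_code(code),
                                   .norm_code(codebook$icd10_prefixes)))
    } else if (voc[i] %in% c("ICD9CM", "ICD9")) {
      matched[i] <- any(startsWith(.norm_code(code),
                                   .norm_code(codebook$icd9_prefixes)))
    } else if (voc[i] %in% c("SNOMEDCT", "SNOMED")) {
      matched[i] <- code %in% codebook$snomed_codes
    } else {
      stop("unknown vocabulary: ", records$vocabulary[i])
    }
  }
  unique(records$patient_id[matched])
}

#' Overlap between NLP-identified and code-diagnosed positive patients
#'
#' @param nlp_positive Character vector of patient ids found positive by the
#'   NLP pipeline (must be non-empty).
#' @param dx_positive Character vector of patient ids with a matching
#'   diagnostic code.
#' @return List: `overlap` (count) and `percent` (share of NLP positives also
#'   diagnosed, percent, rounded to 1 decimal).
#' @examples
#' crosscheck_fraction(as.character(1:13556), as.character(1:1971))
#' @export
crosscheck_fraction <- function(nlp_positive, dx_positive) {
  nlp_positive <- unique(as.character(nlp_positive))
  dx_positive <- unique(as.character(dx_positive))
  if (!length(nlp_positive)) {
    stop("percent undefined: no NLP-positive patients")
  }
  ov <- length(intersect(nlp_positive, dx_positive))
  list(overlap = ov, percent = round(100 * ov / length(nlp_positive), 1))
}

#' Grouped procedure distribution for positive vs. negative patients
#'
#' Generic grouped-count report: per procedure group, the percentage of
#' procedure records in each cohort.
#'
#' @param procedures Data frame: `patient_id`, `group`.
#' @param statuses Output of [aggregate_patient_status()].
#' @param negative Which patients form the comparison cohort:
#'   `"all_others"` (everyone not positive) or `"documented"` (documented
#'   negatives only).
#' @return Data frame: `group`, `pct_positive`, `pct_negative`; each column
#'   sums to 100 over groups (when its cohort has records).
#' @export
procedure_group_distribution <- function(procedures, statuses,
                                         negative = c("all_others",
                                                      "documented")) {
  negative <- match.arg(negative)
  pos_ids <- statuses$patient_id[statuses$status == "positive"]
  neg_ids <- if (negative == "all_others") {
    statuses$patient_id[statuses$status != "positive"]
  } else {
    statuses$patient_id[statuses$status == "negative_documented"]
  }
  groups <- sort(unique(procedures$group))
  pct <- function(ids) {
    sub <- procedures[procedures$patient_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) return(stats::setNames(rep(NA_real_, length(groups)),
                                           groups))
    tab <- table(factor(sub$group, levels = groups))
    100 * as.numeric(tab) / nrow(sub)
  }
  data.frame(group = groups,
             pct_positive = pct(pos_ids),
             pct_negative = pct(neg_ids),
             stringsAsFactors = FALSE, row.names = NULL)
}
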