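# File schemas: JSONL note corpora, CSV patient/diagnosis tables.
# Readers validate row-level constraints and report offending ids/lines.

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
}

#' Read a note corpus (JSONL or CSV)
#'
#' JSONL carries one object per line with fields `note_id`, `patient_id`,
#' `date` (ISO-8601), `is_osm`, `text`; a CSV with identical headers is also
#' accepted. Validates unique note ids and parseable dates.
#'
#' @param path Input file; `.jsonl`/`.ndjson` parsed as JSON lines, anything
#'   else as CSV.
#' @return Data frame of typed note records.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("line ", i, ": ",
                                               conditionMessage(e)))
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    notes <- do.call(rbind, recs)
  } else {
    notes <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if ("is_osm" %in% names(notes)) {
      notes$is_osm <- toupper(notes$is_osm) %in% c("TRUE", "1", "T")
    }
  }
  .require_cols(notes, c("note_id", "patient_id", "date", "text"), path)
  if (is.null(notes$is_osm)) notes$is_osm <- FALSE
  dup <- unique(notes$note_id[duplicated(notes$note_id)])
  if (length(dup)) {
    stop("duplicated note_id in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  d <- as.Date(notes$date)
  if (anyNA(d)) {
    stop("unparseable date(s) in ", path, " for note(s) ",
         paste(utils::head(notes$note_id[is.na(d)], 5), collapse = ", "))
  }
  notes$date <- d
  notes[, c("note_id", "patient_id", "date", "is_osm", "text")]
}

#' Read a patient table (CSV)
#'
#' Columns: `patient_id`, `sex`, `race`, `birth_date`, `svi`. Validates
#' unique ids, parseable birth dates and SVI in \[0,1\] (or empty for
#' missing).
#'
#' @param path CSV path.
#' @return Data frame of typed patient records.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  .require_cols(p, c("patient_id", "sex", "race", "birth_date", "svi"), path)
  dup <- unique(p$patient_id[duplicated(p$patient_id)])
  if (length(dup)) {
    stop("duplicated patient_id in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  p$birth_date <- as.Date(p$birth_date)
  if (anyNA(p$birth_date)) stop("unparseable birth_date in ", path)
  p$svi <- suppressWarnings(as.numeric(ifelse(p$svi == "", NA, p$svi)))
  bad <- !is.na(p$svi) & (p$svi < 0 | p$svi > 1)
  if (any(bad)) {
    stop("svi outside [0,1] in ", path, " for patient(s) ",
         paste(utils::head(p$patient_id[bad], 5), collapse = ", "))
  }
  p
}

#' Read a diagnosis table (CSV)
#'
#' Columns: `patient_id`, `code`, `vocabulary`, `date`.
#'
#' @param path CSV path.
#' @return Data frame of typed diagnosis records.
#' @export
read_diagnoses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  .require_cols(d, c("patient_id", "code", "vocabulary", "date"), path)
  d$date <- as.Date(d$date)
  d
}

#' Write a data frame as JSON lines
#'
#' One JSON object per row, UTF-8; list-columns are serialized as arrays.
#' Canonical field order and number formatting make regeneration under the
#' same seed byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    row <- lapply(df[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      if (inherits(v, "Date")) format(v, "%Y-%m-%d") else v
    })
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Distinct normalized word tokens of a note corpus
#'
#' The vocabulary fed to [expand_misspellings()]: every distinct token after
#' lowercasing and stripping non-letters, tokens shorter than `min_nchar`
#' dropped.
#'
#' @param texts Character vector of note texts.
#' @param min_nchar Minimum token length kept (default 3).
#' @return Sorted character vector.
#' @export
corpus_vocabulary <- function(texts, min_nchar = 3L) {
  toks <- unlist(regmatches(texts, gregexpr("[A-Za-z]+", texts)))
  toks <- unique(tolower(toks))
  sort(toks[nchar(toks) >= min_nchar])
}
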