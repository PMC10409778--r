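# Rule-based sentence splitting for clinical free text.
#
# Clinical notes mix narrative prose with template fields ("MJ: +"),
# abbreviations (Dr., prn.) and drug strings with embedded punctuation
# ("MARINOL(2.5MG/TAB"). The splitter is deterministic and requires no model:
# a candidate boundary is a sentence-final character followed by whitespace,
# and a period boundary is vetoed when it terminates a known clinical
# abbreviation or a single capital (initials).

.clinical_abbrevs <- c(
  "dr", "mr", "mrs", "ms", "prn", "qd", "bid", "tid", "qid", "hs", "po",
  "hx", "dx", "rx", "fx", "sx", "tx", "pt", "pts", "vs", "st", "etc", "eg",
  "ie", "approx", "appt", "yo", "y.o", "mos", "wk", "wks", "neg", "pos"
)

#' Split free text into sentence spans
#'
#' @param text Character scalar (may be empty).
#' @return Data frame with columns `sentence_index` (0-based), `start`, `end`
#'   (1-based inclusive character offsets into `text`) and `sentence_text`.
#'   Spans are ordered, non-overlapping, and jointly cover all non-whitespace
#'   characters. Empty or all-whitespace input gives zero rows.
#' @examples
#' split_sentences("Denies use. Urine tox negative.")$sentence_text
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(sentence_index = integer(0), start = integer(0),
                      end = integer(0), sentence_text = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  # candidate boundaries: ., !, ?, or newline acting as a hard break
  boundary <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") { boundary[i] <- TRUE; next }
    if (!ch %in% c(".", "!", "?")) next
    nxt <- if (i < n) chars[i + 1L] else " "
    if (!grepl("[[:space:]]", nxt)) next    # "2.5MG", "y.o." mid-token
    if (ch == ".") {
      # word immediately before the period
      j <- i - 1L
      while (j >= 1L && grepl("[A-Za-z.]", chars[j])) j <- j - 1L
      word <- if (j + 1L <= i - 1L) {
        tolower(gsub("\\.$", "", paste(chars[(j + 1L):(i - 1L)], collapse = "")))
      } else ""
      if (word %in% .clinical_abbrevs) next
      if (nchar(word) == 1L && grepl("[a-z]", word)) next  # initials
    }
    boundary[i] <- TRUE
  }

  ends <- which(boundary)
  if (!length(ends) || ends[length(ends)] < n) ends <- c(ends, n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  out <- list()
  idx <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    seg <- substr(text, s, e)
    # trim whitespace but keep offsets aligned to the original text
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (s2 > e2) next
    out[[length(out) + 1L]] <- data.frame(
      sentence_index = idx, start = s2, end = e2,
      sentence_text = substr(text, s2, e2), stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
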