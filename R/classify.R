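# Sentence-level positive/negative use classification: deterministic
# negation-aware rule baseline, a trainable n-gram linear model, and an
# evaluation harness.

#' Assign train/validation/test splits grouped by note
#'
#' Sentences from one note never straddle splits (grouping by `note_id`), so
#' no information leaks from train to test through a shared note. Assignment
#' is deterministic given the seed.
#'
#' @param sentences Data frame with at least `note_id`.
#' @param fractions Numeric length-3 vector (train, valid, test) summing to 1.
#' @param seed Integer RNG seed.
#' @return `sentences` with a `split` column (`train`/`valid`/`test`).
#' @export
assign_splits <- function(sentences, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(is.data.frame(sentences), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  notes <- unique(sentences$note_id)
  if (length(notes) < 3L) stop("need at least 3 distinct notes to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  notes <- sample(notes)
  n <- length(notes)
  n_train <- max(1L, round(fractions[1] * n))
  n_valid <- max(1L, round(fractions[2] * n))
  if (n_train + n_valid >= n) {
    n_train <- n - 2L; n_valid <- 1L
  }
  split_of <- stats::setNames(
    rep(c("train", "valid", "test"),
        c(n_train, n_valid, n - n_train - n_valid)), notes)
  sentences$split <- unname(split_of[sentences$note_id])
  sentences
}

# save/restore global RNG state so package functions with a seed argument
# do not perturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# --- rule-based baseline ----------------------------------------------------

.rx_tox_positive <- "(positive\\s+for\\b[^.;]*)|(\\btox[^.;]*\\bpositive\\b)"
.rx_negation <- paste0(
  "\\b(denies|denied|deny|negative\\s+for|no\\s+(use|history)|not\\s+tried|",
  "never(\\s+(used|tried|smoked))?|does\\s+not\\s+(use|smoke)|quit)\\b")
.rx_affirmation <- paste0(
  "\\b(admits?|admitted|endorses?|smokes?|smoking|using|uses|used|",
  "reports?\\s+(using|use|smoking)|states?\\s+(used|using|smoking)|",
  "agreed\\s+to\\s+try|daily|vapes?|vaping|rx|prescribed|prescription)\\b")
.rx_counseling <- paste0(
  "\\b(discussed|discussion|counsel(ed|ing)?|educat(ed|ion)|",
  "pros\\s+and\\s+cons|risks?\\s+(of|and))\\b")
.rx_third_party <- paste0(
  "\\b(mother|father|mom|dad|brother|sister|grandmother|grandfather|",
  "guardian'?s|sibling|roommate|household|family\\s+member|in\\s+utero|",
  "maternal|prenatal|pregnancy|hallways?)\\b")
.rx_patient_anchor <- paste0(
  "\\b(pt|patient|he|she|they)\\s+(admits?|endorses?|reports?|states?|",
  "smokes|uses)\\b|\\badmits?\\s+to\\b|\\bstates?\\s+(used|using)\\b")

# cue positions (start offsets) of a regex in lowercased text
.cue_pos <- function(low, rx) {
  m <- gregexpr(rx, low, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Deterministic rule-based use label for one sentence
#'
#' Negation-aware cue scoping in the spirit of NegEx-style assertion rules,
#' specialised to the cannabis vocabulary. Decision order:
#' \enumerate{
#'   \item A toxicology-positive pattern ("positive for ... cannabis",
#'     "tox ... positive") that covers a cannabis term, or a template "+"
#'     immediately after a cannabis field ("MJ: +", "THC +"), is positive and
#'     overrides any denial earlier in the sentence.
#'   \item A counseling/discussion cue with no patient-anchored affirmation is
#'     negative (pros-and-cons conversations are not positive use).
#'   \item A third-party attribution cue (mother, brother, household, in
#'     utero, ...) with no patient-anchored affirmation is negative: someone
#'     else's use does not make the patient a user.
#'   \item Otherwise each cannabis term is scoped to cues earlier in its
#'     clause (clauses split at ";"): an in-clause negation cue scopes forward
#'     over the whole clause and negates the term even across intervening
#'     affirmation words; with no negation, a preceding affirmation cue makes
#'     the sentence positive. Any negated term makes the sentence negative.
#'   \item No cue at all: negative (a bare mention is documentation, not
#'     endorsement).
#' }
#'
#' @param sentence_text Character scalar; must contain at least one lexicon
#'   hit.
#' @param lexicon `cannabis_lexicon`.
#' @return List of class `use_label`: `label` (`"positive"`/`"negative"`) and
#'   `score` (0.95 for rule positive, 0.05 for rule negative).
#' @examples
#' lex <- build_lexicon()
#' rule_based_label("Pt admits to smoking marijuana daily", lex)$label
#' @export
rule_based_label <- function(sentence_text, lexicon) {
  hits <- find_keyword_hits(sentence_text, lexicon)
  if (!nrow(hits)) stop("rule_based_label requires a sentence with a lexicon hit")
  low <- tolower(sentence_text)

  # 1. toxicology / template positives
  m <- gregexpr(.rx_tox_positive, low, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      s <- m[i]; e <- s + attr(m, "match.length")[i] - 1L
      # positive finding scopes to the end of its clause
      semis <- .cue_pos(low, ";")
      scope_end <- min(c(semis[semis > e], nchar(low)))
      if (any(hits$start >= s & hits$start <= scope_end)) {
        return(.use_label("positive", 0.95))
      }
    }
  }
  for (k in seq_len(nrow(hits))) {
    tail <- substr(low, hits$end[k] + 1L, hits$end[k] + 4L)
    if (grepl("^\\s*:?\\s*\\+", tail)) return(.use_label("positive", 0.95))
  }

  anchored <- grepl(.rx_patient_anchor, low, perl = TRUE)

  # 2. counseling-only mentions
  if (grepl(.rx_counseling, low, perl = TRUE) && !anchored) {
    return(.use_label("negative", 0.05))
  }
  # 3. third-party use
  if (grepl(.rx_third_party, low, perl = TRUE) && !anchored) {
    return(.use_label("negative", 0.05))
  }

  # 4. clause-scoped cue resolution: a negation cue scopes forward over the
  # rest of its clause ("denied smoking marijuana" is negative even though
  # "smoking" sits between the denial and the term), so any preceding
  # in-clause negation wins; otherwise a preceding affirmation affirms.
  clause_break <- c(0L, .cue_pos(low, ";"), nchar(low) + 1L)
  neg_pos <- .cue_pos(low, .rx_negation)
  aff_pos <- .cue_pos(low, .rx_affirmation)
  any_affirmed <- FALSE
  any_negated <- FALSE
  for (k in seq_len(nrow(hits))) {
    p <- hits$start[k]
    cl_start <- max(clause_break[clause_break < p])
    has_neg <- any(neg_pos < p & neg_pos > cl_start)
    has_aff <- any(aff_pos < p & aff_pos > cl_start)
    if (has_neg) any_negated <- TRUE
    else if (has_aff) any_affirmed <- TRUE
  }
  if (any_negated) return(.use_label("negative", 0.05))
  if (any_affirmed) return(.use_label("positive", 0.95))
  .use_label("negative", 0.05)
}

.use_label <- function(label, score) {
  structure(list(label = label, score = score), class = "use_label")
}

#' Label every extracted sentence with the rule baseline
#'
#' @param sentences Sentence data frame from [screen_notes()].
#' @param lexicon `cannabis_lexicon`.
#' @return `sentences` with `label` and `score` columns appended.
#' @export
label_sentences <- function(sentences, lexicon) {
  if (!nrow(sentences)) {
    sentences$label <- character(0); sentences$score <- numeric(0)
    return(sentences)
  }
  labs <- lapply(sentences$sentence_text, rule_based_label, lexicon = lexicon)
  sentences$label <- vapply(labs, `[[`, "", "label")
  sentences$score <- vapply(labs, `[[`, 0, "score")
  sentences
}

# --- trainable n-gram linear model ------------------------------------------

# word unigram + bigram document-term matrix (sparse), vocabulary optionally
# fixed (for prediction-time alignment)
.dtm <- function(texts, vocab = NULL) {
  toks <- lapply(tolower(texts), function(t) {
    w <- regmatches(t, gregexpr("[a-z0-9+]+", t))[[1]]
    if (length(w) > 1L) c(w, paste(w[-length(w)], w[-1L])) else w
  })
  if (is.null(vocab)) vocab <- sort(unique(unlist(toks)))
  ij <- lapply(seq_along(toks), function(i) {
    idx <- match(toks[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    tab <- table(idx)
    cbind(i = i, j = as.integer(names(tab)), x = as.integer(tab))
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) ij <- cbind(i = integer(0), j = integer(0), x = integer(0))
  m <- Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = ij[, "x"],
                            dims = c(length(toks), length(vocab)))
  list(m = m, vocab = vocab)
}

#' Train the baseline sentence classifier
#'
#' A ridge-penalised logistic regression on word unigram + bigram counts —
#' a deterministic desk-scale stand-in for heavier contextual models, behind
#' the same train/predict contract so other backends can be plugged in.
#'
#' @param train,valid Data frames with `sentence_text` and `label`
#'   (`"positive"`/`"negative"`); both must be non-empty and `train` must
#'   contain both classes.
#' @param config Optional list: `lambda` (ridge penalty, default 0.01),
#'   `threshold` (decision threshold, default 0.5).
#' @return Object of class `use_classifier` with the fitted model, vocabulary,
#'   threshold, and validation metrics (`valid_metrics`).
#' @export
train_classifier <- function(train, valid, config = list()) {
  stopifnot(is.data.frame(train), is.data.frame(valid))
  if (!nrow(train) || !nrow(valid)) stop("train and valid must be non-empty")
  y <- as.integer(train$label == "positive")
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  lambda <- config$lambda %||% 0.01
  threshold <- config$threshold %||% 0.5
  d <- .dtm(train$sentence_text)
  fit <- glmnet::glmnet(d$m, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  model <- structure(list(fit = fit, vocab = d$vocab, threshold = threshold),
                     class = "use_classifier")
  preds <- predict_scores(model, valid)
  model$valid_metrics <- evaluate(preds, valid$label)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score sentences with a trained classifier
#'
#' @param model `use_classifier` from [train_classifier()].
#' @param sentences Data frame with `sentence_text` (other columns carried
#'   through).
#' @return `sentences` with `score` (probability of positive) and `label`
#'   columns; `label` is positive iff `score >= model$threshold`.
#' @export
predict_scores <- function(model, sentences) {
  stopifnot(inherits(model, "use_classifier"))
  d <- .dtm(sentences$sentence_text, vocab = model$vocab)
  p <- as.numeric(stats::predict(model$fit, d$m, type = "response"))
  sentences$score <- p
  sentences$label <- ifelse(p >= model$threshold, "positive", "negative")
  sentences
}

# --- evaluation -------------------------------------------------------------

#' Classification metrics against gold labels
#'
#' Confusion counts with the positive class as "positive", accuracy,
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), and AUROC computed by the
#' rank statistic (Mann-Whitney) with tie correction. AUROC requires scores
#' and both classes in the gold labels; without scores it is `NA`, and
#' single-class gold yields `NA` with a warning (the other metrics are still
#' returned).
#'
#' @param predictions Data frame with `label` and optionally `score`, or a
#'   character vector of labels.
#' @param gold Character vector of gold labels, same length.
#' @return List of class `eval_metrics`: `accuracy`, `auroc`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
evaluate <- function(predictions, gold) {
  if (is.data.frame(predictions)) {
    labels <- predictions$label
    scores <- predictions$score
  } else {
    labels <- as.character(predictions)
    scores <- NULL
  }
  gold <- as.character(gold)
  if (length(labels) != length(gold)) stop("length mismatch")
  if (!length(gold)) stop("empty input")
  pos <- gold == "positive"
  tp <- sum(labels == "positive" & pos)
  fp <- sum(labels == "positive" & !pos)
  tn <- sum(labels == "negative" & !pos)
  fn <- sum(labels == "negative" & pos)
  auroc <- NA_real_
  if (!is.null(scores)) {
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warning("auroc undefined: gold labels contain a single class")
    } else {
      r <- rank(scores)                    # midranks give the tie correction
      auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  structure(list(
    accuracy = (tp + tn) / length(gold),
    auroc = auroc,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(gold)),
    class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | auroc %s | sensitivity %.3f | specificity %.3f (n=%d)\n",
    x$accuracy, ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc)),
    x$sensitivity, x$specificity, x$n))
  invisible(x)
}
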