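# Adjusted-odds-ratio disparity models over sex, race, and SVI.

#' Build the disparity design (outcome + covariates)
#'
#' Two comparison settings mirror the two cohort contrasts:
#' `documentation` — any cannabis documentation (positive or negative) vs. no
#' documentation; `positive_use` — positive patients vs. a comparator that is
#' either all other patients (default) or documented negatives only.
#' Reference levels are male (sex) and white (race); patients with unknown
#' sex or unavailable race are kept in the model through indicator columns so
#' they still inform the other contrasts, but no aOR is reported for those
#' levels. SVI is rescaled by 100 so one model unit equals a 0.01 change in
#' the index; rows with missing SVI are dropped and counted.
#'
#' @param patients Patient table (`patient_id`, `sex`, `race`, `svi`).
#' @param statuses Output of [aggregate_patient_status()].
#' @param setting `"documentation"` or `"positive_use"`.
#' @param positive_comparator For `positive_use`: `"all_others"` (default) or
#'   `"documented_negative"`.
#' @return List of class `disparity_design`: `data` (model frame with
#'   `outcome`, `sex`, `race`, `svi100`, `patient_id`), `setting`,
#'   `n_dropped_svi`.
#' @export
build_design <- function(patients, statuses,
                         setting = c("documentation", "positive_use"),
                         positive_comparator = c("all_others",
                                                 "documented_negative")) {
  setting <- match.arg(setting)
  positive_comparator <- match.arg(positive_comparator)
  d <- merge(patients, statuses, by = "patient_id")
  if (setting == "documentation") {
    d$outcome <- as.integer(d$status != "undocumented")
  } else {
    if (positive_comparator == "documented_negative") {
      d <- d[d$status != "undocumented", , drop = FALSE]
    }
    d$outcome <- as.integer(d$status == "positive")
  }
  n0 <- nrow(d)
  d <- d[!is.na(d$svi), , drop = FALSE]
  n_dropped <- n0 - nrow(d)
  if (length(unique(d$outcome)) < 2L) {
    stop("outcome has a single level; disparity model not identifiable")
  }
  d$sex <- factor(d$sex, levels = c("male", "female", "unknown"))
  d$race <- factor(d$race, levels = c("white", "asian", "black", "hispanic",
                                      "other", "unavailable"))
  d$sex <- droplevels(d$sex)
  d$race <- droplevels(d$race)
  d$svi100 <- 100 * d$svi
  structure(list(
    data = d[, c("patient_id", "outcome", "sex", "race", "svi100")],
    setting = setting, n_dropped_svi = n_dropped),
    class = "disparity_design")
}

#' Fit the disparity model and report adjusted odds ratios
#'
#' Multivariable logistic regression of the design outcome on sex, race and
#' SVI. aORs are exponentiated coefficients with Wald 95% confidence
#' intervals and p-values. The default fixed-effects GLM treats each patient
#' as one independent row; `glmm_random_intercept` adds a random intercept
#' for a supplied clustering column (e.g. clinic site) via
#' [lme4::glmer()]. Zero-variance covariates are dropped with a warning, and
#' complete or quasi-complete separation is flagged on the affected results.
#'
#' @param design `disparity_design` from [build_design()].
#' @param method `"glm_logistic"` (default) or `"glmm_random_intercept"`.
#' @param cluster Optional vector (aligned with `design$data` rows) of
#'   cluster ids for the random intercept.
#' @return Data frame of class `disparity_result`: `setting`, `covariate`,
#'   `reference_level`, `aOR`, `ci_low`, `ci_high`, `p_value`, `flag`.
#'   Per convention SVI is reported per 0.01-unit change; `unknown` sex and
#'   `unavailable` race rows are omitted (reference-level aORs are 1 by
#'   construction and never reported as contrasts).
#' @export
fit_disparity_model <- function(design,
                                method = c("glm_logistic",
                                           "glmm_random_intercept"),
                                cluster = NULL) {
  stopifnot(inherits(design, "disparity_design"))
  method <- match.arg(method)
  d <- design$data

  terms <- c("sex", "race", "svi100")
  keep <- vapply(terms, function(t) length(unique(d[[t]])) > 1L, TRUE)
  if (!all(keep)) {
    warning("dropping zero-variance covariates: ",
            paste(terms[!keep], collapse = ", "))
  }
  rhs <- paste(terms[keep], collapse = " + ")
  if (!nzchar(rhs)) stop("no usable covariates")

  if (method == "glm_logistic") {
    fit <- stats::glm(stats::as.formula(paste("outcome ~", rhs)),
                      family = stats::binomial(), data = d)
    sm <- summary(fit)$coefficients
  } else {
    if (is.null(cluster)) stop("glmm_random_intercept requires a cluster vector")
    d$.cluster <- as.factor(cluster)
    fit <- lme4::glmer(
      stats::as.formula(paste("outcome ~", rhs, "+ (1 | .cluster)")),
      family = stats::binomial(), data = d,
      control = lme4::glmerControl(calc.derivs = FALSE))
    sm <- summary(fit)$coefficients
  }

  est <- sm[, 1]; se <- sm[, 2]
  pz <- 2 * stats::pnorm(-abs(est / se))
  sep_flag <- se > 10    # huge Wald SE is the usual separation footprint

  rows <- list()
  addrow <- function(term, covariate, reference) {
    if (!term %in% rownames(sm)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      setting = design$setting, covariate = covariate,
      reference_level = reference,
      aOR = exp(est[[term]]),
      ci_low = exp(est[[term]] - 1.96 * se[[term]]),
      ci_high = exp(est[[term]] + 1.96 * se[[term]]),
      p_value = pz[[term]],
      flag = if (sep_flag[[term]]) "possible_separation" else "",
      stringsAsFactors = FALSE)
  }
  addrow("sexfemale", "sex:female", "male")
  for (r in c("asian", "black", "hispanic", "other")) {
    addrow(paste0("race", r), paste0("race:", r), "white")
  }
  addrow("svi100", "svi_per_0.01", "")
  out <- do.call(rbind, rows)
  class(out) <- c("disparity_result", class(out))
  attr(out, "fit") <- fit
  attr(out, "n") <- nrow(d)
  attr(out, "n_dropped_svi") <- design$n_dropped_svi
  out
}

#' Reassign patients whose only positive evidence is medical cannabis
#'
#' Sensitivity filter: a positive patient whose positive sentences all
#' involve prescription cannabinoid terms (marinol, dronabinol, epidiolex,
#' syndros, cesamet, cannabidiol) in a prescription context (an "rx" or
#' "prescri-" cue in the sentence) is reassigned to `negative_documented`,
#' and the disparity model can then be refit on the filtered statuses.
#'
#' @param statuses Output of [aggregate_patient_status()].
#' @param use_labels Labeled sentence table including a `hits` list-column
#'   (from [screen_notes()]) and `sentence_text`.
#' @param notes Note table mapping `note_id` to `patient_id`.
#' @param lexicon `cannabis_lexicon` (supplies the medical-term list).
#' @return `statuses` with medical-only positives reassigned; attribute
#'   `n_reassigned` records how many.
#' @export
exclude_medical_cannabis <- function(statuses, use_labels, notes, lexicon) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  if (!nrow(use_labels)) {
    attr(statuses, "n_reassigned") <- 0L
    return(statuses)
  }
  pos <- use_labels[use_labels$label == "positive", , drop = FALSE]
  if (!nrow(pos)) {
    attr(statuses, "n_reassigned") <- 0L
    return(statuses)
  }
  medical_only <- vapply(seq_len(nrow(pos)), function(i) {
    h <- pos$hits[[i]]
    seeds <- if (is.null(h)) character(0) else unique(h$canonical_seed)
    rx_ctx <- grepl("\\brx\\b|prescri", tolower(pos$sentence_text[i]),
                    perl = TRUE)
    length(seeds) > 0 && all(seeds %in% lexicon$medical_terms) && rx_ctx
  }, TRUE)
  pos$medical_only <- medical_only
  pat_of <- stats::setNames(notes$patient_id, notes$note_id)
  pos$patient_id <- unname(pat_of[pos$note_id])
  # patients with >= 1 non-medical positive sentence stay positive
  by_pat <- split(pos$medical_only, pos$patient_id)
  reassign <- names(by_pat)[vapply(by_pat, all, TRUE)]
  idx <- statuses$patient_id %in% reassign & statuses$status == "positive"
  statuses$status[idx] <- "negative_documented"
  statuses$first_positive_date[idx] <- as.Date(NA)
  statuses$age_at_first_positive[idx] <- NA_real_
  attr(statuses, "n_reassigned") <- sum(idx)
  statuses
}
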