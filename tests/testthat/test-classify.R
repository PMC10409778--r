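# Sentence classification: splits, rule baseline, trained model, metrics.

lex <- build_lexicon()

test_that("splits are note-grouped, proportioned, deterministic", {
  s <- data.frame(note_id = sprintf("N%02d", 1:10),
                  sentence_text = "x", stringsAsFactors = FALSE)
  out <- assign_splits(s, seed = 1)
  expect_equal(as.integer(table(out$split)[c("train", "valid", "test")]),
               c(8L, 1L, 1L))
  expect_identical(out, assign_splits(s, seed = 1))

  # sentences of one note stay together
  s2 <- data.frame(note_id = rep(sprintf("N%02d", 1:10), each = 3),
                   sentence_text = "x", stringsAsFactors = FALSE)
  out2 <- assign_splits(s2, seed = 4)
  per_note <- tapply(out2$split, out2$note_id,
                     function(x) length(unique(x)))
  expect_true(all(per_note == 1L))

  expect_error(assign_splits(s[1:2, ], seed = 1), "at least 3")
  expect_error(assign_splits(s, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("rule baseline reproduces the published example polarities", {
  ex <- example_sentences()
  for (i in seq_len(nrow(ex))) {
    got <- rule_based_label(ex$sentence_text[i], lex)
    expect_equal(got$label, ex$label[i], label = ex$sentence_text[i])
  }
  expect_error(rule_based_label("no relevant terms here", lex),
               "lexicon hit")
})

test_that("rule baseline handles negation, toxicology, third-party scoping", {
  pos <- c("Urine tox screen: positive for amphetamines and cannabis.",
           "THC +",
           "She admits to using cannabis most evenings.")
  neg <- c("Urine tox sent, negative for cannabis and opiates.",
           "Patient denies marijuana use at this time.",
           "She denied smoking marijuana when asked directly.",
           "Mother reports marijuana use in the household but not by the patient.",
           "Provided education about cannabis and driving safety.")
  for (s in pos) expect_equal(rule_based_label(s, lex)$label, "positive",
                              label = s)
  for (s in neg) expect_equal(rule_based_label(s, lex)$label, "negative",
                              label = s)
})

test_that("trained n-gram model separates planted cue classes", {
  lab <- generate_labeled_sentences(400, noise = 0, seed = 9)
  lab <- assign_splits(lab, seed = 2)
  train <- lab[lab$split == "train", ]
  valid <- lab[lab$split == "valid", ]
  m <- train_classifier(train, valid)
  expect_gte(m$valid_metrics$accuracy, 0.95)

  # retraining is deterministic
  m2 <- train_classifier(train, valid)
  expect_equal(m$valid_metrics$accuracy, m2$valid_metrics$accuracy)
  expect_equal(m$valid_metrics$auroc, m2$valid_metrics$auroc)

  expect_error(train_classifier(train[0, ], valid), "non-empty")
  one_class <- train[train$label == "positive", ]
  expect_error(train_classifier(one_class, valid), "both classes")

  # agreement with the rule baseline on cue-pure sentences
  test <- lab[lab$split == "test", ]
  pred <- predict_scores(m, test)
  rule <- vapply(test$sentence_text,
                 function(s) rule_based_label(s, lex)$label, "")
  expect_gte(mean(pred$label == rule), 0.90)
})

test_that("scores respect the decision threshold monotonically", {
  lab <- generate_labeled_sentences(200, noise = 0, seed = 13)
  lab <- assign_splits(lab, seed = 2)
  m <- train_classifier(lab[lab$split == "train", ],
                        lab[lab$split == "valid", ])
  pred <- predict_scores(m, lab)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$label, ifelse(pred$score >= 0.5, "positive", "negative"))
  n_pos <- function(thr) sum(pred$score >= thr)
  thrs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(thrs, n_pos, 0L)) <= 0))
})

test_that("evaluate matches hand-computed confusion arithmetic", {
  pred <- c("positive", "positive", "positive", "negative")
  gold <- c("positive", "positive", "negative", "negative")
  ev <- evaluate(pred, gold)
  expect_equal(ev$tp, 2L); expect_equal(ev$fp, 1L)
  expect_equal(ev$tn, 1L); expect_equal(ev$fn, 0L)
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 0.5)

  perfect <- data.frame(label = gold, score = c(0.9, 0.8, 0.2, 0.1))
  evp <- evaluate(perfect, gold)
  expect_equal(evp$accuracy, 1.0)
  expect_equal(evp$auroc, 1.0)
  expect_equal(evp$sensitivity, 1.0)
  expect_equal(evp$specificity, 1.0)
})

test_that("evaluate equals brute-force enumeration on all <=8-item inputs", {
  for (n in 1:4) {
    combos <- expand.grid(rep(list(c("positive", "negative")), 2 * n),
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      pred <- unlist(combos[r, 1:n], use.names = FALSE)
      gold <- unlist(combos[r, (n + 1):(2 * n)], use.names = FALSE)
      got <- evaluate(pred, gold)
      want <- oracle_metrics(pred, gold)
      expect_equal(got$tp, want$tp); expect_equal(got$fp, want$fp)
      expect_equal(got$tn, want$tn); expect_equal(got$fn, want$fn)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$sensitivity, want$sensitivity)
      expect_equal(got$specificity, want$specificity)
    }
  }
})

test_that("auroc is rank-based: monotone-invariant, ~0.5 under random scores", {
  set.seed(5)
  gold <- rep(c("positive", "negative"), each = 30)
  score <- stats::runif(60)
  pred <- data.frame(label = ifelse(score >= 0.5, "positive", "negative"),
                     score = score)
  a1 <- evaluate(pred, gold)$auroc
  pred2 <- pred; pred2$score <- stats::plogis(5 * score - 2)  # strictly monotone
  expect_equal(evaluate(pred2, gold)$auroc, a1, tolerance = 1e-12)

  set.seed(99)
  gold_big <- sample(rep(c("positive", "negative"), each = 500))
  predb <- data.frame(label = "negative", score = stats::runif(1000))
  expect_lt(abs(evaluate(predb, gold_big)$auroc - 0.5), 0.06)

  expect_warning(ev1 <- evaluate(data.frame(label = "positive", score = 0.9),
                                 "positive"), "single class")
  expect_true(is.na(ev1$auroc))
  expect_equal(ev1$accuracy, 1.0)
})
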