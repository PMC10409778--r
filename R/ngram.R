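# Character n-gram machinery used for misspelling detection.

#' Normalize a token for n-gram profiling
#'
#' Lowercases and strips every non-letter character. Profiling and cosine
#' similarity are always computed on this normalized form so that case or
#' punctuation in the source text cannot change a similarity value.
#'
#' @param token Character scalar.
#' @return Normalized character scalar (possibly empty).
#' @export
normalize_token <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  gsub("[^a-z]", "", tolower(token))
}

#' Character n-gram count profile of a token
#'
#' Counts every contiguous character substring of lengths `n_min` through
#' `n_max` of the normalized token, combined into a single named count vector
#' (one shared vector space across all gram lengths).
#'
#' @param token Character scalar; must be non-empty after normalization.
#' @param n_min,n_max Gram length range; defaults 1 and 3.
#' @return Object of class `ngram_profile`: a named integer vector of counts
#'   with attributes `token`, `n_min`, `n_max`.
#' @examples
#' p <- char_ngram_profile("marijuana")
#' p[["a"]]  # 3
#' @export
char_ngram_profile <- function(token, n_min = 1L, n_max = 3L) {
  tok <- normalize_token(token)
  if (nchar(tok) == 0L) {
    stop("token is empty after normalization: ", sQuote(token))
  }
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 1L || n_min > n_max) {
    stop("require 1 <= n_min <= n_max")
  }
  len <- nchar(tok)
  grams <- character(0)
  for (n in seq(n_min, min(n_max, len))) {
    grams <- c(grams, substring(tok, seq_len(len - n + 1L), seq(n, len)))
  }
  counts <- table(grams)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, token = tok, n_min = n_min, n_max = n_max,
            class = "ngram_profile")
}

#' Cosine similarity of two n-gram profiles
#'
#' Standard cosine A.B / (|A||B|) over the union of n-gram keys of the two
#' count vectors. Both profiles must have been built with the same gram-length
#' range. Returns 0 when the supports are disjoint.
#'
#' @param a,b `ngram_profile` objects from [char_ngram_profile()].
#' @return Similarity in \[0, 1\].
#' @examples
#' a <- char_ngram_profile("marijuana")
#' b <- char_ngram_profile("marijuahana")
#' round(ngram_cosine(a, b), 2)  # 0.90
#' @export
ngram_cosine <- function(a, b) {
  stopifnot(inherits(a, "ngram_profile"), inherits(b, "ngram_profile"))
  if (attr(a, "n_min") != attr(b, "n_min") ||
      attr(a, "n_max") != attr(b, "n_max")) {
    stop("profiles built with different n-gram ranges")
  }
  keys <- union(names(a), names(b))
  av <- as.numeric(a[keys]); av[is.na(av)] <- 0
  bv <- as.numeric(b[keys]); bv[is.na(bv)] <- 0
  dot <- sum(av * bv)
  if (dot == 0) return(0)
  min(1, dot / sqrt(sum(av^2) * sum(bv^2)))
}

#' Attach corpus-observed misspellings to lexicon seed terms
#'
#' For every distinct normalized vocabulary word, computes the combined
#' character n-gram cosine similarity against each eligible seed term and
#' attaches the word to a seed when the similarity clears that seed's
#' threshold. A word clearing several thresholds goes to the highest-similarity
#' seed (ties broken by lexicographically first seed). Words that are
#' themselves seed or medical terms are never attached. Seeds shorter than
#' `min_seed_nchar` characters are skipped: n-gram cosine on very short tokens
#' (mj, thc, cbd) accepts too many unrelated words.
#'
#' @param vocabulary Character vector of corpus word tokens (normalized
#'   internally; duplicates and empties dropped).
#' @param lexicon A [build_lexicon()] object supplying seeds and thresholds.
#' @param n_min,n_max Gram-length range (default 1-3).
#' @param min_seed_nchar Minimum seed length eligible for expansion
#'   (default 4); set to 1 to expand every seed.
#' @return Named list mapping seed term -> character vector of accepted
#'   variants, with a `similarities` attribute (named numeric vector,
#'   names `"seed:variant"`). Seeds with no variants are omitted.
#' @export
expand_misspellings <- function(vocabulary, lexicon, n_min = 1L, n_max = 3L,
                                min_seed_nchar = 4L) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  vocab <- unique(vapply(as.character(vocabulary), normalize_token, ""))
  vocab <- vocab[nchar(vocab) > 0L]
  known <- c(lexicon$seed_terms, lexicon$medical_terms)
  vocab <- setdiff(vocab, known)
  seeds <- lexicon$seed_terms[nchar(lexicon$seed_terms) >= min_seed_nchar]
  out <- stats::setNames(vector("list", length(seeds)), seeds)
  sims <- numeric(0)
  if (length(vocab) && length(seeds)) {
    seed_prof <- lapply(seeds, char_ngram_profile, n_min = n_min, n_max = n_max)
    for (w in vocab) {
      wp <- char_ngram_profile(w, n_min = n_min, n_max = n_max)
      s <- vapply(seed_prof, ngram_cosine, 0, b = wp)
      thr <- unlist(lexicon$thresholds[seeds])
      ok <- which(s >= thr)
      if (length(ok)) {
        # max similarity wins; ties to lexicographically first seed
        best <- ok[order(-s[ok], seeds[ok])][1L]
        out[[seeds[best]]] <- c(out[[seeds[best]]], w)
        sims[paste0(seeds[best], ":", w)] <- s[best]
      }
    }
  }
  out <- Filter(function(x) length(x) > 0, out)
  out <- lapply(out, sort)
  attr(out, "similarities") <- sims
  out
}
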