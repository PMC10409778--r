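# Lexicon construction, validation and (de)serialization.

# Default seed keywords and medically prescribed cannabinoid terms.
# Ambiguous seeds (cbd, weed) get context-exclusion keyword sets in
# default_exclusions().
.default_seeds <- c("marijuana", "cannabis", "cbd", "weed", "thc", "mj")
.default_medical <- c("tetrahydrocannabinol", "epidiolex", "cannabidiol",
                      "marinol", "dronabinol", "syndros", "cesamet")

.default_exclusions <- function() {
  list(
    bile_duct = c("abdominal", "gallbladder", "pancreas", "common bile duct",
                  "biliary", "cholecystitis", "cholangiogram"),
    allergy = c("pollen", "allergy", "allergies", "allergic", "allergen",
                "allergens")
  )
}

#' Build a validated cannabis-term lexicon
#'
#' Assembles the dictionary the screening stage matches against: seed keywords,
#' medical (prescription cannabinoid) terms, per-seed misspelling-similarity
#' thresholds, accepted misspellings, and the context-exclusion keyword sets
#' used to discard notes where an ambiguous term refers to a non-cannabis
#' concept (CBD as common bile duct, weed as plant/allergen).
#'
#' @param config Optional configuration: a named list, or a path to a
#'   YAML/JSON file with any of the keys `seeds`, `medical_terms`,
#'   `thresholds` (named, per-seed), `misspellings` (named list seed ->
#'   variants), `exclusions` (named list of keyword vectors, typically
#'   `bile_duct` and `allergy`), `default_threshold`.
#' @param default_threshold Similarity threshold applied to seeds without an
#'   explicit entry; default 0.70.
#' @return Object of class `cannabis_lexicon`: list with elements
#'   `seed_terms`, `medical_terms`, `misspellings`, `thresholds`,
#'   `exclusion_sets`.
#' @examples
#' lex <- build_lexicon()
#' lex$thresholds$marijuana  # 0.7
#' @export
build_lexicon <- function(config = NULL, default_threshold = 0.70) {
  cfg <- list()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("lexicon config not found: ", config)
    cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    cfg <- config
  } else if (!is.null(config)) {
    stop("config must be NULL, a named list, or a file path")
  }

  if (!is.null(cfg$default_threshold)) default_threshold <- cfg$default_threshold
  norm <- function(x) unique(vapply(as.character(x), normalize_token, "",
                                    USE.NAMES = FALSE))
  seeds <- norm(c(.default_seeds, cfg$seeds))
  medical <- norm(c(.default_medical, cfg$medical_terms))
  medical <- setdiff(medical, seeds)
  if (!length(seeds)) stop("lexicon must contain at least one seed term")
  if (anyDuplicated(c(seeds, medical))) {
    stop("duplicate terms across seed and medical lists")
  }

  thresholds <- stats::setNames(as.list(rep(default_threshold, length(seeds))),
                                seeds)
  for (nm in names(cfg$thresholds)) {
    key <- normalize_token(nm)
    if (!key %in% seeds) stop("threshold for unknown seed: ", nm)
    thresholds[[key]] <- cfg$thresholds[[nm]]
  }
  thr <- unlist(thresholds)
  if (any(thr <= 0 | thr > 1)) {
    stop("thresholds must lie in (0, 1]: ",
         paste(names(thr)[thr <= 0 | thr > 1], collapse = ", "))
  }

  misspellings <- list()
  for (nm in names(cfg$misspellings)) {
    key <- normalize_token(nm)
    if (!key %in% seeds) stop("misspellings for unknown seed: ", nm)
    misspellings[[key]] <- norm(cfg$misspellings[[nm]])
  }
  all_vars <- unlist(misspellings, use.names = FALSE)
  if (anyDuplicated(all_vars)) {
    stop("a misspelling may map to only one seed: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  }

  exclusions <- .default_exclusions()
  for (nm in names(cfg$exclusions)) {
    exclusions[[nm]] <- tolower(as.character(cfg$exclusions[[nm]]))
  }

  structure(
    list(seed_terms = sort(seeds),
         medical_terms = sort(medical),
         misspellings = misspellings,
         thresholds = thresholds,
         exclusion_sets = exclusions),
    class = "cannabis_lexicon"
  )
}

#' Add expansion output to a lexicon
#'
#' Merges the variant map returned by [expand_misspellings()] into the
#' lexicon's accepted-misspelling table.
#'
#' @param lexicon `cannabis_lexicon`.
#' @param variants Named list seed -> character vector, as returned by
#'   [expand_misspellings()].
#' @return Updated `cannabis_lexicon`.
#' @export
add_misspellings <- function(lexicon, variants) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  for (seed in names(variants)) {
    if (!seed %in% lexicon$seed_terms) stop("unknown seed: ", seed)
    lexicon$misspellings[[seed]] <-
      sort(unique(c(lexicon$misspellings[[seed]], variants[[seed]])))
  }
  lexicon
}

#' All terms the screening stage matches, with their canonical seed
#'
#' @param lexicon `cannabis_lexicon`.
#' @return Data frame with columns `term`, `canonical_seed`, `kind`
#'   (seed / medical / misspelling). Medical terms are their own canonical
#'   seed.
#' @export
lexicon_terms <- function(lexicon) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  rows <- list(
    data.frame(term = lexicon$seed_terms,
               canonical_seed = lexicon$seed_terms,
               kind = "seed", stringsAsFactors = FALSE),
    data.frame(term = lexicon$medical_terms,
               canonical_seed = lexicon$medical_terms,
               kind = "medical", stringsAsFactors = FALSE)
  )
  for (seed in names(lexicon$misspellings)) {
    v <- lexicon$misspellings[[seed]]
    if (length(v)) {
      rows <- c(rows, list(data.frame(term = v, canonical_seed = seed,
                                      kind = "misspelling",
                                      stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  out[order(-nchar(out$term), out$term), , drop = FALSE]
}

#' Write / read a lexicon as JSON
#'
#' Round-trips losslessly: `read_lexicon(write_lexicon(lex, f))` reproduces
#' `lex`.
#'
#' @param lexicon `cannabis_lexicon`.
#' @param path Output / input file path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` returns a
#'   `cannabis_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "cannabis_lexicon"))
  jsonlite::write_json(unclass(lexicon), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lex <- build_lexicon(list(
    seeds = raw$seed_terms, medical_terms = raw$medical_terms,
    thresholds = raw$thresholds, misspellings = raw$misspellings,
    exclusions = raw$exclusion_sets))
  lex
}

#' @export
print.cannabis_lexicon <- function(x, ...) {
  cat("<cannabis_lexicon>\n")
  cat("  seeds:   ", paste(x$seed_terms, collapse = ", "), "\n")
  cat("  medical: ", paste(x$medical_terms, collapse = ", "), "\n")
  n_mis <- sum(lengths(x$misspellings))
  cat("  accepted misspellings:", n_mis, "\n")
  invisible(x)
}
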