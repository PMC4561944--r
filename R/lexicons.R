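# Custom dictionaries: disease terms, abbreviations, medication generic
# names with heart-disease-related categories, smoking terms, section
# headings, family-relation terms, and a misspelling map.

#' The legal medication categories
#'
#' The enumerated heart-disease-related medication categories; every
#' medication dictionary entry must map to one of these.
#' @return Character vector of category names.
#' @export
medication_categories <- function() {
  leg <- legal_indicator_table()
  leg$indicator[leg$risk_factor == "MEDICATION"]
}

#' The eight risk factors
#' @return Character vector.
#' @export
risk_factors <- function() {
  c("CAD", "DIABETES", "FAMILY_HIST", "HYPERLIPIDEMIA", "HYPERTENSION",
    "MEDICATION", "OBESITY", "SMOKER")
}

.read_map <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L)
    return(stats::setNames(character(), character()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- keep[which(nfield != 2L)[1L]]
    stop(sprintf("malformed lexicon line %d in %s: expected 2 tab-separated fields, got %d",
                 bad, basename(path), nfield[which(nfield != 2L)[1L]]), call. = FALSE)
  }
  keys <- norm_term(vapply(parts, `[[`, "", 1L))
  vals <- trimws(vapply(parts, `[[`, "", 2L))
  stats::setNames(vals, keys)
}

.read_set <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  unique(norm_term(lines))
}

# lower-case + collapse internal whitespace
norm_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Load the lexicon set
#'
#' Reads the seven dictionary files the pipeline uses. Map files are
#' two-column TSV (`term<TAB>value`), set files one term per line; `#`
#' starts a comment. Keys are lower-cased and whitespace-normalized.
#'
#' @param dir Directory holding the lexicon files; defaults to the curated
#'   starter lexicons shipped with the package.
#' @param verbose Log entry counts per file.
#' @return An object of class `lexicon_set` with elements `disease_terms`,
#'   `abbreviations`, `medications`, `smoking_terms`, `section_headings`,
#'   `relation_terms`, `misspellings`, `cad_events`.
#' @export
load_lexicons <- function(dir = system.file("extdata", "lexicons", package = "cardionlp"),
                          verbose = FALSE) {
  files <- c(disease_terms = "disease_terms.tsv",
             abbreviations = "abbreviations.tsv",
             medications = "medications.tsv",
             misspellings = "misspellings.tsv",
             cad_events = "cad_events.tsv",
             smoking_terms = "smoking_terms.txt",
             section_headings = "section_headings.txt",
             relation_terms = "relation_terms.txt")
  paths <- stats::setNames(file.path(dir, files), names(files))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing lexicon file(s): ",
         paste(files[missing], collapse = ", "), " in ", dir, call. = FALSE)
  }
  lex <- list(
    disease_terms = .read_map(paths[["disease_terms"]]),
    abbreviations = .read_map(paths[["abbreviations"]]),
    medications = .read_map(paths[["medications"]]),
    misspellings = .read_map(paths[["misspellings"]]),
    cad_events = .read_map(paths[["cad_events"]]),
    smoking_terms = .read_set(paths[["smoking_terms"]]),
    section_headings = .read_set(paths[["section_headings"]]),
    relation_terms = .read_set(paths[["relation_terms"]])
  )
  bad_cat <- setdiff(unique(lex$medications), medication_categories())
  if (length(bad_cat) > 0L) {
    stop("medication lexicon contains unknown categories: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  # abbreviation map must be acyclic: an expansion is never itself a key
  cyc <- intersect(norm_term(unname(lex$abbreviations)), names(lex$abbreviations))
  if (length(cyc) > 0L) {
    stop("abbreviation map is cyclic through: ", paste(cyc, collapse = ", "),
         call. = FALSE)
  }
  if (verbose) {
    counts <- vapply(lex, length, integer(1L))
    message("loaded lexicons: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  structure(lex, class = "lexicon_set")
}

#' @export
print.lexicon_set <- function(x, ...) {
  counts <- vapply(unclass(x), length, integer(1L))
  cat("<lexicon_set>\n")
  for (nm in names(counts)) cat(sprintf("  %-17s %d entries\n", nm, counts[[nm]]))
  invisible(x)
}

#' Expand a known abbreviation
#'
#' Exact, case-insensitive lookup in the abbreviation dictionary; unknown
#' terms pass through unchanged. Idempotent (the map is acyclic and no
#' expansion is itself a short form).
#'
#' @param term Character vector of terms.
#' @param lex A [load_lexicons()] result.
#' @return Character vector of the same length.
#' @export
expand_abbreviation <- function(term, lex) {
  key <- norm_term(term)
  hit <- lex$abbreviations[key]
  out <- ifelse(is.na(hit), term, unname(hit))
  unname(out)
}

#' Correct a known misspelling
#'
#' Exact map lookup only; there is no fuzzy edit-distance matching.
#'
#' @inheritParams expand_abbreviation
#' @param token Character vector of tokens.
#' @return Character vector of the same length.
#' @export
correct_misspelling <- function(token, lex) {
  key <- norm_term(token)
  hit <- lex$misspellings[key]
  unname(ifelse(is.na(hit), token, unname(hit)))
}

#' Look up a medication inside a phrase
#'
#' Abbreviations are expanded and misspellings corrected token-wise, then
#' the longest case-insensitive dictionary match within the normalized
#' phrase wins.
#'
#' @param phrase A string (e.g. one noun-phrase chunk or sentence).
#' @param lex A [load_lexicons()] result.
#' @return A list `list(generic = ..., category = ...)`, or `NULL` when no
#'   dictionary medication occurs in the phrase.
#' @export
lookup_medication <- function(phrase, lex) {
  toks <- strsplit(norm_term(phrase), " ", fixed = TRUE)[[1L]]
  if (length(toks) == 0L) return(NULL)
  toks <- norm_term(correct_misspelling(expand_abbreviation(toks, lex), lex))
  normalized <- paste(toks, collapse = " ")
  best <- NULL
  for (name in names(lex$medications)) {
    if (grepl(paste0("\\b", .rx_escape(name), "\\b"), normalized, perl = TRUE)) {
      if (is.null(best) || nchar(name) > nchar(best)) best <- name
    }
  }
  if (is.null(best)) return(NULL)
  list(generic = best, category = unname(lex$medications[[best]]))
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
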