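# Lexicon-driven recognition of disease-disorder, CAD clinical-phrase, and
# medication mentions over tokenized sentences.

# Generic n-gram dictionary matcher. For each token n-gram (n = 1..max_n)
# it tries the raw normalized text, the misspelling-corrected form, and the
# abbreviation-expanded form (in that order of preference) against `dict`
# (a named vector keyed by normalized term). Returns candidate matches with
# token extents; overlaps collapse to the longest match.
.match_ngrams <- function(tokens, lex, dict, max_n = 4L) {
  n_tok <- nrow(tokens)
  empty <- data.frame(start = integer(), end = integer(),
                      matched_term = character(), key = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (n_tok == 0L) return(empty)
  word <- grepl("^[A-Za-z0-9]", tokens$text)
  cand <- list()
  for (i in seq_len(n_tok)) {
    if (!word[i]) next
    for (n in seq_len(min(max_n, n_tok - i + 1L))) {
      j <- i + n - 1L
      if (!all(word[i:j])) break
      raw <- norm_term(paste(tokens$text[i:j], collapse = " "))
      corrected <- norm_term(paste(correct_misspelling(tokens$text[i:j], lex),
                                   collapse = " "))
      expanded <- norm_term(expand_abbreviation(raw, lex))
      expanded_corr <- norm_term(expand_abbreviation(corrected, lex))
      forms <- c(raw, corrected, expanded, expanded_corr)
      srcs <- c("dictionary", "dictionary", "abbreviation", "abbreviation")
      hit <- which(forms %in% names(dict))[1L]
      if (!is.na(hit)) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = tokens$start[i], end = tokens$end[j],
          matched_term = NA_character_, key = forms[hit], source = srcs[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  # longest match wins; overlapping shorter matches are dropped
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  occ <- list()
  for (k in seq_len(nrow(cand))) {
    ov <- vapply(occ, function(iv) cand$start[k] < iv[2L] && cand$end[k] > iv[1L],
                 logical(1L))
    if (!any(ov)) {
      keep[k] <- TRUE
      occ[[length(occ) + 1L]] <- c(cand$start[k], cand$end[k])
    }
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Recognize disease-disorder mentions
#'
#' Matches the disease lexicon (and abbreviation/misspelling variants) over
#' each sentence's tokens; terms that do not map to one of the five
#' disease risk factors (CAD, diabetes, hyperlipidemia, hypertension,
#' obesity) never enter the lexicon, so irrelevant disorders are filtered
#' by construction. Negated mentions are not suppressed.
#'
#' @param doc A [clinical_document()].
#' @param lex A [load_lexicons()] result.
#' @param sentences Optional precomputed [split_sentences()] output.
#' @return data.frame with columns `risk_factor`, `start`, `end`,
#'   `matched_term` (the document slice at the span), `source`
#'   ("dictionary" or "abbreviation"), `sentence_index`.
#' @export
recognize_diseases <- function(doc, lex, sentences = split_sentences(doc$text)) {
  .recognize_with(doc, lex, sentences, lex$disease_terms, "risk_factor")
}

#' Recognize CAD clinical phrases (events, test results, symptoms)
#'
#' Matches the starter lexicon of CAD-related clinical events
#' ("myocardial infarction", "angioplasty"), test results ("stress test"),
#' and symptoms ("chest pain"); each hit carries the CAD indicator class
#' it maps to. This is the known-weak component: the starter lexicon is
#' small and real notes express these concepts in many more ways.
#'
#' @inheritParams recognize_diseases
#' @return data.frame like [recognize_diseases()] plus an `indicator`
#'   column (event / test result / symptom); `risk_factor` is "CAD".
#' @export
recognize_cad_events <- function(doc, lex, sentences = split_sentences(doc$text)) {
  out <- .recognize_with(doc, lex, sentences, lex$cad_events, "indicator")
  out$risk_factor <- rep("CAD", nrow(out))
  out[, c("risk_factor", "indicator", "start", "end", "matched_term",
          "source", "sentence_index")]
}

.recognize_with <- function(doc, lex, sentences, dict, value_col) {
  rows <- list()
  for (s in seq_len(nrow(sentences))) {
    toks <- tokenize(sentences$text[s], sentences$start[s])
    m <- .match_ngrams(toks, lex, dict)
    if (nrow(m) == 0L) next
    m[[value_col]] <- unname(dict[m$key])
    m$sentence_index <- sentences$index[s]
    rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) == 0L) {
    empty <- data.frame(v = character(), start = integer(), end = integer(),
                        matched_term = character(), source = character(),
                        sentence_index = integer(), stringsAsFactors = FALSE)
    names(empty)[1L] <- value_col
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$matched_term <- text_slice(doc$text, out$start, out$end)
  out[, c(value_col, "start", "end", "matched_term", "source", "sentence_index")]
}

#' Recognize medication mentions
#'
#' Dictionary lookup of medication generic names (with abbreviation
#' expansion, e.g. ASA, and misspelling correction, e.g. "pravastain")
#' over sentence tokens; each hit carries its heart-disease-related
#' category.
#'
#' @inheritParams recognize_diseases
#' @return data.frame with columns `generic_name`, `category`, `start`,
#'   `end`, `matched_term`, `sentence_index`.
#' @export
recognize_medications <- function(doc, lex, sentences = split_sentences(doc$text)) {
  rows <- list()
  for (s in seq_len(nrow(sentences))) {
    toks <- tokenize(sentences$text[s], sentences$start[s])
    m <- .match_ngrams(toks, lex, lex$medications)
    if (nrow(m) == 0L) next
    m$generic_name <- m$key
    m$category <- unname(lex$medications[m$key])
    m$sentence_index <- sentences$index[s]
    rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) == 0L) {
    return(data.frame(generic_name = character(), category = character(),
                      start = integer(), end = integer(),
                      matched_term = character(), sentence_index = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$matched_term <- text_slice(doc$text, out$start, out$end)
  out[, c("generic_name", "category", "start", "end", "matched_term",
          "sentence_index")]
}
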