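# Document-level classifiers: smoking status (Naive Bayes over smoking
# sentences plus selection rules) and the rule-based family-history-of-
# premature-CAD classifier.

.smoking_classes <- c("current", "past", "never")

#' Find sentences mentioning smoking
#'
#' A sentence qualifies when it contains any term from the smoking-term
#' dictionary (smoker, tobacco, packs per year, ...), case-insensitively
#' with word-boundary anchoring.
#'
#' @param doc A [clinical_document()].
#' @param lex A [load_lexicons()] result.
#' @param sentences Optional precomputed [split_sentences()] output.
#' @return The subset of `sentences` that mention smoking.
#' @export
find_smoking_sentences <- function(doc, lex, sentences = split_sentences(doc$text)) {
  if (nrow(sentences) == 0L) return(sentences)
  pat <- paste0("\\b(?:", paste(.rx_escape(lex$smoking_terms), collapse = "|"),
                ")\\b")
  hit <- grepl(pat, norm_term(sentences$text), perl = TRUE)
  sentences[hit, , drop = FALSE]
}

# bag of words + POS tags, the smoking feature template
.smoking_bag <- function(text) {
  toks <- pos_tag(tokenize(text))
  toks <- toks[grepl("^[A-Za-z0-9]", toks$text), , drop = FALSE]
  c(tolower(toks$text), paste0("POS=", toks$pos))
}

#' Train the smoking-status sentence classifier
#'
#' Multinomial Naive Bayes with additive smoothing over bag-of-words and
#' POS-tag features; classes are "current", "past", "never" (the rare
#' "ever" class is dropped from the problem entirely).
#'
#' @param texts Character vector of smoking sentences.
#' @param labels Parallel vector of classes (current/past/never); each
#'   class must be represented.
#' @param seed Seed recorded in the model (training is deterministic).
#' @param alpha Smoothing pseudo-count.
#' @param min_count Drop features rarer than this across the corpus.
#' @return An `nb_model` (with `$kind = "smoking"`).
#' @export
train_smoking_nb <- function(texts, labels, seed = 0L, alpha = 1, min_count = 1L) {
  if (length(texts) == 0L) stop("empty smoking training corpus", call. = FALSE)
  bad <- !labels %in% .smoking_classes
  if (any(bad)) stop("illegal smoking class(es): ",
                     paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  bags <- lapply(texts, .smoking_bag)
  model <- nb_train(bags, labels, classes = .smoking_classes,
                    alpha = alpha, min_count = min_count, seed = seed)
  model$kind <- "smoking"
  model
}

#' Classify one smoking sentence
#' @param text Sentence text.
#' @param model A [train_smoking_nb()] model.
#' @return One of "current", "past", "never" (ties break in that order).
#' @export
classify_smoking_sentence <- function(text, model) {
  nb_predict(model, .smoking_bag(text))
}

#' Resolve a document's smoking status from its sentence classes
#'
#' No smoking sentences means "unknown"; otherwise the priority rule
#' current > past > never selects among the per-sentence classes (a
#' current-smoker statement dominates on clinical recency grounds).
#'
#' @param sentence_classes Character vector of per-sentence classes.
#' @return One of "current", "past", "never", "unknown".
#' @export
resolve_document_smoking <- function(sentence_classes) {
  if (length(sentence_classes) == 0L) return("unknown")
  for (cls in .smoking_classes) {
    if (cls %in% sentence_classes) return(cls)
  }
  "unknown"
}

#' Classify a document's smoking status end-to-end
#' @inheritParams find_smoking_sentences
#' @param model A [train_smoking_nb()] model.
#' @return One of "current", "past", "never", "unknown".
#' @export
classify_document_smoking <- function(doc, model, lex,
                                      sentences = split_sentences(doc$text)) {
  sm <- find_smoking_sentences(doc, lex, sentences)
  resolve_document_smoking(
    vapply(sm$text, classify_smoking_sentence, character(1L),
           model = model, USE.NAMES = FALSE))
}

# first parseable age in a sentence, NA when none
.extract_age <- function(text) {
  lo <- tolower(text)
  pats <- c("at\\s+age\\s+([0-9]{1,3})",
            "aged?\\s+(?:of\\s+)?([0-9]{1,3})",
            "at\\s+([0-9]{1,3})\\b",
            "died[^0-9]{0,20}([0-9]{1,3})\\b")
  for (p in pats) {
    m <- regexpr(p, lo, perl = TRUE)
    if (m > 0L) {
      cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
      return(as.numeric(substring(lo, cs[1L], cs[1L] + cl[1L] - 1L)))
    }
  }
  NA_real_
}

#' Classify family history of premature CAD
#'
#' Rule-based: a document is "present" iff some sentence contains a CAD
#' term, a first-degree-relation term, and a parseable age below the
#' premature-age threshold; otherwise "not present". The threshold
#' defaults to 55 years and is configurable (45 is the other published
#' convention). Sentences with a CAD+relation co-occurrence but no
#' parseable age are treated as not premature.
#'
#' @inheritParams find_smoking_sentences
#' @param age_threshold Premature-death age cutoff in years (strict `<`).
#' @param cad_terms Terms counting as CAD mentions in this rule.
#' @return "present" or "not present".
#' @export
classify_family_history <- function(doc, lex,
                                    sentences = split_sentences(doc$text),
                                    age_threshold = 55,
                                    cad_terms = c("cad", "coronary artery disease")) {
  if (nrow(sentences) == 0L) return("not present")
  cad_pat <- paste0("\\b(?:", paste(.rx_escape(cad_terms), collapse = "|"), ")\\b")
  rel_pat <- paste0("\\b(?:", paste(.rx_escape(lex$relation_terms), collapse = "|"),
                    ")s?\\b")
  for (i in seq_len(nrow(sentences))) {
    lo <- norm_term(sentences$text[i])
    if (!grepl(cad_pat, lo, perl = TRUE)) next
    if (!grepl(rel_pat, lo, perl = TRUE)) next
    age <- .extract_age(sentences$text[i])
    if (!is.na(age) && age < age_threshold) return("present")
  }
  "not present"
}
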