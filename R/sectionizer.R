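# CRF sentence sectionizer: labels each sentence as a section heading, a
# heading with trailing text, or body text, and propagates the prevailing
# section name forward. Section context is both a risk-factor cue and a
# feature for time-attribute assignment.

.section_labels <- c("SECTION_HEADING", "SECTION_HEADING_WITH_TEXT", "TEXT")

.words_of <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  regmatches(text, gregexpr("[A-Za-z][A-Za-z0-9]*", text))[[1L]]
}

#' Compute the sectionizer feature vector for one sentence
#'
#' The local feature template: first word uppercased, all words uppercased,
#' all words lowercased, heading-dictionary match, first word, second word,
#' the neighbors' local features, sentence-final full stop, and colon
#' presence. Neighbor features are the neighbor's own local features
#' (non-recursive).
#'
#' @param text Sentence text.
#' @param prev_text,next_text Neighbor sentence texts (`NA` at the
#'   boundaries).
#' @param lex A [load_lexicons()] result (for the heading dictionary).
#' @return Named list of local features plus `prev` and `next` sublists.
#' @export
featurize_sentence <- function(text, prev_text = NA, next_text = NA, lex) {
  f <- .local_section_features(text, lex)
  f$prev <- if (is.na(prev_text)) NULL else .local_section_features(prev_text, lex)
  f$nxt <- if (is.na(next_text)) NULL else .local_section_features(next_text, lex)
  f
}

.local_section_features <- function(text, lex) {
  w <- .words_of(text)
  has_words <- length(w) > 0L
  list(
    first_word_uppercased = has_words && grepl("^[A-Z]", w[1L]),
    all_words_uppercased = has_words && all(w == toupper(w)),
    all_words_lowercased = has_words && all(w == tolower(w)),
    dictionary_match = has_words && .heading_dict_match(text, lex),
    first_word = if (has_words) tolower(w[1L]) else "",
    second_word = if (length(w) > 1L) tolower(w[2L]) else "",
    ends_full_stop = !is.na(text) && grepl("\\.\\s*$", text),
    contains_colon = !is.na(text) && grepl(":", text, fixed = TRUE)
  )
}

.heading_dict_match <- function(text, lex) {
  lo <- norm_term(text)
  any(vapply(lex$section_headings,
             function(h) grepl(paste0("\\b", .rx_escape(h), "\\b"), lo, perl = TRUE),
             logical(1L)))
}

# flatten a feature vector into CRF indicator-feature strings
.section_feature_strings <- function(f, prefix = "") {
  out <- character()
  bool_feats <- c("first_word_uppercased", "all_words_uppercased",
                  "all_words_lowercased", "dictionary_match",
                  "ends_full_stop", "contains_colon")
  for (b in bool_feats) if (isTRUE(f[[b]])) out <- c(out, paste0(prefix, b))
  out <- c(out, paste0(prefix, "first=", f$first_word),
           paste0(prefix, "second=", f$second_word))
  if (!is.null(f$prev)) out <- c(out, .section_feature_strings(f$prev, "p."))
  if (!is.null(f$nxt)) out <- c(out, .section_feature_strings(f$nxt, "n."))
  out
}

.sectionizer_sequence <- function(sent_texts, lex) {
  n <- length(sent_texts)
  lapply(seq_len(n), function(i) {
    f <- featurize_sentence(sent_texts[i],
                            if (i > 1L) sent_texts[i - 1L] else NA,
                            if (i < n) sent_texts[i + 1L] else NA, lex)
    .section_feature_strings(f)
  })
}

#' Train the sectionizer CRF
#'
#' Fits a linear-chain CRF over each document's sentence sequence with the
#' three classes SECTION_HEADING, SECTION_HEADING_WITH_TEXT, TEXT.
#'
#' @param docs List of training documents; each element is a list with
#'   `texts` (character vector of sentence texts in order) and `labels`
#'   (parallel character vector from the three classes).
#' @param lex A [load_lexicons()] result.
#' @param seed Seed recorded in the model (training is deterministic).
#' @param lambda,maxit CRF regularization and optimizer budget.
#' @return A `crf_model` (with `$kind = "sectionizer"`).
#' @export
train_sectionizer <- function(docs, lex, seed = 0L, lambda = 0.1, maxit = 150L) {
  if (length(docs) == 0L) stop("empty training corpus", call. = FALSE)
  x <- lapply(docs, function(d) .sectionizer_sequence(d$texts, lex))
  y <- lapply(docs, function(d) d$labels)
  bad <- !unlist(y) %in% .section_labels
  if (any(bad)) stop("unknown section label(s): ",
                     paste(unique(unlist(y)[bad]), collapse = ", "), call. = FALSE)
  model <- crf_train(x, y, labels = .section_labels,
                     lambda = lambda, maxit = maxit, seed = seed)
  model$kind <- "sectionizer"
  model
}

#' Extract the section name from a heading sentence
#'
#' The text before the first colon, lower-cased and trimmed; a heading
#' without a colon yields the whole lower-cased sentence (with a warning,
#' since the rule expects a colon).
#'
#' @param text Sentence text.
#' @param warn Warn when no colon is present.
#' @return Lower-cased section name.
#' @export
extract_section_name <- function(text, warn = TRUE) {
  if (grepl(":", text, fixed = TRUE)) {
    norm_term(sub(":.*$", "", text))
  } else {
    if (warn) warning("heading sentence has no colon: ", text, call. = FALSE)
    norm_term(text)
  }
}

#' Apply the heading-dictionary override
#'
#' A sentence classified as TEXT that contains a term from the section
#' headings dictionary is relabeled SECTION_HEADING; nothing else changes.
#' Idempotent.
#'
#' @param sectioned data.frame with at least `text` and `label` columns.
#' @param lex A [load_lexicons()] result.
#' @return The data.frame with corrected labels.
#' @export
apply_heading_override <- function(sectioned, lex) {
  if (nrow(sectioned) == 0L) return(sectioned)
  is_text <- sectioned$label == "TEXT"
  hit <- vapply(sectioned$text, .heading_dict_match, logical(1L),
                lex = lex, USE.NAMES = FALSE)
  sectioned$label[is_text & hit] <- "SECTION_HEADING"
  sectioned
}

#' Classify a document's sentences into section classes
#'
#' Viterbi-decodes the sentence sequence, applies the heading-dictionary
#' override, and propagates the prevailing section name forward from the
#' most recent heading.
#'
#' @param doc A [clinical_document()].
#' @param model A [train_sectionizer()] model.
#' @param lex A [load_lexicons()] result.
#' @param sentences Optional precomputed [split_sentences()] output.
#' @return data.frame with columns `index`, `start`, `end`, `text`,
#'   `label`, `section_name` (NA before the first heading).
#' @export
classify_sections <- function(doc, model, lex,
                              sentences = split_sentences(doc$text)) {
  out <- sentences
  if (nrow(out) == 0L) {
    out$label <- character(); out$section_name <- character()
    return(out)
  }
  x <- .sectionizer_sequence(out$text, lex)
  out$label <- crf_predict(model, x)
  out <- apply_heading_override(out, lex)
  sec <- NA_character_
  out$section_name <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (out$label[i] %in% c("SECTION_HEADING", "SECTION_HEADING_WITH_TEXT")) {
      sec <- extract_section_name(out$text[i], warn = FALSE)
    }
    out$section_name[i] <- sec
  }
  out
}
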