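# Time-attribute assignment: a Naive Bayes classifier over phrase-context
# features places each recognized risk factor before, during, or after the
# document creation time; the "continuing" class expands to all three.

.time_classes <- c("before DCT", "during DCT", "after DCT", "continuing")

# section headings whose medications always hold across the whole timeline
.medication_sections <- c("medications", "current medications",
                          "medications on admission", "discharge medications")

#' Build the time-attribute feature vector for one phrase
#'
#' The feature template: the identified risk-factor span tokens, previous
#' word and its POS tag, next word and its POS tag, section information,
#' and the indicator attribute. Missing neighbors are encoded with a
#' sentinel.
#'
#' @param span_tokens Character vector: the tokens of the recognized
#'   phrase.
#' @param prev_word,next_word Neighboring words (NA at boundaries).
#' @param prev_pos,next_pos Their POS tags (NA at boundaries).
#' @param section_name Prevailing section name (NA before any heading).
#' @param indicator The phrase's indicator attribute.
#' @return Character vector of feature tokens (a Naive Bayes bag).
#' @export
featurize_time <- function(span_tokens, prev_word = NA, prev_pos = NA,
                           next_word = NA, next_pos = NA,
                           section_name = NA, indicator = "") {
  sent <- function(x) if (is.na(x) || !nzchar(x)) "<none>" else tolower(x)
  c(paste0("w=", tolower(span_tokens)),
    paste0("pw=", sent(prev_word)),
    paste0("ppos=", if (is.na(prev_pos)) "<none>" else prev_pos),
    paste0("nw=", sent(next_word)),
    paste0("npos=", if (is.na(next_pos)) "<none>" else next_pos),
    paste0("sec=", sent(section_name)),
    paste0("ind=", tolower(indicator)))
}

#' Train the time-attribute classifier
#'
#' Multinomial Naive Bayes over [featurize_time()] bags with the four
#' classes before DCT, during DCT, after DCT, and continuing (fixed order,
#' which is also the prediction tie-break order).
#'
#' @param bags List of feature bags from [featurize_time()].
#' @param labels Parallel class labels; all four classes must appear.
#' @param seed Seed recorded in the model (training is deterministic).
#' @param alpha Smoothing pseudo-count.
#' @return An `nb_model` (with `$kind = "time"`).
#' @export
train_time_nb <- function(bags, labels, seed = 0L, alpha = 1) {
  if (length(bags) == 0L) stop("empty time-attribute training corpus", call. = FALSE)
  bad <- !labels %in% .time_classes
  if (any(bad)) stop("illegal time class(es): ",
                     paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
  model <- nb_train(bags, labels, classes = .time_classes,
                    alpha = alpha, seed = seed)
  model$kind <- "time"
  model
}

#' Classify a phrase's time class
#' @param features Feature bag from [featurize_time()].
#' @param model A [train_time_nb()] model.
#' @return One of "before DCT", "during DCT", "after DCT", "continuing".
#' @export
classify_time <- function(features, model) {
  nb_predict(model, features)
}

#' Expand the continuing class to the three time attributes
#'
#' "continuing" becomes {before DCT, during DCT, after DCT}; any other
#' class is its own singleton set.
#'
#' @param time_class A time class string.
#' @return Character vector of 1 or 3 time attributes.
#' @export
expand_continuing <- function(time_class) {
  stopifnot(length(time_class) == 1L, time_class %in% .time_classes)
  if (time_class == "continuing") time_attributes() else time_class
}

#' Hard section rule for medication time attributes
#'
#' Medications listed under a medication section heading ("medications",
#' "medications on admission", ...) always hold before, during, and after
#' the DCT; this deterministic rule overrides the classifier.
#'
#' @param risk_factor Risk factor of the phrase.
#' @param section_name Prevailing section name (NA allowed).
#' @return TRUE when the override applies.
#' @export
medication_section_override <- function(risk_factor, section_name) {
  !is.na(section_name) && risk_factor == "MEDICATION" &&
    norm_term(section_name) %in% .medication_sections
}
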