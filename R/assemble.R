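# Wires recognizers, rule ledger, sectionizer, and classifiers into
# document-level risk-factor annotations.

#' Assign the indicator attribute for a recognized item
#'
#' Looks the item's provenance up in the declarative rule ledger: disease
#' dictionary hits get "mention", thresholded lab values their lab
#' indicator, medication hits their category, CAD clinical phrases their
#' phrase class.
#'
#' @param source Provenance: "disease", "cad_event", "lab", or
#'   "medication".
#' @param key Rule key: the risk factor (disease), lab kind, medication
#'   category, or CAD phrase class.
#' @return list(risk_factor =, indicator =).
#' @export
assign_indicator <- function(source, key) {
  rules <- indicator_rules()
  hit <- which(rules$source == source & rules$key == key)
  if (length(hit) == 0L) {
    stop(sprintf("no indicator rule for item of provenance '%s' with key '%s'",
                 source, key), call. = FALSE)
  }
  list(risk_factor = rules$risk_factor[hit[1L]],
       indicator = rules$indicator[hit[1L]])
}

# time-attribute features for an item occupying [start,end) in a sentence
.item_time_features <- function(item_start, item_end, sent_row, section_name,
                                indicator) {
  toks <- pos_tag(tokenize(sent_row$text, sent_row$start))
  inside <- toks$start < item_end & toks$end > item_start
  span_tokens <- toks$text[inside]
  before <- which(toks$end <= item_start)
  after <- which(toks$start >= item_end)
  pv <- if (length(before) > 0L) max(before) else NA_integer_
  nx <- if (length(after) > 0L) min(after) else NA_integer_
  featurize_time(
    span_tokens = if (length(span_tokens) > 0L) span_tokens else "<empty>",
    prev_word = if (is.na(pv)) NA else toks$text[pv],
    prev_pos = if (is.na(pv)) NA else toks$pos[pv],
    next_word = if (is.na(nx)) NA else toks$text[nx],
    next_pos = if (is.na(nx)) NA else toks$pos[nx],
    section_name = section_name, indicator = indicator)
}

#' Extract all risk-factor annotations from one document
#'
#' Runs the full pipeline: sentence splitting, sectionizing, disease /
#' CAD-phrase / medication recognition, lab-value extraction and
#' thresholding, indicator assignment, time classification with the
#' continuing expansion and the medication-section override, document
#' smoking and family-history classification, and tag-level
#' deduplication (identical tags merge, evidence spans union).
#'
#' @param doc A [clinical_document()].
#' @param models list with elements `sectionizer` (CRF), `smoking` and
#'   `time` (Naive Bayes).
#' @param lex A [load_lexicons()] result.
#' @param thresholds A [lab_thresholds()] object.
#' @param fh_age_threshold Premature-CAD age cutoff (years).
#' @return data.frame of annotations: `risk_factor`, `indicator`,
#'   `time_attrs` (comma-joined, "" for document-level tags), `spans`
#'   (semicolon-joined `start-end` evidence intervals, "" for
#'   document-level tags).
#' @export
extract_document <- function(doc, models, lex,
                             thresholds = lab_thresholds(),
                             fh_age_threshold = 55) {
  sentences <- split_sentences(doc$text)
  sectioned <- classify_sections(doc, models$sectionizer, lex, sentences)

  items <- list()  # each: risk_factor, indicator, start, end, sentence_index
  add_item <- function(rf, ind, start, end, sidx) {
    items[[length(items) + 1L]] <<- list(risk_factor = rf, indicator = ind,
                                         start = start, end = end,
                                         sentence_index = sidx)
  }
  dis <- recognize_diseases(doc, lex, sentences)
  for (i in seq_len(nrow(dis))) {
    a <- assign_indicator("disease", dis$risk_factor[i])
    add_item(a$risk_factor, a$indicator, dis$start[i], dis$end[i],
             dis$sentence_index[i])
  }
  cev <- recognize_cad_events(doc, lex, sentences)
  for (i in seq_len(nrow(cev))) {
    a <- assign_indicator("cad_event", cev$indicator[i])
    add_item(a$risk_factor, a$indicator, cev$start[i], cev$end[i],
             cev$sentence_index[i])
  }
  med <- recognize_medications(doc, lex, sentences)
  for (i in seq_len(nrow(med))) {
    a <- assign_indicator("medication", med$category[i])
    add_item(a$risk_factor, a$indicator, med$start[i], med$end[i],
             med$sentence_index[i])
  }
  for (s in seq_len(nrow(sentences))) {
    labs <- filter_by_threshold(
      extract_lab_values(sentences$text[s], sentences$start[s]), thresholds)
    for (i in seq_len(nrow(labs))) {
      add_item(labs$risk_factor[i], labs$indicator[i],
               labs$start[i], labs$end[i], sentences$index[s])
    }
  }

  tag_rows <- list()
  for (it in items) {
    srow <- which(sentences$index == it$sentence_index)
    sec <- sectioned$section_name[srow]
    if (medication_section_override(it$risk_factor, sec)) {
      cls <- "continuing"
    } else {
      feats <- .item_time_features(it$start, it$end, sentences[srow, ], sec,
                                   it$indicator)
      cls <- classify_time(feats, models$time)
    }
    times <- expand_continuing(cls)
    tag_rows[[length(tag_rows) + 1L]] <- data.frame(
      risk_factor = it$risk_factor, indicator = it$indicator,
      time_attrs = paste(times, collapse = ","),
      spans = sprintf("%d-%d", it$start, it$end),
      stringsAsFactors = FALSE)
  }

  smoking <- classify_document_smoking(doc, models$smoking, lex, sentences)
  family <- classify_family_history(doc, lex, sentences,
                                    age_threshold = fh_age_threshold)
  tag_rows[[length(tag_rows) + 1L]] <- data.frame(
    risk_factor = "SMOKER", indicator = smoking, time_attrs = "",
    spans = "", stringsAsFactors = FALSE)
  tag_rows[[length(tag_rows) + 1L]] <- data.frame(
    risk_factor = "FAMILY_HIST", indicator = family, time_attrs = "",
    spans = "", stringsAsFactors = FALSE)

  ann <- do.call(rbind, tag_rows)
  # merge duplicates: identical (risk_factor, indicator, time set) rows
  key <- paste(ann$risk_factor, ann$indicator, ann$time_attrs, sep = "\r")
  merged <- lapply(split(seq_len(nrow(ann)), key), function(idx) {
    first <- ann[idx[1L], , drop = FALSE]
    sp <- ann$spans[idx]; sp <- sp[nzchar(sp)]
    first$spans <- paste(unique(sp), collapse = ";")
    first
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$risk_factor, out$indicator, out$time_attrs), ,
             drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(is_legal_indicator(out$risk_factor, out$indicator)))
  out
}

#' Expand annotations into per-time gold-style tags
#'
#' An annotation with three time attributes becomes three tags; the
#' document-level smoking and family-history annotations become one tag
#' each with an empty time attribute.
#'
#' @param annotations data.frame from [extract_document()].
#' @param doc_id Document identifier stamped on every tag.
#' @return data.frame with columns `doc_id`, `risk_factor`, `indicator`,
#'   `time_attr` (NA for document-level tags).
#' @export
annotations_to_tags <- function(annotations, doc_id) {
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    times <- strsplit(annotations$time_attrs[i], ",", fixed = TRUE)[[1L]]
    if (length(times) == 0L) times <- NA_character_
    data.frame(doc_id = doc_id,
               risk_factor = annotations$risk_factor[i],
               indicator = annotations$indicator[i],
               time_attr = times, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  unique(out)
}
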