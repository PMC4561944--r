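# End-to-end orchestration: train the three learned components, run
# extraction over a corpus, evaluate predictions against gold.

#' Train the three learned pipeline components
#'
#' Generates labeled training sets from the synthetic templates and fits
#' the sectionizer CRF, the smoking Naive Bayes, and the time-attribute
#' Naive Bayes.
#'
#' @param cfg A [gen_config()] describing the training corpus.
#' @param lex A [load_lexicons()] result.
#' @param crf_maxit Optimizer budget for the sectionizer.
#' @return list with elements `sectionizer`, `smoking`, `time` plus
#'   `seed` and `data_hash` (fingerprint of the training material).
#' @export
train_models <- function(cfg, lex = load_lexicons(), crf_maxit = 150L) {
  sets <- generate_training_sets(cfg)
  models <- list(
    sectionizer = train_sectionizer(sets$sectionizer, lex, seed = cfg$seed,
                                    maxit = crf_maxit),
    smoking = train_smoking_nb(sets$smoking$text, sets$smoking$label,
                               seed = cfg$seed),
    time = train_time_nb(sets$time$bags, sets$time$labels, seed = cfg$seed))
  models$seed <- cfg$seed
  models$data_hash <- hash_object(sets)
  models
}

#' Train one pipeline component and persist it
#'
#' @param component "sectionizer", "smoking", or "time".
#' @param cfg A [gen_config()] for the training material.
#' @param out_file Optional path; the model is saved there with
#'   [saveRDS()] (seed and data hash embedded).
#' @param lex A [load_lexicons()] result.
#' @return The trained model, invisibly when written to file.
#' @export
run_train <- function(component, cfg, out_file = NULL, lex = load_lexicons()) {
  valid <- c("sectionizer", "smoking", "time")
  if (!component %in% valid) {
    stop("unknown component '", component, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  sets <- generate_training_sets(cfg)
  model <- switch(component,
    sectionizer = train_sectionizer(sets$sectionizer, lex, seed = cfg$seed),
    smoking = train_smoking_nb(sets$smoking$text, sets$smoking$label,
                               seed = cfg$seed),
    time = train_time_nb(sets$time$bags, sets$time$labels, seed = cfg$seed))
  model$data_hash <- hash_object(sets[[if (component == "smoking") "smoking"
                                       else component]])
  if (!is.null(out_file)) {
    saveRDS(model, out_file)
    return(invisible(model))
  }
  model
}

#' Run extraction over a corpus
#'
#' @param corpus Either a [generate_corpus()] result, a list of
#'   [clinical_document()]s, or a directory containing `.xml` (annotated)
#'   or `.txt` (plain) notes.
#' @param models A [train_models()] result (or equivalent list).
#' @param lex A [load_lexicons()] result.
#' @param thresholds A [lab_thresholds()].
#' @param fh_age_threshold Premature-CAD age cutoff.
#' @param out_dir Optional directory; one annotation XML per note is
#'   written there.
#' @param verbose Log per-document tag counts.
#' @return data.frame of predicted tags (`doc_id`, `risk_factor`,
#'   `indicator`, `time_attr`).
#' @export
run_extract <- function(corpus, models, lex = load_lexicons(),
                        thresholds = lab_thresholds(),
                        fh_age_threshold = 55, out_dir = NULL,
                        verbose = FALSE) {
  docs <- .as_document_list(corpus)
  if (length(docs) == 0L) {
    warning("no input documents", call. = FALSE)
    return(.tag_frame())
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  all_tags <- list()
  for (doc in docs) {
    ann <- extract_document(doc, models, lex, thresholds, fh_age_threshold)
    tags <- annotations_to_tags(ann, doc$doc_id)
    if (verbose) message(sprintf("%s: %d tags", doc$doc_id, nrow(tags)))
    if (!is.null(out_dir)) {
      write_annotations(doc, tags,
                        file.path(out_dir, paste0(doc$doc_id, ".xml")))
    }
    all_tags[[length(all_tags) + 1L]] <- tags
  }
  out <- do.call(rbind, all_tags)
  rownames(out) <- NULL
  out
}

.as_document_list <- function(corpus) {
  if (is.character(corpus) && length(corpus) == 1L && dir.exists(corpus)) {
    xmls <- sort(list.files(corpus, pattern = "\\.xml$", full.names = TRUE))
    txts <- sort(list.files(corpus, pattern = "\\.txt$", full.names = TRUE))
    return(c(lapply(xmls, function(f) read_annotated_doc(f)$doc),
             lapply(txts, read_note)))
  }
  lapply(corpus, function(el) {
    if (inherits(el, "clinical_document")) el
    else if (is.list(el) && inherits(el$doc, "clinical_document")) el$doc
    else stop("cannot interpret corpus element as a document", call. = FALSE)
  })
}

#' Evaluate predicted annotation files against gold files
#'
#' @param gold_dir,pred_dir Directories of annotated XML files with
#'   matching document sets.
#' @param macro_empty Passed to [evaluate()].
#' @param report_prefix Optional path prefix for [write_eval_report()].
#' @return An `eval_report`.
#' @export
run_evaluate <- function(gold_dir, pred_dir, macro_empty = "skip",
                         report_prefix = NULL) {
  gold <- read_corpus(gold_dir)
  pred <- read_corpus(pred_dir)
  gids <- vapply(gold, function(r) r$doc$doc_id, character(1L))
  pids <- vapply(pred, function(r) r$doc$doc_id, character(1L))
  sym <- c(setdiff(gids, pids), setdiff(pids, gids))
  if (length(sym) > 0L) {
    stop("gold/predicted document sets differ: ",
         paste(sym, collapse = ", "), call. = FALSE)
  }
  gtags <- do.call(rbind, lapply(gold, `[[`, "tags"))
  ptags <- do.call(rbind, lapply(pred, `[[`, "tags"))
  if (is.null(gtags)) gtags <- .tag_frame()
  if (is.null(ptags)) ptags <- .tag_frame()
  rep <- evaluate(gtags, ptags, macro_empty = macro_empty)
  if (!is.null(report_prefix)) write_eval_report(rep, report_prefix)
  rep
}
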