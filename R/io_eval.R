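# XML corpus reading/writing and the micro/macro-averaged tag-level
# precision/recall/F evaluator.

.tag_frame <- function() {
  data.frame(doc_id = character(), risk_factor = character(),
             indicator = character(), time_attr = character(),
             stringsAsFactors = FALSE)
}

#' Read an annotated XML corpus
#'
#' Each file holds one document: a `TEXT` element with the note text and a
#' `TAGS` element of empty `TAG` elements with `risk_factor`, `indicator`,
#' and `time` attributes (empty `time` for document-level smoking and
#' family-history tags). Indicator legality is validated against the
#' schema.
#'
#' @param path A directory of `.xml` files or a character vector of file
#'   paths.
#' @return A list with one element per document:
#'   `list(doc = clinical_document, tags = data.frame)`.
#' @export
read_corpus <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else path
  lapply(files, read_annotated_doc)
}

#' Read one annotated XML document
#' @param file Path to an XML file.
#' @return `list(doc = clinical_document, tags = data.frame)`.
#' @export
read_annotated_doc <- function(file) {
  x <- tryCatch(xml2::read_xml(file),
                error = function(e) stop("malformed XML in ", file, ": ",
                                         conditionMessage(e), call. = FALSE))
  doc_id <- xml2::xml_attr(x, "doc_id")
  patient_id <- xml2::xml_attr(x, "patient_id")
  if (is.na(doc_id)) doc_id <- tools::file_path_sans_ext(basename(file))
  if (is.na(patient_id)) patient_id <- doc_id
  text_node <- xml2::xml_find_first(x, ".//TEXT")
  if (inherits(text_node, "xml_missing"))
    stop("no TEXT element in ", file, call. = FALSE)
  text <- xml2::xml_text(text_node)
  doc <- suppressWarnings(clinical_document(doc_id, text, patient_id))
  tag_nodes <- xml2::xml_find_all(x, ".//TAGS/TAG")
  if (length(tag_nodes) == 0L) {
    tags <- .tag_frame()
  } else {
    tags <- data.frame(
      doc_id = doc_id,
      risk_factor = xml2::xml_attr(tag_nodes, "risk_factor"),
      indicator = xml2::xml_attr(tag_nodes, "indicator"),
      time_attr = xml2::xml_attr(tag_nodes, "time"),
      stringsAsFactors = FALSE)
    tags$time_attr[!nzchar(tags$time_attr) | is.na(tags$time_attr)] <- NA_character_
    bad <- !is_legal_indicator(tags$risk_factor, tags$indicator)
    if (any(bad)) {
      stop(sprintf("illegal (risk factor, indicator) pair(s) in %s: %s", file,
                   paste(unique(paste0(tags$risk_factor[bad], "/",
                                       tags$indicator[bad])), collapse = ", ")),
           call. = FALSE)
    }
    badt <- !is.na(tags$time_attr) & !tags$time_attr %in% time_attributes()
    if (any(badt)) {
      stop("illegal time attribute(s) in ", file, ": ",
           paste(unique(tags$time_attr[badt]), collapse = ", "), call. = FALSE)
    }
  }
  list(doc = doc, tags = tags)
}

#' Write a document and its tags as XML
#'
#' Tags are written in canonical order (risk factor, indicator, time) so
#' output is diffable; reading the file back recovers the text verbatim
#' and the same tag set.
#'
#' @param doc A [clinical_document()].
#' @param tags data.frame with `risk_factor`, `indicator`, `time_attr`
#'   columns (NA time for document-level tags).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(doc, tags, path) {
  root <- xml2::xml_new_root("ClinicalDocument",
                             doc_id = doc$doc_id, patient_id = doc$patient_id)
  tn <- xml2::xml_add_child(root, "TEXT")
  xml2::xml_set_text(tn, doc$text)
  tg <- xml2::xml_add_child(root, "TAGS")
  if (nrow(tags) > 0L) {
    ord <- order(tags$risk_factor, tags$indicator, tags$time_attr,
                 na.last = FALSE)
    tags <- tags[ord, , drop = FALSE]
    for (i in seq_len(nrow(tags))) {
      xml2::xml_add_child(tg, "TAG",
                          risk_factor = tags$risk_factor[i],
                          indicator = tags$indicator[i],
                          time = if (is.na(tags$time_attr[i])) "" else
                            tags$time_attr[i])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

.dedup_tags <- function(tags) {
  unique(tags[, c("doc_id", "risk_factor", "indicator", "time_attr")])
}

.tag_key <- function(tags) {
  paste(tags$risk_factor, tags$indicator,
        ifelse(is.na(tags$time_attr), "", tags$time_attr), sep = "\r")
}

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

# micro + macro scores for one subset selector over per-doc tag lists
.score_subset <- function(gold_by_doc, pred_by_doc, doc_ids, select,
                          macro_empty) {
  tp_tot <- fp_tot <- fn_tot <- 0
  per_doc <- list()
  for (d in doc_ids) {
    g <- select(gold_by_doc[[d]])
    p <- select(pred_by_doc[[d]])
    gk <- .tag_key(g); pk <- .tag_key(p)
    tp <- sum(pk %in% gk); fp <- sum(!pk %in% gk); fn <- sum(!gk %in% pk)
    tp_tot <- tp_tot + tp; fp_tot <- fp_tot + fp; fn_tot <- fn_tot + fn
    if (length(gk) == 0L && length(pk) == 0L) {
      if (macro_empty == "skip") next
      per_doc[[d]] <- c(precision = 0, recall = 0, f = 0)
    } else {
      per_doc[[d]] <- .prf(tp, fp, fn)
    }
  }
  micro <- .prf(tp_tot, fp_tot, fn_tot)
  if (length(per_doc) == 0L) {
    macro <- c(precision = NA_real_, recall = NA_real_, f = NA_real_)
  } else {
    m <- do.call(rbind, per_doc)
    macro <- colMeans(m)
  }
  c(micro_p = unname(micro["precision"]), micro_r = unname(micro["recall"]),
    micro_f = unname(micro["f"]),
    macro_p = unname(macro["precision"]), macro_r = unname(macro["recall"]),
    macro_f = unname(macro["f"]),
    tp = tp_tot, fp = fp_tot, fn = fn_tot)
}

#' Evaluate predicted tags against gold tags
#'
#' Tag-level matching on (document, risk factor, indicator, time
#' attribute), with per-document deduplication. Micro scores pool
#' TP/FP/FN across documents; macro scores are unweighted means of
#' per-document precision/recall/F. Smoking and family-history tags are
#' document-level and carry no time attribute.
#'
#' @param gold,pred data.frames of tags (`doc_id`, `risk_factor`,
#'   `indicator`, `time_attr`). Every predicted doc_id must exist in the
#'   gold set; gold documents with no prediction rows count as all-missed.
#' @param macro_empty Convention for documents where both gold and
#'   prediction are empty for a key: "skip" the document for that key
#'   (default) or score it "zero".
#' @return An object of class `eval_report`: list with `overall` (named
#'   scores), `by_indicator` and `by_time` data.frames, and `n_docs`.
#' @export
evaluate <- function(gold, pred, macro_empty = c("skip", "zero")) {
  macro_empty <- match.arg(macro_empty)
  gold <- .dedup_tags(gold); pred <- .dedup_tags(pred)
  extra <- setdiff(pred$doc_id, gold$doc_id)
  if (length(extra) > 0L) {
    stop("predicted documents absent from gold: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  doc_ids <- sort(unique(gold$doc_id))
  gold_by_doc <- split(gold, factor(gold$doc_id, levels = doc_ids))
  pred_by_doc <- split(pred, factor(pred$doc_id, levels = doc_ids))

  all_sel <- function(tags) tags
  overall <- .score_subset(gold_by_doc, pred_by_doc, doc_ids, all_sel,
                           macro_empty)

  ind_keys <- unique(rbind(gold[, c("risk_factor", "indicator")],
                           pred[, c("risk_factor", "indicator")]))
  ind_keys <- ind_keys[order(ind_keys$risk_factor, ind_keys$indicator), ,
                       drop = FALSE]
  by_indicator <- do.call(rbind, lapply(seq_len(nrow(ind_keys)), function(i) {
    rf <- ind_keys$risk_factor[i]; ind <- ind_keys$indicator[i]
    sel <- function(tags) tags[tags$risk_factor == rf & tags$indicator == ind, ,
                               drop = FALSE]
    sc <- .score_subset(gold_by_doc, pred_by_doc, doc_ids, sel, macro_empty)
    data.frame(risk_factor = rf, indicator = ind, t(sc),
               stringsAsFactors = FALSE)
  }))

  time_keys <- unique(rbind(gold[!is.na(gold$time_attr),
                                 c("risk_factor", "time_attr")],
                            pred[!is.na(pred$time_attr),
                                 c("risk_factor", "time_attr")]))
  by_time <- NULL
  if (nrow(time_keys) > 0L) {
    time_keys <- time_keys[order(time_keys$risk_factor, time_keys$time_attr), ,
                           drop = FALSE]
    by_time <- do.call(rbind, lapply(seq_len(nrow(time_keys)), function(i) {
      rf <- time_keys$risk_factor[i]; ta <- time_keys$time_attr[i]
      sel <- function(tags) tags[tags$risk_factor == rf &
                                   !is.na(tags$time_attr) &
                                   tags$time_attr == ta, , drop = FALSE]
      sc <- .score_subset(gold_by_doc, pred_by_doc, doc_ids, sel, macro_empty)
      data.frame(risk_factor = rf, time_attr = ta, t(sc),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(overall = overall, by_indicator = by_indicator,
                 by_time = by_time, n_docs = length(doc_ids),
                 macro_empty = macro_empty),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d documents (macro empty-empty: %s)\n",
              x$n_docs, x$macro_empty))
  cat(sprintf("  overall micro P/R/F = %.4f / %.4f / %.4f\n",
              x$overall[["micro_p"]], x$overall[["micro_r"]],
              x$overall[["micro_f"]]))
  cat(sprintf("  overall macro P/R/F = %.4f / %.4f / %.4f\n",
              x$overall[["macro_p"]], x$overall[["macro_r"]],
              x$overall[["macro_f"]]))
  cat(sprintf("  %d indicator keys, %d time keys\n",
              NROW(x$by_indicator), NROW(x$by_time)))
  invisible(x)
}

#' Write an evaluation report to TSV and JSON
#'
#' The TSV mirrors the by-indicator and by-time table layout; the JSON
#' block carries the same numbers machine-readably.
#'
#' @param report An [evaluate()] result.
#' @param prefix Output path prefix; writes `<prefix>_indicator.tsv`,
#'   `<prefix>_time.tsv`, `<prefix>.json`.
#' @return Invisibly, the written paths.
#' @export
write_eval_report <- function(report, prefix) {
  paths <- character()
  pi_ <- paste0(prefix, "_indicator.tsv")
  utils::write.table(report$by_indicator, pi_, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, pi_)
  if (!is.null(report$by_time)) {
    pt <- paste0(prefix, "_time.tsv")
    utils::write.table(report$by_time, pt, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, pt)
  }
  pj <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(overall = as.list(report$overall),
         by_indicator = report$by_indicator,
         by_time = report$by_time, n_docs = report$n_docs),
    pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, pj)
  invisible(paths)
}
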