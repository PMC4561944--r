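#' Construct a clinical document
#'
#' A document is one clinical note: identifiers, the document creation time
#' (DCT, taken from the note's record-date header), and the raw text. All
#' character offsets used by the pipeline are 0-based, half-open intervals
#' into `text`.
#'
#' @param doc_id Document identifier.
#' @param text Raw note text (UTF-8).
#' @param patient_id Patient identifier; defaults to the doc_id.
#' @param dct Document creation time as a `Date`, or `NA`. When `NULL`
#'   (default) the DCT is parsed from a "Record date: YYYY-MM-DD" header in
#'   the text; absence yields `NA` with a warning.
#' @return An object of class `clinical_document`.
#' @export
clinical_document <- function(doc_id, text, patient_id = doc_id, dct = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  if (is.null(dct)) {
    dct <- parse_record_date(text)
    if (is.na(dct)) {
      warning(sprintf("document '%s' has no parseable record-date header; DCT set to NA",
                      doc_id), call. = FALSE)
    }
  }
  structure(
    list(doc_id = doc_id, patient_id = patient_id,
         dct = as.Date(dct), text = text),
    class = "clinical_document"
  )
}

#' Parse the record-date header of a note
#'
#' Looks for the first line matching "Record date: YYYY-MM-DD"
#' (case-insensitive).
#'
#' @param text Note text.
#' @return A `Date`, or `NA` if no header is found.
#' @export
parse_record_date <- function(text) {
  m <- regmatches(text, regexpr("record date\\s*:\\s*\\d{4}-\\d{2}-\\d{2}",
                                text, ignore.case = TRUE))
  if (length(m) == 0L) return(as.Date(NA))
  as.Date(sub("(?i)record date\\s*:\\s*", "", m[[1L]], perl = TRUE))
}

#' Read a plain-text note from disk
#'
#' One note per file; the file name (without extension) becomes the doc_id.
#'
#' @param path Path to a UTF-8 text file.
#' @param patient_id Optional patient identifier.
#' @return A [clinical_document()].
#' @export
read_note <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("note file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  id <- tools::file_path_sans_ext(basename(path))
  clinical_document(id, txt, patient_id = if (is.null(patient_id)) id else patient_id)
}

#' @export
print.clinical_document <- function(x, ...) {
  cat(sprintf("<clinical_document %s> patient=%s dct=%s, %d chars\n",
              x$doc_id, x$patient_id, format(x$dct), nchar(x$text)))
  invisible(x)
}

# slice of text at a 0-based half-open interval
text_slice <- function(text, start, end) {
  substring(text, start + 1L, end)
}
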