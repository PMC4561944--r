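# Machine-readable annotation schema: risk factor x indicator legality and
# the declarative indicator-assignment rule ledger.

.schema_cache <- new.env(parent = emptyenv())

.read_schema_tsv <- function(file, cols) {
  path <- system.file("extdata", "schema", file, package = "cardionlp")
  if (!nzchar(path)) stop("schema file not found: ", file, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Legal (risk factor, indicator) pairs
#'
#' The machine-readable schema of which indicator attributes are legal for
#' each risk factor, and whether time attributes apply. Family history and
#' smoking are document-level tags without time attributes.
#'
#' @return data.frame with columns `risk_factor`, `indicator`,
#'   `time_applicable` (logical).
#' @export
legal_indicator_table <- function() {
  if (is.null(.schema_cache$legal)) {
    df <- .read_schema_tsv("legal_indicators.tsv",
                           c("risk_factor", "indicator", "time_applicable"))
    df$time_applicable <- df$time_applicable == "yes"
    .schema_cache$legal <- df
  }
  .schema_cache$legal
}

#' Is a (risk factor, indicator) pair legal?
#' @param risk_factor,indicator Character vectors (recycled).
#' @return Logical vector.
#' @export
is_legal_indicator <- function(risk_factor, indicator) {
  leg <- legal_indicator_table()
  paste(risk_factor, indicator, sep = "\r") %in%
    paste(leg$risk_factor, leg$indicator, sep = "\r")
}

#' The indicator-assignment rule ledger
#'
#' The ordered, declarative list of rules mapping a recognized item's
#' provenance (disease dictionary, CAD clinical phrase, thresholded lab
#' value, medication dictionary) to its risk factor and indicator
#' attribute. Stored as data so the rule count and content are auditable.
#'
#' @return data.frame with columns `source`, `key`, `risk_factor`,
#'   `indicator`.
#' @export
indicator_rules <- function() {
  if (is.null(.schema_cache$rules)) {
    df <- .read_schema_tsv("indicator_rules.tsv",
                           c("source", "key", "risk_factor", "indicator"))
    bad <- !is_legal_indicator(df$risk_factor, df$indicator)
    if (any(bad)) {
      stop("indicator rules contain illegal pairs: ",
           paste(df$risk_factor[bad], df$indicator[bad], sep = "/", collapse = ", "),
           call. = FALSE)
    }
    .schema_cache$rules <- df
  }
  .schema_cache$rules
}

#' The three DCT-relative time attributes
#' @return Character vector `c("before DCT", "during DCT", "after DCT")`.
#' @export
time_attributes <- function() c("before DCT", "during DCT", "after DCT")
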