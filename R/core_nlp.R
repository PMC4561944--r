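# Core NLP: sentence detection, tokenization, POS tagging, NP chunking.
# Offsets are 0-based, half-open, in characters of the raw document text.

#' Split note text into sentences
#'
#' Clinical notes are line-oriented: every line break ends a sentence, so
#' heading-like lines ("MEDICATIONS:") are isolated for the sectionizer.
#' Within a line, sentence-final punctuation followed by whitespace also
#' starts a new sentence.
#'
#' @param text Note text.
#' @return A data.frame with columns `index` (0-based), `start`, `end`
#'   (0-based half-open character interval), `text`. The slice of the input
#'   at `[start, end)` equals `text` for every row.
#' @export
split_sentences <- function(text) {
  empty <- data.frame(index = integer(), start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  spans <- list()
  # line boundaries first
  line_starts <- c(0L, utils::head(gregexpr("\n", text, fixed = TRUE)[[1L]], -1L))
  nl <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  if (nl[1L] == -1L) {
    lines <- data.frame(start = 0L, end = nchar(text))
  } else {
    starts <- c(0L, as.integer(nl))          # position after each newline (0-based)
    ends <- c(as.integer(nl) - 1L, nchar(text))
    lines <- data.frame(start = starts, end = ends)
  }
  for (i in seq_len(nrow(lines))) {
    seg <- text_slice(text, lines$start[i], lines$end[i])
    if (!nzchar(trimws(seg))) next
    # in-line boundaries: . ! ? followed by whitespace
    brk <- gregexpr("[.!?]+(?=\\s)", seg, perl = TRUE)[[1L]]
    cuts <- if (brk[1L] == -1L) integer() else
      as.integer(brk) + attr(brk, "match.length") - 1L  # 0-based end of punct run
    piece_start <- 0L
    for (cut in c(cuts, nchar(seg))) {
      piece <- substring(seg, piece_start + 1L, cut)
      # trim to non-whitespace extent so the span round-trips exactly
      lead <- regexpr("\\S", piece)
      if (lead > 0L) {
        trail <- nchar(sub("\\s+$", "", piece))
        spans[[length(spans) + 1L]] <-
          c(lines$start[i] + piece_start + lead - 1L,
            lines$start[i] + piece_start + trail)
      }
      piece_start <- cut
    }
  }
  if (length(spans) == 0L) return(empty)
  m <- do.call(rbind, spans)
  data.frame(index = seq_len(nrow(m)) - 1L,
             start = m[, 1L], end = m[, 2L],
             text = mapply(text_slice, m[, 1L], m[, 2L],
                           MoreArgs = list(text = text), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

.token_regex <- "[A-Za-z][A-Za-z0-9]*|[0-9]+(?:\\.[0-9]+)?|[^\\sA-Za-z0-9]"

#' Tokenize a sentence
#'
#' Words (letters possibly followed by digits, so "DM2" and "A1c" stay
#' whole), numbers (with decimals), and single punctuation characters.
#' Slash compounds like "158/72" become three tokens.
#'
#' @param sentence_text Sentence text.
#' @param sentence_start 0-based document offset of the sentence (default 0),
#'   added to token spans so they index the document.
#' @return data.frame with columns `start`, `end`, `text`, `pos` (NA until
#'   tagged).
#' @export
tokenize <- function(sentence_text, sentence_start = 0L) {
  empty <- data.frame(start = integer(), end = integer(),
                      text = character(), pos = character(),
                      stringsAsFactors = FALSE)
  if (is.na(sentence_text) || !nzchar(trimws(sentence_text))) return(empty)
  m <- gregexpr(.token_regex, sentence_text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(start = sentence_start + starts,
             end = sentence_start + starts + lens,
             text = substring(sentence_text, starts + 1L, starts + lens),
             pos = NA_character_, stringsAsFactors = FALSE)
}

.verb_stems <- c("smoke", "quit", "deny", "denie", "take", "took", "taking",
                 "continue", "start", "stop", "stopp", "discontinue", "use",
                 "report", "die", "live", "work", "drink", "admit", "admitt",
                 "present", "prescribe", "increase", "decrease", "check",
                 "follow", "recommend", "restart", "resume", "hold", "tolerate")
.aux_verbs <- c("is", "are", "was", "were", "be", "been", "being", "am",
                "has", "have", "had", "having", "does", "do", "did", "done")
.modals <- c("will", "would", "can", "could", "shall", "should", "may",
             "might", "must")
.dets <- c("the", "a", "an", "this", "that", "these", "those", "no", "any",
           "each", "every", "some", "his", "her", "their")
.preps <- c("of", "in", "on", "at", "to", "for", "with", "without", "from",
            "by", "under", "over", "per", "since", "until", "during", "about")
.conjs <- c("and", "or", "but", "nor")
.prons <- c("he", "she", "it", "they", "we", "i", "you", "who", "him", "them")
.adjs <- c("high", "low", "elevated", "normal", "abnormal", "current",
           "former", "past", "premature", "obese", "uncontrolled", "stable",
           "daily", "well", "new", "old", "mild", "severe", "positive",
           "negative", "significant", "morbid")
.advs <- c("not", "never", "currently", "previously", "now", "then", "ago",
           "still", "again", "also", "very", "too")

#' Assign part-of-speech tags
#'
#' A deterministic lexicon-and-suffix tagger emitting Penn-style tags
#' (NN/NNS, VB/VBZ/VBD/VBG, JJ, RB, CD, DT, IN, CC, MD, PRP, punctuation as
#' itself). Built for the coarse noun/verb distinctions the downstream
#' feature templates need; it is not a general-purpose English tagger.
#'
#' @param tokens data.frame from [tokenize()].
#' @return The same data.frame with `pos` filled.
#' @export
pos_tag <- function(tokens) {
  if (nrow(tokens) == 0L) return(tokens)
  tokens$pos <- vapply(tokens$text, .tag_one, character(1L), USE.NAMES = FALSE)
  tokens
}

.tag_one <- function(tok) {
  lo <- tolower(tok)
  if (grepl("^[0-9]", tok)) return("CD")
  if (grepl("^[^A-Za-z0-9]$", tok)) return(tok)
  if (lo %in% .dets) return("DT")
  if (lo %in% .preps) return("IN")
  if (lo %in% .conjs) return("CC")
  if (lo %in% .prons) return("PRP")
  if (lo %in% .modals) return("MD")
  if (lo %in% .advs) return("RB")
  if (lo %in% .aux_verbs) return("VBZ")
  if (lo %in% .adjs) return("JJ")
  if (lo %in% .verb_stems) return("VB")
  # inflected verb forms from the stem list
  strip <- function(sfx) sub(paste0(sfx, "$"), "", lo)
  if (grepl("s$", lo) && (strip("s") %in% .verb_stems || strip("es") %in% .verb_stems))
    return("VBZ")
  if (grepl("ed$", lo) && (strip("ed") %in% .verb_stems || strip("d") %in% .verb_stems))
    return("VBD")
  if (grepl("ing$", lo) && (strip("ing") %in% .verb_stems || nchar(lo) > 5L))
    return("VBG")
  if (grepl("ly$", lo) && nchar(lo) > 3L) return("RB")
  if (grepl("s$", lo) && nchar(lo) > 3L) return("NNS")
  "NN"
}

#' Coarse word class of a Penn-style tag
#' @param pos Tag string.
#' @return "noun", "verb", "adj", "adv", "num", or "other".
#' @export
pos_class <- function(pos) {
  ifelse(grepl("^N", pos), "noun",
  ifelse(grepl("^V", pos) | pos == "MD", "verb",
  ifelse(grepl("^J", pos), "adj",
  ifelse(grepl("^R", pos), "adv",
  ifelse(pos == "CD", "num", "other")))))
}

#' Chunk tagged tokens into noun phrases
#'
#' Maximal runs of determiner/adjective/number/noun tokens that contain at
#' least one noun become candidate windows for concept recognition.
#'
#' @param tagged data.frame from [pos_tag()].
#' @return data.frame with `start`, `end` (document character interval),
#'   `text` is not included; one row per chunk, plus token index bounds
#'   `first_tok`, `last_tok` (1-based into `tagged`).
#' @export
chunk_noun_phrases <- function(tagged) {
  empty <- data.frame(start = integer(), end = integer(),
                      first_tok = integer(), last_tok = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tagged) == 0L) return(empty)
  ok <- grepl("^(DT|JJ|CD|NN)", tagged$pos)
  runs <- rle(ok)
  out <- list()
  pos0 <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i]) {
      idx <- pos0:(pos0 + len - 1L)
      if (any(grepl("^NN", tagged$pos[idx]))) {
        out[[length(out) + 1L]] <- c(tagged$start[idx[1L]],
                                     tagged$end[idx[length(idx)]],
                                     idx[1L], idx[length(idx)])
      }
    }
    pos0 <- pos0 + len
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L],
             first_tok = m[, 3L], last_tok = m[, 4L],
             stringsAsFactors = FALSE)
}
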