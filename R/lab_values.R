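# Rule-based extraction of blood pressure, lipid-panel, and blood-test
# values from sentence text, with clinical threshold filters that turn
# qualifying values into risk-factor evidence.

.lab_empty <- function() {
  data.frame(kind = character(), value = numeric(), value2 = numeric(),
             units = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Clinical thresholds for lab-value filtering
#'
#' Strict-inequality cutoffs above which a lab value becomes risk-factor
#' evidence. The blood-pressure cutoffs (systolic > 140, diastolic > 90)
#' come from the extraction rule ledger; the remaining defaults are the
#' standard clinical guideline values and are configurable.
#'
#' @param systolic_high,diastolic_high Blood pressure cutoffs, mmHg.
#' @param a1c_high Hemoglobin A1c cutoff, percent.
#' @param glucose_high Fasting glucose cutoff, mg/dL.
#' @param total_chol_high Total cholesterol cutoff, mg/dL.
#' @param ldl_high LDL cholesterol cutoff, mg/dL.
#' @param bmi_obese Body-mass-index cutoff, kg/m^2.
#' @return A list of class `lab_thresholds`.
#' @export
lab_thresholds <- function(systolic_high = 140, diastolic_high = 90,
                           a1c_high = 6.5, glucose_high = 126,
                           total_chol_high = 240, ldl_high = 100,
                           bmi_obese = 30) {
  th <- list(systolic_high = systolic_high, diastolic_high = diastolic_high,
             a1c_high = a1c_high, glucose_high = glucose_high,
             total_chol_high = total_chol_high, ldl_high = ldl_high,
             bmi_obese = bmi_obese)
  if (any(vapply(th, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1L)))) {
    stop("all thresholds must be single positive numbers", call. = FALSE)
  }
  structure(th, class = "lab_thresholds")
}

.num <- "([0-9]{2,3})"
.rng <- "([0-9]{2,3})(?:\\s*[-–—]\\s*([0-9]{2,3}))?"

#' Extract blood-pressure readings
#'
#' Recognizes the dialects "BP: 158/72", "blood pressure 149/96",
#' "blood pressure elevated at 188/92", and the range form
#' "120-130/88-92" (hyphen or dash). For ranges the per-component maximum
#' is kept, so a high diastolic hiding at the top of a range still reaches
#' the threshold filter. Readings outside 50-300 mmHg systolic or
#' 30-200 mmHg diastolic are discarded as implausible.
#'
#' @param text Sentence text.
#' @param offset 0-based document offset of the text (added to spans).
#' @return data.frame of lab values with `kind = "BP"`, `value` the
#'   systolic and `value2` the diastolic component, in mmHg.
#' @export
extract_blood_pressure <- function(text, offset = 0L) {
  if (is.na(text) || !nzchar(text)) return(.lab_empty())
  pats <- c(
    paste0("(?i)\\b(?:bp|b\\.p\\.|blood\\s+pressures?)\\b[^0-9\\n]{0,40}?",
           .rng, "\\s*/\\s*", .rng),
    # bare double-range form is distinctive enough to match without a keyword
    paste0("([0-9]{2,3})\\s*[-–—]\\s*([0-9]{2,3})\\s*/\\s*",
           "([0-9]{2,3})\\s*[-–—]\\s*([0-9]{2,3})")
  )
  out <- list()
  taken <- logical(nchar(text))
  for (pat in pats) {
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m); lens <- attr(m, "match.length")
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (i in seq_along(starts)) {
      if (any(taken[starts[i]:(starts[i] + lens[i] - 1L)])) next
      grp <- function(j) {
        if (cs[i, j] <= 0L) return(NA_real_)
        as.numeric(substring(text, cs[i, j], cs[i, j] + cl[i, j] - 1L))
      }
      sys <- max(grp(1L), grp(2L), na.rm = TRUE)
      dia <- max(grp(3L), grp(4L), na.rm = TRUE)
      if (sys < 50 || sys > 300 || dia < 30 || dia > 200) next
      taken[starts[i]:(starts[i] + lens[i] - 1L)] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        kind = "BP", value = sys, value2 = dia, units = "mmHg",
        start = offset + starts[i] - 1L, end = offset + starts[i] - 1L + lens[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.lab_empty())
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

.keyword_values <- function(text, offset, keywords, kinds, units,
                            filler = "[^0-9\\n]{0,15}?") {
  if (is.na(text) || !nzchar(text)) return(.lab_empty())
  pat <- paste0("(?i)\\b(", paste(keywords, collapse = "|"), ")\\b",
                filler, "([0-9]+(?:\\.[0-9]+)?)")
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(.lab_empty())
  starts <- as.integer(m); lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
  rows <- lapply(seq_along(starts), function(i) {
    kw <- norm_term(substring(text, cs[i, 1L], cs[i, 1L] + cl[i, 1L] - 1L))
    val <- as.numeric(substring(text, cs[i, 2L], cs[i, 2L] + cl[i, 2L] - 1L))
    kind <- kinds[[kw]]
    data.frame(kind = kind, value = val, value2 = NA_real_,
               units = units[[kind]],
               start = offset + starts[i] - 1L,
               end = offset + starts[i] - 1L + lens[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract lipid-panel values
#'
#' One value per analyte keyword (total cholesterol, TG/triglycerides,
#' HDL, LDL) followed within a short window by a number, as in
#' "total cholesterol 164, TG 145, HDL 33, and LDL 102".
#'
#' @inheritParams extract_blood_pressure
#' @return data.frame of lab values (kinds TOTAL_CHOL, TG, HDL, LDL; mg/dL).
#' @export
extract_lipids <- function(text, offset = 0L) {
  kinds <- c("total cholesterol" = "TOTAL_CHOL", "cholesterol" = "TOTAL_CHOL",
             "tg" = "TG", "triglycerides" = "TG",
             "hdl" = "HDL", "ldl" = "LDL")
  units <- c(TOTAL_CHOL = "mg/dL", TG = "mg/dL", HDL = "mg/dL", LDL = "mg/dL")
  .keyword_values(text, offset,
                  keywords = c("total\\s+cholesterol", "cholesterol",
                               "triglycerides", "tg", "hdl", "ldl"),
                  kinds = kinds, units = units)
}

#' Extract blood-test values (BUN, creatinine, glucose, A1c, BMI)
#'
#' Keyword-then-number patterns such as "BUN is 27, creatinine is 4.7, and
#' glucose is 79" or "A1c 8.2". BUN and creatinine are extracted for
#' completeness and later dropped by the threshold filter, which only
#' promotes heart-disease-relevant kinds.
#'
#' @inheritParams extract_blood_pressure
#' @return data.frame of lab values (kinds BUN, CREATININE, GLUCOSE, A1C,
#'   BMI).
#' @export
extract_misc_bloods <- function(text, offset = 0L) {
  kinds <- c("bun" = "BUN", "creatinine" = "CREATININE", "glucose" = "GLUCOSE",
             "a1c" = "A1C", "hba1c" = "A1C", "hemoglobin a1c" = "A1C",
             "bmi" = "BMI", "body mass index" = "BMI")
  units <- c(BUN = "mg/dL", CREATININE = "mg/dL", GLUCOSE = "mg/dL",
             A1C = "%", BMI = "kg/m2")
  .keyword_values(text, offset,
                  keywords = c("bun", "creatinine", "glucose",
                               "hemoglobin\\s+a1c", "hba1c", "a1c",
                               "body\\s+mass\\s+index", "bmi"),
                  kinds = kinds, units = units)
}

#' Extract all lab values from one sentence
#' @inheritParams extract_blood_pressure
#' @return data.frame combining the BP, lipid, and blood-test extractors.
#' @export
extract_lab_values <- function(text, offset = 0L) {
  res <- rbind(extract_blood_pressure(text, offset),
               extract_lipids(text, offset),
               extract_misc_bloods(text, offset))
  res[order(res$start), , drop = FALSE]
}

#' Filter lab values against clinical thresholds
#'
#' Strict inequalities: blood pressure qualifies when systolic >
#' `systolic_high` OR diastolic > `diastolic_high`; A1c, glucose, total
#' cholesterol, LDL, and BMI when above their cutoffs. Qualifying values
#' become risk-factor evidence (HYPERTENSION/high blood pressure,
#' DIABETES/high A1c or high glucose, HYPERLIPIDEMIA/high cholesterol or
#' high LDL, OBESITY/BMI). TG, BUN, and creatinine are never promoted.
#'
#' @param values data.frame from the extractors.
#' @param th A [lab_thresholds()] object.
#' @return The qualifying subset with `risk_factor` and `indicator`
#'   columns appended.
#' @export
filter_by_threshold <- function(values, th = lab_thresholds()) {
  stopifnot(inherits(th, "lab_thresholds"))
  if (nrow(values) == 0L) {
    out <- .lab_empty(); out$risk_factor <- character(); out$indicator <- character()
    return(out)
  }
  qualifies <- with(values, ifelse(
    kind == "BP", value > th$systolic_high | value2 > th$diastolic_high,
    ifelse(kind == "A1C", value > th$a1c_high,
    ifelse(kind == "GLUCOSE", value > th$glucose_high,
    ifelse(kind == "TOTAL_CHOL", value > th$total_chol_high,
    ifelse(kind == "LDL", value > th$ldl_high,
    ifelse(kind == "BMI", value > th$bmi_obese, FALSE)))))))
  out <- values[qualifies, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$risk_factor <- character(); out$indicator <- character()
    return(out)
  }
  rules <- indicator_rules()
  labr <- rules[rules$source == "lab", ]
  idx <- match(out$kind, labr$key)
  out$risk_factor <- labr$risk_factor[idx]
  out$indicator <- labr$indicator[idx]
  rownames(out) <- NULL
  out
}
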