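# Seeded synthetic longitudinal notes with gold tags. Notes carry a
# record-date header, sectioned text, lab-value sentences, medication
# lists, smoking and family-history statements, and abbreviation and
# misspelling noise. Gold tags are computed from the planting decisions by
# the generator's own inline logic (not the extractor's code), so the
# corpus doubles as an independent oracle for end-to-end tests.

#' Configuration for the synthetic note generator
#'
#' @param seed Mandatory integer seed; every random choice flows from it.
#' @param n_patients,notes_per_patient Corpus dimensions.
#' @param p_disease,p_medication,p_bp,p_lipids,p_bloods,p_smoking,p_family,p_cad_event
#'   Per-note inclusion probabilities of each construct family.
#' @param abbreviation_rate Probability that a planted disease/medication
#'   surface uses its abbreviation (DM2, HTN, ASA, ...).
#' @param misspelling_rate Probability that a planted surface uses a known
#'   misspelling ("pravastain", "obeise", ...).
#' @param systolic_range,diastolic_range Uniform integer ranges for
#'   planted blood pressures (mmHg).
#' @param thresholds A [lab_thresholds()] object: the cutoffs the
#'   generator's own gold logic applies to planted values.
#' @param fh_age_threshold Premature-CAD age cutoff used for gold family
#'   history.
#' @return List of class `gen_config`.
#' @export
gen_config <- function(seed,
                       n_patients = 10L, notes_per_patient = 3L,
                       p_disease = 0.8, p_medication = 0.8, p_bp = 0.5,
                       p_lipids = 0.4, p_bloods = 0.5, p_smoking = 0.6,
                       p_family = 0.4, p_cad_event = 0.2,
                       abbreviation_rate = 0.3, misspelling_rate = 0.1,
                       systolic_range = c(100L, 200L),
                       diastolic_range = c(50L, 110L),
                       thresholds = lab_thresholds(),
                       fh_age_threshold = 55) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("gen_config requires a single integer seed", call. = FALSE)
  probs <- c(p_disease = p_disease, p_medication = p_medication, p_bp = p_bp,
             p_lipids = p_lipids, p_bloods = p_bloods, p_smoking = p_smoking,
             p_family = p_family, p_cad_event = p_cad_event,
             abbreviation_rate = abbreviation_rate,
             misspelling_rate = misspelling_rate)
  if (any(probs < 0 | probs > 1))
    stop("inclusion probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 notes_per_patient = as.integer(notes_per_patient),
                 p_disease = p_disease, p_medication = p_medication,
                 p_bp = p_bp, p_lipids = p_lipids, p_bloods = p_bloods,
                 p_smoking = p_smoking, p_family = p_family,
                 p_cad_event = p_cad_event,
                 abbreviation_rate = abbreviation_rate,
                 misspelling_rate = misspelling_rate,
                 systolic_range = systolic_range,
                 diastolic_range = diastolic_range,
                 thresholds = thresholds,
                 fh_age_threshold = fh_age_threshold),
            class = "gen_config")
}

.pick <- function(x) x[[sample.int(length(x), 1L)]]

# ---- generator-side term tables (independent of the lexicon files) ------

.gen_diseases <- list(
  DIABETES = list(surfaces = c("diabetes", "diabetes mellitus",
                               "type 2 diabetes", "diabetes type 2"),
                  abbrevs = c("DM2", "DMII", "T2DM", "DM"),
                  misspell = c(diabetes = "diabetis")),
  HYPERTENSION = list(surfaces = "hypertension", abbrevs = "HTN",
                      misspell = c(hypertension = "hypertention")),
  HYPERLIPIDEMIA = list(surfaces = c("hyperlipidemia", "dyslipidemia",
                                     "hypercholesterolemia"),
                        abbrevs = "HLD",
                        misspell = c(hyperlipidemia = "hyperlipidemea")),
  CAD = list(surfaces = c("coronary artery disease", "ischemic heart disease"),
             abbrevs = "CAD", misspell = character()),
  OBESITY = list(surfaces = c("obesity", "obese", "morbid obesity"),
                 abbrevs = character(), misspell = c(obese = "obeise"))
)

.gen_meds <- data.frame(
  generic = c("lisinopril", "enalapril", "losartan", "valsartan",
              "pramlintide", "acarbose", "aspirin", "metoprolol",
              "carvedilol", "amlodipine", "diltiazem", "sitagliptin",
              "ezetimibe", "gemfibrozil", "fenofibrate", "exenatide",
              "insulin glargine", "insulin", "repaglinide", "metformin",
              "niacin", "nitroglycerin", "orlistat", "atorvastatin",
              "pravastatin", "simvastatin", "glipizide", "glyburide",
              "hydrochlorothiazide", "pioglitazone", "clopidogrel"),
  category = c("ACE inhibitors", "ACE inhibitors", "ACE inhibitors ARBs",
               "ACE inhibitors ARBs", "amylin", "antidiabetes medications",
               "aspirin", "beta-blockers", "beta-blockers",
               "calcium-channel blockers", "calcium-channel blockers",
               "DPP-4 inhibitors", "ezetimibe", "fibrates", "fibrates",
               "GLP-1 agonists", "insulin", "insulin", "meglitinides",
               "metformin", "niacin", "nitrates", "obesity", "statins",
               "statins", "statins", "sulfonylureas", "sulfonylureas",
               "thiazide diuretics", "thiazolidinediones", "thienopyridines"),
  stringsAsFactors = FALSE)

.gen_med_misspell <- c(pravastatin = "pravastain", metformin = "metforman",
                       lisinopril = "lisinipril", aspirin = "asprin",
                       atorvastatin = "atorvastatine")
.gen_med_abbrev <- c(aspirin = "ASA", nitroglycerin = "NTG",
                     hydrochlorothiazide = "HCTZ")

.gen_smoking <- list(
  current = c("Patient smokes %d packs per day.",
              "Current smoker, %d ppd.",
              "He smokes cigarettes daily.",
              "Active tobacco use, about %d ppd."),
  past = c("Quit smoking %d years ago.",
           "Former smoker, quit in %d.",
           "Past tobacco use, stopped %d years ago.",
           "He quit tobacco in %d."),
  never = c("Never smoked.",
            "Denies tobacco use.",
            "No history of smoking.",
            "Nonsmoker, denies cigarettes.")
)

.gen_cad_events <- data.frame(
  template = c("s/p myocardial infarction in %d.",
               "Underwent angioplasty in %d.",
               "Reports chest pain on exertion.",
               "Stress test was abnormal last month."),
  anchor = c("myocardial infarction", "angioplasty", "chest pain",
             "stress test"),
  indicator = c("event", "event", "symptom", "test result"),
  time_class = c("before DCT", "before DCT", "during DCT", "before DCT"),
  has_year = c(TRUE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE)

.section_order <- c("HISTORY OF PRESENT ILLNESS", "PAST MEDICAL HISTORY",
                    "MEDICATIONS", "VITAL SIGNS", "LABORATORY DATA",
                    "SOCIAL HISTORY", "FAMILY HISTORY", "ASSESSMENT AND PLAN")
.section_key <- c("HISTORY OF PRESENT ILLNESS" = "history of present illness",
                  "PAST MEDICAL HISTORY" = "past medical history",
                  "MEDICATIONS" = "medications",
                  "VITAL SIGNS" = "vital signs",
                  "LABORATORY DATA" = "laboratory data",
                  "SOCIAL HISTORY" = "social history",
                  "FAMILY HISTORY" = "family history",
                  "ASSESSMENT AND PLAN" = "assessment and plan")

# one planted sentence: text, section, plus 0+ tag-bearing construct rows
.construct_row <- function(sentence, section, anchor, risk_factor, indicator,
                           time_class) {
  data.frame(sentence = sentence, section = section, anchor = anchor,
             risk_factor = risk_factor, indicator = indicator,
             time_class = time_class, stringsAsFactors = FALSE)
}

.noisify_disease <- function(rf, cfg) {
  tbl <- .gen_diseases[[rf]]
  surface <- .pick(tbl$surfaces)
  if (length(tbl$abbrevs) > 0L && stats::runif(1L) < cfg$abbreviation_rate) {
    surface <- .pick(tbl$abbrevs)
  } else if (surface %in% names(tbl$misspell) &&
             stats::runif(1L) < cfg$misspelling_rate) {
    surface <- unname(tbl$misspell[surface])
  }
  surface
}

.noisify_med <- function(generic, cfg) {
  if (generic %in% names(.gen_med_abbrev) &&
      stats::runif(1L) < cfg$abbreviation_rate) {
    return(unname(.gen_med_abbrev[generic]))
  }
  if (generic %in% names(.gen_med_misspell) &&
      stats::runif(1L) < cfg$misspelling_rate) {
    return(unname(.gen_med_misspell[generic]))
  }
  generic
}

.gen_one_note <- function(cfg, doc_id, patient_id, date) {
  th <- cfg$thresholds
  sec_sent <- stats::setNames(vector("list", length(.section_order)),
                              .section_order)
  constructs <- list()
  plant <- function(section_upper, sentence, rows = NULL) {
    sec_sent[[section_upper]] <<- c(sec_sent[[section_upper]], sentence)
    if (!is.null(rows)) constructs[[length(constructs) + 1L]] <<- rows
  }
  yr <- function() sample(2055:2074, 1L)

  # disease mentions
  if (stats::runif(1L) < cfg$p_disease) {
    rfs <- sample(names(.gen_diseases), sample.int(3L, 1L))
    for (rf in rfs) {
      surface <- .noisify_disease(rf, cfg)
      tpl <- sample.int(5L, 1L)
      if (tpl == 1L) {
        plant("PAST MEDICAL HISTORY", surface,
              .construct_row(surface, "past medical history", surface, rf,
                             "mention", "continuing"))
      } else if (tpl == 2L) {
        s <- sprintf("History of %s diagnosed in %d.", surface, yr())
        plant("HISTORY OF PRESENT ILLNESS", s,
              .construct_row(s, "history of present illness", surface, rf,
                             "mention", "before DCT"))
      } else if (tpl == 3L) {
        s <- sprintf("Patient presents today with uncontrolled %s.", surface)
        plant("HISTORY OF PRESENT ILLNESS", s,
              .construct_row(s, "history of present illness", surface, rf,
                             "mention", "during DCT"))
      } else if (tpl == 4L) {
        s <- sprintf("%s well controlled on current regimen.", surface)
        plant("ASSESSMENT AND PLAN", s,
              .construct_row(s, "assessment and plan", surface, rf,
                             "mention", "continuing"))
      } else {
        s <- sprintf("Will follow up %s at next visit.", surface)
        plant("ASSESSMENT AND PLAN", s,
              .construct_row(s, "assessment and plan", surface, rf,
                             "mention", "after DCT"))
      }
    }
  }

  # CAD clinical phrases
  if (stats::runif(1L) < cfg$p_cad_event) {
    i <- sample.int(nrow(.gen_cad_events), 1L)
    e <- .gen_cad_events[i, ]
    s <- if (e$has_year) sprintf(e$template, yr()) else e$template
    plant("HISTORY OF PRESENT ILLNESS", s,
          .construct_row(s, "history of present illness", e$anchor, "CAD",
                         e$indicator, e$time_class))
  }

  # medications
  if (stats::runif(1L) < cfg$p_medication) {
    meds <- .gen_meds[sample.int(nrow(.gen_meds), sample.int(3L, 1L)), ]
    for (i in seq_len(nrow(meds))) {
      surface <- .noisify_med(meds$generic[i], cfg)
      cat_ <- meds$category[i]
      dose <- .pick(c(10L, 20L, 25L, 40L, 81L, 100L, 500L))
      tpl <- sample.int(5L, 1L)
      if (tpl == 1L) {
        s <- sprintf("%s %dmg daily", surface, dose)
        plant("MEDICATIONS", s,
              .construct_row(s, "medications", surface, "MEDICATION", cat_,
                             "continuing"))
      } else if (tpl == 2L) {
        s <- sprintf("Continue %s %dmg.", surface, dose)
        plant("ASSESSMENT AND PLAN", s,
              .construct_row(s, "assessment and plan", surface, "MEDICATION",
                             cat_, "continuing"))
      } else if (tpl == 3L) {
        s <- sprintf("Started %s last month.", surface)
        plant("HISTORY OF PRESENT ILLNESS", s,
              .construct_row(s, "history of present illness", surface,
                             "MEDICATION", cat_, "before DCT"))
      } else if (tpl == 4L) {
        s <- sprintf("Will start %s next week.", surface)
        plant("ASSESSMENT AND PLAN", s,
              .construct_row(s, "assessment and plan", surface, "MEDICATION",
                             cat_, "after DCT"))
      } else {
        s <- sprintf("Received %s in clinic today.", surface)
        plant("HISTORY OF PRESENT ILLNESS", s,
              .construct_row(s, "history of present illness", surface,
                             "MEDICATION", cat_, "during DCT"))
      }
    }
  }

  # blood pressure; gold iff per-component max exceeds the thresholds
  if (stats::runif(1L) < cfg$p_bp) {
    s1 <- sample(cfg$systolic_range[1L]:cfg$systolic_range[2L], 1L)
    d1 <- sample(cfg$diastolic_range[1L]:cfg$diastolic_range[2L], 1L)
    tpl <- sample.int(4L, 1L)
    if (tpl == 4L) {
      s2 <- s1 + sample.int(15L, 1L); d2 <- d1 + sample.int(8L, 1L)
      anchor <- sprintf("BP ranging %d-%d/%d-%d", s1, s2, d1, d2)
      s <- paste0(anchor, " over the past month.")
      tc <- "before DCT"
      sys_eff <- s2; dia_eff <- d2
    } else {
      anchor <- sprintf(c("BP: %d/%d", "blood pressure %d/%d",
                          "blood pressure elevated at %d/%d")[tpl], s1, d1)
      s <- anchor
      tc <- "during DCT"
      sys_eff <- s1; dia_eff <- d1
    }
    rows <- NULL
    if (sys_eff > th$systolic_high || dia_eff > th$diastolic_high) {
      rows <- .construct_row(s, "vital signs", anchor, "HYPERTENSION",
                             "high blood pressure", tc)
    }
    plant("VITAL SIGNS", s, rows)
  }

  # BMI rides with vitals
  if (stats::runif(1L) < cfg$p_bloods) {
    bmi <- round(stats::runif(1L, 18, 45), 1L)
    anchor <- sprintf("BMI %s", format(bmi))
    s <- paste0(anchor, ".")
    rows <- if (bmi > th$bmi_obese)
      .construct_row(s, "vital signs", anchor, "OBESITY", "BMI", "during DCT")
    plant("VITAL SIGNS", s, rows)
  }

  # lipid panel
  if (stats::runif(1L) < cfg$p_lipids) {
    tc_v <- sample(150:320, 1L); tg <- sample(80:300, 1L)
    hdl <- sample(20:80, 1L); ldl <- sample(60:200, 1L)
    tpl <- sample.int(3L, 1L)
    if (tpl == 1L) {
      s <- sprintf(
        "Fasting lipids showed total cholesterol %d, TG %d, HDL %d, and LDL %d.",
        tc_v, tg, hdl, ldl)
      tcl <- "during DCT"
      rows <- list()
      if (tc_v > th$total_chol_high)
        rows <- c(rows, list(.construct_row(
          s, "laboratory data", sprintf("total cholesterol %d", tc_v),
          "HYPERLIPIDEMIA", "high cholesterol", tcl)))
      if (ldl > th$ldl_high)
        rows <- c(rows, list(.construct_row(
          s, "laboratory data", sprintf("LDL %d", ldl),
          "HYPERLIPIDEMIA", "high LDL", tcl)))
      rows <- if (length(rows) > 0L) do.call(rbind, rows)
      plant("LABORATORY DATA", s, rows)
    } else if (tpl == 2L) {
      anchor <- sprintf("LDL %d", ldl)
      s <- paste0(anchor, " on labs drawn last week.")
      rows <- if (ldl > th$ldl_high)
        .construct_row(s, "laboratory data", anchor, "HYPERLIPIDEMIA",
                       "high LDL", "before DCT")
      plant("LABORATORY DATA", s, rows)
    } else {
      s <- sprintf("total cholesterol %d and LDL %d checked today.", tc_v, ldl)
      rows <- list()
      if (tc_v > th$total_chol_high)
        rows <- c(rows, list(.construct_row(
          s, "laboratory data", sprintf("total cholesterol %d", tc_v),
          "HYPERLIPIDEMIA", "high cholesterol", "during DCT")))
      if (ldl > th$ldl_high)
        rows <- c(rows, list(.construct_row(
          s, "laboratory data", sprintf("LDL %d", ldl),
          "HYPERLIPIDEMIA", "high LDL", "during DCT")))
      rows <- if (length(rows) > 0L) do.call(rbind, rows)
      plant("LABORATORY DATA", s, rows)
    }
  }

  # blood tests: glucose / A1c (BUN and creatinine never promote)
  if (stats::runif(1L) < cfg$p_bloods) {
    tpl <- sample.int(4L, 1L)
    if (tpl == 1L) {
      bun <- sample(5:40, 1L); cr <- round(stats::runif(1L, 0.5, 5), 1L)
      gl <- sample(70:250, 1L)
      s <- sprintf("BUN is %d, creatinine is %s, and glucose is %d.",
                   bun, format(cr), gl)
      rows <- if (gl > th$glucose_high)
        .construct_row(s, "laboratory data", sprintf("glucose is %d", gl),
                       "DIABETES", "high glucose", "during DCT")
      plant("LABORATORY DATA", s, rows)
    } else if (tpl == 2L) {
      a1c <- round(stats::runif(1L, 5, 12), 1L)
      anchor <- sprintf("A1c %s", format(a1c))
      s <- paste0(anchor, " today.")
      rows <- if (a1c > th$a1c_high)
        .construct_row(s, "laboratory data", anchor, "DIABETES", "high A1c",
                       "during DCT")
      plant("LABORATORY DATA", s, rows)
    } else if (tpl == 3L) {
      a1c <- round(stats::runif(1L, 5, 12), 1L)
      anchor <- sprintf("HbA1c %s", format(a1c))
      s <- paste0(anchor, " three months ago.")
      rows <- if (a1c > th$a1c_high)
        .construct_row(s, "laboratory data", anchor, "DIABETES", "high A1c",
                       "before DCT")
      plant("LABORATORY DATA", s, rows)
    } else {
      gl <- sample(70:250, 1L)
      anchor <- sprintf("glucose %d", gl)
      s <- paste0(anchor, " this morning.")
      rows <- if (gl > th$glucose_high)
        .construct_row(s, "laboratory data", anchor, "DIABETES",
                       "high glucose", "during DCT")
      plant("LABORATORY DATA", s, rows)
    }
  }

  # smoking
  smoking_status <- "unknown"
  if (stats::runif(1L) < cfg$p_smoking) {
    cls <- .pick(names(.gen_smoking))
    tpl <- .pick(.gen_smoking[[cls]])
    s <- if (grepl("%d", tpl, fixed = TRUE)) {
      n <- if (cls == "past" && grepl("in %d", tpl, fixed = TRUE)) yr() else
        sample.int(3L, 1L)
      sprintf(tpl, n)
    } else tpl
    plant("SOCIAL HISTORY", s)
    smoking_status <- cls
  }

  # family history
  family_status <- "not present"
  if (stats::runif(1L) < cfg$p_family) {
    tpl <- sample.int(6L, 1L)
    if (tpl <= 4L) {
      age <- sample(35:85, 1L)
      rel <- .pick(c("Father", "Mother", "Brother", "Sister"))
      cadw <- .pick(c("CAD", "coronary artery disease"))
      s <- sprintf(c("%s died of %s at age %d.",
                     "%s had %s and died at %d.",
                     "%s with %s at age %d.",
                     "%s died of %s at age %d.")[tpl], rel, cadw, age)
      if (age < cfg$fh_age_threshold) family_status <- "present"
      plant("FAMILY HISTORY", s,
            .construct_row(s, "family history", cadw, "CAD", "mention",
                           "before DCT"))
    } else if (tpl == 5L) {
      s <- "Mother has hypertension."
      plant("FAMILY HISTORY", s,
            .construct_row(s, "family history", "hypertension",
                           "HYPERTENSION", "mention", "before DCT"))
    } else {
      plant("FAMILY HISTORY", "Denies cardiac disease in relatives.")
    }
  }

  # assemble note text and sentence labels
  texts <- sprintf("Record date: %s", format(date))
  labels <- "SECTION_HEADING_WITH_TEXT"
  for (sec in .section_order) {
    if (length(sec_sent[[sec]]) == 0L) next
    texts <- c(texts, paste0(sec, ":"))
    labels <- c(labels, "SECTION_HEADING")
    texts <- c(texts, unlist(sec_sent[[sec]]))
    labels <- c(labels, rep("TEXT", length(sec_sent[[sec]])))
  }
  doc <- clinical_document(doc_id, paste(texts, collapse = "\n"),
                           patient_id = patient_id)

  constructs <- if (length(constructs) > 0L) do.call(rbind, constructs) else
    .construct_row(character(), character(), character(), character(),
                   character(), character())

  # gold tags: expand continuing, add the document-level pair, dedup
  tag_rows <- list()
  for (i in seq_len(nrow(constructs))) {
    times <- if (constructs$time_class[i] == "continuing") time_attributes()
             else constructs$time_class[i]
    tag_rows[[length(tag_rows) + 1L]] <- data.frame(
      doc_id = doc_id, risk_factor = constructs$risk_factor[i],
      indicator = constructs$indicator[i], time_attr = times,
      stringsAsFactors = FALSE)
  }
  tag_rows[[length(tag_rows) + 1L]] <- data.frame(
    doc_id = doc_id, risk_factor = c("SMOKER", "FAMILY_HIST"),
    indicator = c(smoking_status, family_status),
    time_attr = NA_character_, stringsAsFactors = FALSE)
  tags <- unique(do.call(rbind, tag_rows))
  rownames(tags) <- NULL

  list(doc = doc, tags = tags,
       section_labels = data.frame(text = texts, label = labels,
                                   stringsAsFactors = FALSE),
       constructs = constructs,
       smoking_status = smoking_status, family_status = family_status)
}

#' Generate a synthetic annotated corpus
#'
#' Each note gets a record-date header, a handful of sections built from
#' heading templates, and planted constructs whose gold tags the generator
#' derives from its own planting decisions (e.g. a planted blood pressure
#' yields a HYPERTENSION/high-blood-pressure tag iff it exceeds the
#' configured thresholds). Byte-identical output for identical seeds.
#'
#' @param cfg A [gen_config()].
#' @return List of per-document records: `doc` (a [clinical_document()]),
#'   `tags` (gold tag data.frame), `section_labels` (gold sentence labels
#'   for the sectionizer), `constructs` (the planting ledger), and the
#'   document-level `smoking_status` and `family_status`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  out <- with_seed(cfg$seed, {
    corpus <- list()
    base_date <- as.Date("2060-01-15")
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("pt%03d", p)
      for (j in seq_len(cfg$notes_per_patient)) {
        doc_id <- sprintf("%s_note%02d", pid, j)
        date <- base_date + (p - 1L) * 7L + (j - 1L) * 90L +
          sample.int(30L, 1L)
        corpus[[length(corpus) + 1L]] <- .gen_one_note(cfg, doc_id, pid, date)
      }
    }
    corpus
  })
  out
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The expression's value.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Collect all gold tags of a generated corpus
#' @param corpus A [generate_corpus()] result.
#' @return One data.frame of tags across documents.
#' @export
corpus_gold_tags <- function(corpus) {
  do.call(rbind, lapply(corpus, `[[`, "tags"))
}

#' Write a generated corpus as annotated XML files
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(corpus, function(rec) {
    p <- file.path(dir, paste0(rec$doc$doc_id, ".xml"))
    write_annotations(rec$doc, rec$tags, p)
    p
  }, character(1L))
  invisible(paths)
}

#' Generate labeled training sets for the three learned components
#'
#' Builds, from template-planted synthetic data: per-document sentence
#' sequences with section labels (for the sectionizer CRF), smoking
#' sentences with status labels (for the smoking Naive Bayes), and
#' time-feature bags with time classes (for the time-attribute Naive
#' Bayes). Labels follow the planting templates, so the classes are
#' separable by construction at default noise.
#'
#' @param cfg A [gen_config()]; the training corpus is generated from
#'   `cfg$seed + 1` so it is disjoint from a test corpus generated from
#'   `cfg$seed`.
#' @param n_smoking_per_class Minimum smoking sentences per class.
#' @return List with `sectionizer` (list of `texts`/`labels` docs),
#'   `smoking` (data.frame `text`, `label`), `time` (list `bags`,
#'   `labels`).
#' @export
generate_training_sets <- function(cfg, n_smoking_per_class = 120L) {
  stopifnot(inherits(cfg, "gen_config"))
  train_cfg <- cfg
  train_cfg$seed <- cfg$seed + 1L
  corpus <- generate_corpus(train_cfg)

  sectionizer <- lapply(corpus, function(rec)
    list(texts = rec$section_labels$text, labels = rec$section_labels$label))
  # notes are not guaranteed to open with a header: also train on interior
  # subsequences so the chain start is not biased toward the date line
  suffixes <- lapply(corpus, function(rec) {
    n <- nrow(rec$section_labels)
    if (n < 4L) return(NULL)
    k <- (n %/% 2L) + 1L
    list(texts = rec$section_labels$text[k:n],
         labels = rec$section_labels$label[k:n])
  })
  sectionizer <- c(sectionizer, Filter(Negate(is.null), suffixes))

  smoking <- with_seed(train_cfg$seed + 1L, {
    rows <- list()
    for (cls in names(.gen_smoking)) {
      for (i in seq_len(n_smoking_per_class)) {
        tpl <- .pick(.gen_smoking[[cls]])
        s <- if (grepl("%d", tpl, fixed = TRUE)) {
          n <- if (cls == "past" && grepl("in %d", tpl, fixed = TRUE))
            sample(2055:2074, 1L) else sample.int(3L, 1L)
          sprintf(tpl, n)
        } else tpl
        rows[[length(rows) + 1L]] <- data.frame(text = s, label = cls,
                                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  bags <- list(); labels <- character()
  for (rec in corpus) {
    cs <- rec$constructs
    for (i in seq_len(nrow(cs))) {
      pos <- regexpr(cs$anchor[i], cs$sentence[i], fixed = TRUE)
      if (pos < 0L) next
      sent_row <- list(text = cs$sentence[i], start = 0L)
      bags[[length(bags) + 1L]] <- .item_time_features(
        as.integer(pos) - 1L, as.integer(pos) - 1L + attr(pos, "match.length"),
        sent_row, cs$section[i], cs$indicator[i])
      labels <- c(labels, cs$time_class[i])
    }
  }
  list(sectionizer = sectionizer, smoking = smoking,
       time = list(bags = bags, labels = labels))
}
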