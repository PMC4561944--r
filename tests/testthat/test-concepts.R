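mkdoc <- function(text) {
  suppressWarnings(clinical_document("t", text))
}

test_that("disease recognition resolves dictionary terms and abbreviations", {
  lex <- test_lex()
  d1 <- recognize_diseases(mkdoc("Patient with type 1 diabetes."), lex)
  expect_equal(d1$risk_factor, "DIABETES")
  expect_equal(d1$source, "dictionary")
  expect_equal(d1$matched_term, "type 1 diabetes")

  d2 <- recognize_diseases(mkdoc("DMII"), lex)
  expect_equal(d2$risk_factor, "DIABETES")
  expect_equal(d2$source, "abbreviation")

  expect_equal(nrow(recognize_diseases(mkdoc("patient has pneumonia"), lex)), 0L)
})

test_that("abbreviation and full form give identical risk-factor output", {
  lex <- test_lex()
  pairs <- list(c("HTN", "hypertension"),
                c("CAD", "coronary artery disease"),
                c("DM Type II", "diabetes type 2"))
  for (p in pairs) {
    a <- recognize_diseases(mkdoc(sprintf("History of %s noted.", p[1L])), lex)
    b <- recognize_diseases(mkdoc(sprintf("History of %s noted.", p[2L])), lex)
    expect_equal(a$risk_factor, b$risk_factor, info = p[1L])
  }
})

test_that("overlapping matches collapse to the longest term", {
  lex <- test_lex()
  d <- recognize_diseases(mkdoc("known coronary artery disease here"), lex)
  expect_equal(nrow(d), 1L)
  expect_equal(d$matched_term, "coronary artery disease")
})

test_that("medication recognition maps generics, abbreviations, and misspellings to categories", {
  lex <- test_lex()
  m <- recognize_medications(mkdoc("on lisinopril and metformin"), lex)
  expect_setequal(m$category, c("ACE inhibitors", "metformin"))
  m2 <- recognize_medications(mkdoc("pravastain 40mg"), lex)
  expect_equal(m2$category, "statins")
  expect_equal(m2$generic_name, "pravastatin")
  expect_equal(nrow(recognize_medications(mkdoc("no medications"), lex)), 0L)
  expect_true(all(m$category %in% medication_categories()))
})

test_that("CAD clinical phrases carry their indicator class", {
  lex <- test_lex()
  ce <- recognize_cad_events(mkdoc("Reports chest pain on exertion."), lex)
  expect_equal(ce$indicator, "symptom")
  expect_equal(ce$risk_factor, "CAD")
})

test_that("planted dictionary mentions are recovered on synthetic notes", {
  lex <- test_lex()
  corpus <- generate_corpus(test_cfg(seed = 21L, n_patients = 10L))
  for (rec in corpus) {
    cs <- rec$constructs
    mentions <- cs[cs$indicator == "mention", , drop = FALSE]
    if (nrow(mentions) == 0L) next
    found <- recognize_diseases(rec$doc, lex)
    expect_true(all(mentions$risk_factor %in% found$risk_factor),
                info = rec$doc$doc_id)
  }
})
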