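test_that("indicator assignment follows the rule ledger and rejects unknown provenance", {
  expect_equal(assign_indicator("disease", "DIABETES"),
               list(risk_factor = "DIABETES", indicator = "mention"))
  expect_equal(assign_indicator("lab", "A1C"),
               list(risk_factor = "DIABETES", indicator = "high A1c"))
  expect_equal(assign_indicator("medication", "ACE inhibitors"),
               list(risk_factor = "MEDICATION", indicator = "ACE inhibitors"))
  expect_error(assign_indicator("mystery", "X"), "provenance")
})

test_that("every rule in the ledger emits a legal pair", {
  rules <- indicator_rules()
  expect_true(all(is_legal_indicator(rules$risk_factor, rules$indicator)))
  expect_equal(length(medication_categories()), 22L)
})

test_that("a lone high blood pressure becomes a hypertension annotation", {
  models <- test_models()
  lex <- test_lex()
  doc <- suppressWarnings(clinical_document(
    "bp1", "Record date: 2073-12-14\nVITAL SIGNS:\nBP: 158/72"))
  ann <- extract_document(doc, models, lex)
  hbp <- ann[ann$indicator == "high blood pressure", ]
  expect_equal(nrow(hbp), 1L)
  expect_equal(hbp$risk_factor, "HYPERTENSION")
  expect_gte(length(strsplit(hbp$time_attrs, ",")[[1L]]), 1L)
})

test_that("a findings-free document yields exactly the two document-level defaults", {
  models <- test_models()
  lex <- test_lex()
  doc <- suppressWarnings(clinical_document(
    "none", "Record date: 2073-12-14\nPatient doing well."))
  ann <- extract_document(doc, models, lex)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$risk_factor, c("SMOKER", "FAMILY_HIST"))
  expect_equal(ann$indicator[ann$risk_factor == "SMOKER"], "unknown")
  expect_equal(ann$indicator[ann$risk_factor == "FAMILY_HIST"], "not present")
  expect_true(all(ann$time_attrs == ""))
})

test_that("duplicate identical findings merge with unioned spans", {
  models <- test_models()
  lex <- test_lex()
  doc <- suppressWarnings(clinical_document(
    "dup", paste("Record date: 2073-12-14",
                 "PAST MEDICAL HISTORY:",
                 "type 1 diabetes",
                 "type 1 diabetes", sep = "\n")))
  ann <- extract_document(doc, models, lex)
  dia <- ann[ann$risk_factor == "DIABETES" & ann$indicator == "mention", ]
  expect_equal(nrow(dia), 1L)
  expect_equal(length(strsplit(dia$spans, ";")[[1L]]), 2L)
})

test_that("assembled annotations always carry legal indicator pairs", {
  models <- test_models()
  lex <- test_lex()
  corpus <- generate_corpus(test_cfg(seed = 31L, n_patients = 5L))
  for (rec in corpus) {
    ann <- extract_document(rec$doc, models, lex)
    expect_true(all(is_legal_indicator(ann$risk_factor, ann$indicator)))
    timeless <- ann$risk_factor %in% c("SMOKER", "FAMILY_HIST")
    expect_true(all(ann$time_attrs[timeless] == ""))
    expect_true(all(ann$time_attrs[!timeless] != ""))
  }
})
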