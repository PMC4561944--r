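test_that("shipped lexicons load with legal medication categories", {
  lex <- test_lex()
  expect_s3_class(lex, "lexicon_set")
  expect_gt(length(lex$disease_terms), 0L)
  expect_gt(length(lex$medications), 100L)
  cats <- unique(unname(lex$medications))
  expect_true(all(cats %in% medication_categories()))
  # every enumerated category is represented in the starter dictionary
  expect_setequal(cats, medication_categories())
})

test_that("lexicon validation reports malformed lines and missing files", {
  d <- withr::local_tempdir()
  src <- system.file("extdata", "lexicons", package = "cardionlp")
  file.copy(list.files(src, full.names = TRUE), d)
  writeLines(c("ok\tvalue", "bad\tline\textra"), file.path(d, "abbreviations.tsv"))
  expect_error(load_lexicons(d), "line 2")
  unlink(file.path(d, "misspellings.tsv"))
  expect_error(load_lexicons(d), "misspellings.tsv")
})

test_that("empty lexicon files yield a valid empty lexicon set", {
  d <- withr::local_tempdir()
  for (f in c("disease_terms.tsv", "abbreviations.tsv", "medications.tsv",
              "misspellings.tsv", "cad_events.tsv"))
    writeLines("# empty", file.path(d, f))
  for (f in c("smoking_terms.txt", "section_headings.txt",
              "relation_terms.txt"))
    writeLines("# empty", file.path(d, f))
  lex <- load_lexicons(d)
  expect_equal(length(lex$medications), 0L)
  expect_null(lookup_medication("aspirin daily", lex))
})

test_that("abbreviation expansion and misspelling correction behave and are idempotent", {
  lex <- test_lex()
  expect_equal(expand_abbreviation("DM2", lex), "diabetes type 2")
  expect_equal(expand_abbreviation("HTN", lex), "hypertension")
  expect_equal(expand_abbreviation("aspirin", lex), "aspirin")
  expect_equal(correct_misspelling("pravastain", lex), "pravastatin")
  expect_equal(correct_misspelling("obeise", lex), "obese")
  expect_equal(correct_misspelling("metformin", lex), "metformin")

  probe <- c(names(lex$abbreviations), names(lex$misspellings), "unrelated")
  once <- expand_abbreviation(probe, lex)
  expect_equal(expand_abbreviation(once, lex), once)
  oncem <- correct_misspelling(probe, lex)
  expect_equal(correct_misspelling(oncem, lex), oncem)
})

test_that("medication lookup is longest-match, case-insensitive, and abbreviation-aware", {
  lex <- test_lex()
  hit <- lookup_medication("ASA 81 mg daily", lex)
  expect_equal(hit$generic, "aspirin")
  expect_equal(hit$category, "aspirin")
  expect_equal(lookup_medication("metformin 500mg", lex)$category, "metformin")
  expect_null(lookup_medication("vitamin D", lex))
  for (phrase in c("Insulin Glargine at bedtime", "on HCTZ 25mg")) {
    expect_identical(lookup_medication(phrase, lex),
                     lookup_medication(tolower(phrase), lex))
  }
  expect_equal(lookup_medication("insulin glargine 20 units", lex)$generic,
               "insulin glargine")
})
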