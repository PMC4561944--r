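test_that("sentence features follow the template, including empty sentences", {
  lex <- test_lex()
  f <- featurize_sentence("CURRENT MEDICATIONS:", lex = lex)
  expect_true(f$all_words_uppercased)
  expect_true(f$contains_colon)
  expect_true(f$dictionary_match)
  expect_equal(f$first_word, "current")
  expect_equal(f$second_word, "medications")

  f2 <- featurize_sentence("Record date: 2073-12-14", lex = lex)
  expect_true(f2$contains_colon)
  expect_false(f2$all_words_uppercased)
  expect_true(f2$first_word_uppercased)

  f3 <- featurize_sentence("", lex = lex)
  bools <- c("first_word_uppercased", "all_words_uppercased",
             "all_words_lowercased", "dictionary_match", "ends_full_stop",
             "contains_colon")
  expect_true(all(!unlist(f3[bools])))
  expect_equal(f3$first_word, "")

  # neighbor features are the neighbor's own local features, non-recursive
  f4 <- featurize_sentence("aspirin 81mg", prev_text = "MEDICATIONS:",
                           next_text = "BP: 120/80", lex = lex)
  expect_true(f4$prev$contains_colon)
  expect_null(f4$prev$prev)
})

test_that("section names come from the text before the first colon", {
  expect_equal(extract_section_name("Record date: 2073-12-14"), "record date")
  expect_equal(extract_section_name("MEDICATIONS:"), "medications")
  expect_equal(extract_section_name("Allergies: none : known"), "allergies")
  expect_warning(nm <- extract_section_name("plain text"), "colon")
  expect_equal(nm, "plain text")
})

test_that("the heading-dictionary override relabels only qualifying TEXT sentences", {
  lex <- test_lex()
  df <- data.frame(
    text = c("past medical history", "patient doing well", "MEDICATIONS:"),
    label = c("TEXT", "TEXT", "SECTION_HEADING"),
    stringsAsFactors = FALSE)
  out <- apply_heading_override(df, lex)
  expect_equal(out$label,
               c("SECTION_HEADING", "TEXT", "SECTION_HEADING"))
  # idempotent
  expect_identical(apply_heading_override(out, lex), out)
})

test_that("training rejects empty or class-degenerate corpora", {
  lex <- test_lex()
  expect_error(train_sectionizer(list(), lex), "empty")
  one <- list(list(texts = c("PLAN:", "do well"),
                   labels = c("SECTION_HEADING", "TEXT")))
  expect_error(train_sectionizer(one, lex), "missing label")
  # minimal viable corpus: one document with all three classes
  ok <- list(list(
    texts = c("Record date: 2073-12-14", "MEDICATIONS:", "aspirin 81mg"),
    labels = c("SECTION_HEADING_WITH_TEXT", "SECTION_HEADING", "TEXT")))
  m <- train_sectionizer(ok, lex, maxit = 30L)
  expect_s3_class(m, "crf_model")
})

test_that("the trained sectionizer classifies held-out synthetic notes accurately", {
  lex <- test_lex()
  models <- test_models()
  held_out <- generate_corpus(test_cfg(seed = 77L, n_patients = 15L))
  correct <- 0L; total <- 0L
  for (rec in held_out) {
    got <- classify_sections(rec$doc, models$sectionizer, lex)
    expect_equal(nrow(got), nrow(rec$section_labels))
    correct <- correct + sum(got$label == rec$section_labels$label)
    total <- total + nrow(got)
  }
  expect_gte(correct / total, 0.90)
})

test_that("section names propagate forward from the latest heading", {
  lex <- test_lex()
  models <- test_models()
  doc <- suppressWarnings(clinical_document(
    "s", "Record date: 2073-12-14\nMEDICATIONS:\naspirin 81mg daily"))
  got <- classify_sections(doc, models$sectionizer, lex)
  expect_equal(got$label[1L], "SECTION_HEADING_WITH_TEXT")
  expect_equal(got$label[2L], "SECTION_HEADING")
  expect_equal(got$label[3L], "TEXT")
  expect_equal(got$section_name[3L], "medications")
  # body text without headings
  doc2 <- suppressWarnings(clinical_document("s2", "s/p XRT to esophagus"))
  got2 <- classify_sections(doc2, models$sectionizer, lex)
  expect_equal(got2$label, "TEXT")
})
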