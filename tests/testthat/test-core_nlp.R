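test_that("sentence splitting handles boundaries, headings, and empty input", {
  expect_equal(nrow(split_sentences("")), 0L)

  s <- split_sentences("BP: 158/72. Continue lisinopril.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text[1L], "BP: 158/72.")

  s3 <- split_sentences("Record date: 2073-12-14\nMEDICATIONS:\naspirin 81mg")
  expect_equal(nrow(s3), 3L)
  expect_equal(s3$text[2L], "MEDICATIONS:")
})

test_that("sentence spans round-trip and stay ordered on generated notes", {
  corpus <- generate_corpus(test_cfg(seed = 11L, n_patients = 5L))
  for (rec in corpus) {
    txt <- rec$doc$text
    s <- split_sentences(txt)
    expect_true(all(mapply(function(a, b, t) text_slice(txt, a, b) == t,
                           s$start, s$end, s$text)))
    if (nrow(s) > 1L) expect_true(all(s$end[-nrow(s)] <= s$start[-1L]))
    # determinism
    expect_identical(s, split_sentences(txt))
  }
})

test_that("tokenizer splits punctuation and keeps numerics recoverable", {
  expect_equal(tokenize("DM2 .")$text, c("DM2", "."))
  bp <- tokenize("BP: 158/72")$text
  expect_true(all(c("158", "72") %in% bp))
  expect_equal(nrow(tokenize("   ")), 0L)
})

test_that("token spans nest inside their sentence and round-trip", {
  corpus <- generate_corpus(test_cfg(seed = 12L, n_patients = 3L))
  for (rec in corpus[1:3]) {
    txt <- rec$doc$text
    s <- split_sentences(txt)
    for (i in seq_len(nrow(s))) {
      tk <- tokenize(s$text[i], s$start[i])
      if (nrow(tk) == 0L) next
      expect_true(all(tk$start >= s$start[i] & tk$end <= s$end[i]))
      expect_true(all(text_slice(txt, tk$start, tk$end) == tk$text))
    }
  }
})

test_that("POS tagging yields coarse noun/verb classes deterministically", {
  expect_equal(nrow(pos_tag(tokenize(""))), 0L)
  tagged <- pos_tag(tokenize("patient smokes"))
  expect_equal(pos_class(tagged$pos), c("noun", "verb"))
  expect_equal(pos_class(pos_tag(tokenize("aspirin"))$pos), "noun")
  t1 <- pos_tag(tokenize("He quit tobacco in 2001 ."))
  expect_identical(t1, pos_tag(tokenize("He quit tobacco in 2001 .")))
})

test_that("noun-phrase chunking produces maximal noun-bearing spans", {
  expect_equal(nrow(chunk_noun_phrases(pos_tag(tokenize("")))), 0L)
  one <- chunk_noun_phrases(pos_tag(tokenize("type 1 diabetes")))
  expect_equal(nrow(one), 1L)
  expect_equal(one$first_tok, 1L)
  expect_equal(one$last_tok, 3L)
  two <- chunk_noun_phrases(pos_tag(tokenize("continue aspirin and lisinopril")))
  expect_equal(nrow(two), 2L)
})

test_that("record-date header parses into the DCT and absence warns", {
  doc <- clinical_document("a", "Record date: 2073-12-14\ntext")
  expect_equal(doc$dct, as.Date("2073-12-14"))
  expect_warning(clinical_document("b", "no header here"), "record-date")
})
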