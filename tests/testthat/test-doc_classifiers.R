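mkdoc2 <- function(text) suppressWarnings(clinical_document("t", text))

test_that("smoking sentences are selected by the term dictionary", {
  lex <- test_lex()
  doc <- mkdoc2(paste("He quit tobacco in 2001.",
                      "Patient denies chest pain.",
                      "2 packs per year for 10 years", sep = "\n"))
  got <- find_smoking_sentences(doc, lex)
  expect_equal(nrow(got), 2L)
  expect_false(any(grepl("chest pain", got$text)))
})

test_that("the smoking classifier separates template classes on held-out data", {
  models <- test_models()
  expect_equal(classify_smoking_sentence("patient smokes 1 ppd", models$smoking),
               "current")
  expect_equal(classify_smoking_sentence("quit smoking 10 years ago",
                                         models$smoking), "past")
  expect_equal(classify_smoking_sentence("never smoked", models$smoking),
               "never")
})

test_that("smoking training validates classes", {
  expect_error(train_smoking_nb(character(), character()), "empty")
  expect_error(
    train_smoking_nb(c("smokes now", "quit years ago"), c("current", "past")),
    "missing class")
  expect_error(
    train_smoking_nb(c("smokes", "x"), c("current", "ever")), "illegal")
  # duplicates are fine
  m <- train_smoking_nb(rep(c("smokes now", "quit ago", "never smoked"), 2L),
                        rep(c("current", "past", "never"), 2L))
  expect_s3_class(m, "nb_model")
})

test_that("document smoking resolution applies priority and is permutation-invariant", {
  expect_equal(resolve_document_smoking(character()), "unknown")
  expect_equal(resolve_document_smoking(c("past", "current")), "current")
  expect_equal(resolve_document_smoking(c("never", "never")), "never")
  set.seed(5)
  for (i in 1:20) {
    cls <- sample(c("current", "past", "never"), sample.int(5L, 1L),
                  replace = TRUE)
    expect_equal(resolve_document_smoking(cls),
                 resolve_document_smoking(sample(cls)))
  }
})

test_that("family-history rule needs CAD term, relation, and premature age", {
  lex <- test_lex()
  expect_equal(classify_family_history(
    mkdoc2("Father died of CAD at age 50"), lex), "present")
  expect_equal(classify_family_history(
    mkdoc2("Mother has hypertension"), lex), "not present")
  expect_equal(classify_family_history(
    mkdoc2("Brother with CAD, died at 70"), lex), "not present")
  # no parseable age means not premature
  expect_equal(classify_family_history(
    mkdoc2("Father has coronary artery disease"), lex), "not present")
  expect_equal(classify_family_history(mkdoc2("nothing relevant"), lex),
               "not present")
})

test_that("family-history is monotone in the age threshold", {
  lex <- test_lex()
  doc <- mkdoc2("Sister died of coronary artery disease at age 52.")
  for (t1 in c(40, 53, 60, 80)) {
    r1 <- classify_family_history(doc, lex, age_threshold = t1)
    for (t2 in c(t1 + 5, t1 + 20)) {
      r2 <- classify_family_history(doc, lex, age_threshold = t2)
      if (r1 == "present") expect_equal(r2, "present")
    }
  }
  expect_equal(classify_family_history(doc, lex, age_threshold = 45),
               "not present")
})
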