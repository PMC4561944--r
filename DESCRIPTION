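Package: cardionlp
Title: Heart Disease Risk Factor Extraction from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid rule-based and machine-learning information extraction
    pipeline that identifies eight heart-disease risk factors (coronary artery
    disease, diabetes, hyperlipidemia, hypertension, obesity, medication use,
    smoking status, and family history of premature CAD) in free-text clinical
    notes of diabetic patients. Each finding is tagged with an indicator
    attribute (mention, lab value, or medication category) and a time attribute
    relative to the document creation time. Includes lexicon-driven concept
    recognition, regular-expression lab-value extraction with clinical
    thresholds, a conditional-random-field sentence sectionizer, Naive Bayes
    smoking-status and time-attribute classifiers, an XML annotation reader and
    writer, a micro/macro-averaged precision-recall-F evaluator, and a seeded
    synthetic note generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
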