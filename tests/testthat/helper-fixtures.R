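# Shared fixtures: lexicons loaded once, small trained models cached for
# the tests that need the full pipeline.

.fixture_env <- new.env()

test_lex <- function() {
  if (is.null(.fixture_env$lex)) .fixture_env$lex <- load_lexicons()
  .fixture_env$lex
}

# compact but fully representative training configuration
test_cfg <- function(seed = 42L, n_patients = 30L, notes_per_patient = 2L) {
  gen_config(seed = seed, n_patients = n_patients,
             notes_per_patient = notes_per_patient)
}

test_models <- function() {
  if (is.null(.fixture_env$models)) {
    .fixture_env$models <- train_models(test_cfg(), test_lex())
  }
  .fixture_env$models
}

# random legal tag sets for evaluator property tests
random_tags <- function(n_docs, max_tags = 6L) {
  leg <- legal_indicator_table()
  rows <- list()
  for (d in seq_len(n_docs)) {
    k <- sample.int(max_tags, 1L)
    idx <- sample.int(nrow(leg), k, replace = TRUE)
    rows[[d]] <- data.frame(
      doc_id = sprintf("doc%03d", d),
      risk_factor = leg$risk_factor[idx],
      indicator = leg$indicator[idx],
      time_attr = ifelse(leg$time_applicable[idx],
                         sample(time_attributes(), k, replace = TRUE),
                         NA_character_),
      stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, rows))
}
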