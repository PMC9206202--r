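# Shared fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

zh_lexicon <- load_lexicon(phenossu_file("lexicon_zh.tsv"))
fixture_kb <- load_lab_kb(phenossu_file("lab_kb.tsv"))
fixture_schema <- load_schema(phenossu_file("phenossu_schema.tsv"))

# a small ASCII lexicon for constructed encoder tests
tiny_lexicon <- function(extra = NULL) {
  df <- data.frame(
    surface = c("severe", "acute", "no", "cough", "fever", ",",
                "blood", "sugar", "high", "units"),
    letter = c("A", "A", "A", "P", "P", "C", "S", "L", "R", "U"),
    category = c("severity", "temporal pattern", "assertion",
                 "", "", "", "", "", "", ""),
    normalization = c("severe", "acute", "absent", "cough", "fever", "",
                      "blood", "glucose", "higher", "mmol/L"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  as_lexicon(df)
}

uniform_background <- function() {
  structure(stats::setNames(rep(1 / 9, 9), PHENOSSU_ALPHABET),
            class = "phenossu_background")
}

skewed_background <- function() {
  structure(stats::setNames(c(.12, .20, .08, .35, .05, .05, .05, .05, .05),
                            PHENOSSU_ALPHABET),
            class = "phenossu_background")
}

small_corpus <- function(n_docs = 40, seed = 42) {
  generate_corpus(generator_config(n_docs = n_docs, seed = seed))
}

recognize_corpus <- function(corpus, library = builtin_library()) {
  cfg <- corpus$config
  pred <- list()
  for (d in seq_along(corpus$docs)) {
    inst <- recognize_document(corpus$docs[[d]]$text, cfg$lexicon, library,
                               lab_kb = cfg$lab_kb, schema = cfg$schema)
    pred <- c(pred, lapply(inst, function(x) { x$doc <- d; x }))
  }
  pred
}

corpus_gold <- function(corpus) {
  do.call(c, lapply(corpus$docs, `[[`, "instances"))
}
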