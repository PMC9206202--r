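test_that("corpus generation is deterministic given the configuration", {
  c1 <- generate_corpus(generator_config(n_docs = 10, seed = 42))
  c2 <- generate_corpus(generator_config(n_docs = 10, seed = 42))
  expect_identical(vapply(c1$docs, `[[`, character(1), "text"),
                   vapply(c2$docs, `[[`, character(1), "text"))
  expect_identical(lapply(c1$docs, `[[`, "instances"),
                   lapply(c2$docs, `[[`, "instances"))
  c3 <- generate_corpus(generator_config(n_docs = 10, seed = 43))
  expect_false(identical(vapply(c1$docs, `[[`, character(1), "text"),
                         vapply(c3$docs, `[[`, character(1), "text")))
})

test_that("weights concentrated on one class generate only that class", {
  w <- c("A+P(CP)+" = 0, "AP+" = 0, "A+P" = 1, "A*PC*A+" = 0,
         "S*LNU" = 0, "S*LR" = 0)
  corp <- generate_corpus(generator_config(n_docs = 15, weights = w,
                                           seed = 5))
  for (doc in corp$docs) {
    expect_true(all(doc$classes == "A+P"))
    for (inst in doc$instances) {
      expect_equal(inst$attributes[["assertion"]]$value, "present")
      expect_gte(length(inst$attributes), 2) # assertion + >= 1 attribute
    }
  }
})

test_that("generator configuration is validated", {
  w <- c("A+P(CP)+" = 0.5, "AP+" = 0.5, "A+P" = 0.5, "A*PC*A+" = 0,
         "S*LNU" = 0, "S*LR" = 0)
  expect_error(generator_config(weights = w), "sum to 1")
  expect_error(generator_config(n_docs = 0), "n_docs")
  expect_error(generator_config(filler_rate = 2), "rates")
})

test_that("the recognizer reproduces the generator's gold exactly", {
  corp <- small_corpus(40, seed = 42)
  pred <- recognize_corpus(corp)
  gold <- corpus_gold(corp)
  expect_equal(length(pred), length(gold))
  expect_equal(instance_accuracy(pred, gold), 1)
  # and the emitted SNOMED codes agree on logic-based instances
  psig <- vapply(pred, function(x)
    paste(x$doc, x$span[1], x$snomed %||% "-"), character(1))
  gsig <- vapply(gold, function(x)
    paste(x$doc, x$span[1], x$snomed %||% "-"), character(1))
  expect_setequal(psig, gsig)
})

test_that("planted sequences respect copies, offsets and noise", {
  bg <- uniform_background()
  pl <- generate_planted_sequences(bg, "SLNU", copies = 20, n_seqs = 5,
                                   seq_len = 40, noise_rate = 0, seed = 3)
  expect_equal(nrow(pl$sites), 20)
  for (i in seq_len(nrow(pl$sites)))
    expect_equal(substr(pl$sequences[pl$sites$seq[i]], pl$sites$offset[i],
                        pl$sites$offset[i] + 3), "SLNU")

  none <- generate_planted_sequences(bg, "SLNU", copies = 0, n_seqs = 3,
                                     seq_len = 30, seed = 3)
  expect_equal(nrow(none$sites), 0)
  expect_equal(nchar(none$sequences), rep(30, 3))

  expect_error(generate_planted_sequences(bg, "SLNU", copies = 100,
                                          n_seqs = 2, seq_len = 20),
               "infeasible")
})

test_that("the corrupted fraction stays within binomial bounds", {
  bg <- uniform_background()
  word <- "SLNUR"
  pl <- generate_planted_sequences(bg, word, copies = 200, n_seqs = 40,
                                   seq_len = 30, noise_rate = 0.1,
                                   seed = 11)
  planted_letters <- 200 * nchar(word)  # 1000 planted letters
  mismatches <- 0
  chars <- strsplit(word, "")[[1]]
  for (i in seq_len(nrow(pl$sites))) {
    got <- strsplit(substr(pl$sequences[pl$sites$seq[i]],
                           pl$sites$offset[i],
                           pl$sites$offset[i] + nchar(word) - 1), "")[[1]]
    mismatches <- mismatches + sum(got != chars)
  }
  bounds <- stats::qbinom(c(0.005, 0.995), planted_letters, 0.1)
  expect_gte(mismatches, bounds[1])
  expect_lte(mismatches, bounds[2])
})
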