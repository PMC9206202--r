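scan_letters <- function(text, lexicon = zh_lexicon,
                         library = builtin_library()) {
  scan_encoding(encode(text, lexicon), library)
}

test_that("scanning takes the highest-priority longest match", {
  m <- scan_letters("右下腹部突发剧烈疼痛")
  expect_equal(nrow(m), 1)
  expect_equal(m$pattern, "A+P")
  expect_equal(c(m$from, m$to), c(1L, 5L))

  m2 <- scan_letters("没有出现发热, 乏力")
  expect_equal(m2$pattern, "A+P(CP)+")
  expect_equal(m2$letters, "APCP")

  enc <- encode("zz yy xx ww", tiny_lexicon())
  expect_equal(nrow(scan_encoding(enc, builtin_library())), 0)
})

test_that("matches never overlap and resume after the match end", {
  # two sentences in one sequence, separated by filler
  m <- scan_letters("右下腹部突发剧烈疼痛。随后没有出现发热, 乏力")
  expect_equal(m$pattern, c("A+P", "A+P(CP)+"))
  expect_true(all(m$from[-1] > m$to[-nrow(m)]))
})

test_that("the stacked-attribute sentence yields the pain instance", {
  inst <- recognize_document("右下腹部突发剧烈疼痛", zh_lexicon,
                             builtin_library(), lab_kb = fixture_kb,
                             schema = fixture_schema)
  expect_length(inst, 1)
  x <- inst[[1]]
  expect_equal(x$phenotype, "pain")
  vals <- vapply(x$attributes, `[[`, character(1), "value")
  expect_equal(vals[["assertion"]], "present")
  expect_true(x$attributes[["assertion"]]$default)
  expect_equal(vals[["temporal pattern"]], "acute")
  expect_equal(vals[["severity"]], "severe")
  expect_equal(vals[["quadrant pattern"]], "right-lower")
  expect_equal(vals[["body location"]], "abdomen")
})

test_that("negation distributes over an enumerated phenotype list", {
  inst <- recognize_document("没有出现发热, 乏力", zh_lexicon,
                             builtin_library(), schema = fixture_schema)
  expect_length(inst, 2)
  expect_equal(vapply(inst, `[[`, character(1), "phenotype"),
               c("fever", "fatigue"))
  for (x in inst)
    expect_equal(x$attributes[["assertion"]]$value, "absent")
})

test_that("a single attribute propagates to all phenotypes (AP+)", {
  inst <- recognize_document("严重腹痛腹泻", zh_lexicon, builtin_library(),
                             schema = fixture_schema)
  expect_length(inst, 2)
  for (x in inst)
    expect_equal(x$attributes[["severity"]]$value, "severe")
})

test_that("trailing attributes attach to the preceding phenotype", {
  inst <- recognize_document("咳嗽，呈持续性", zh_lexicon, builtin_library(),
                             schema = fixture_schema)
  expect_length(inst, 1)
  expect_equal(inst[[1]]$phenotype, "cough")
  expect_equal(inst[[1]]$attributes[["temporal pattern"]]$value,
               "persistent")
})

test_that("instances per phrase match equal the number of P letters", {
  corp <- small_corpus(15, seed = 9)
  cfg <- corp$config
  for (doc in corp$docs) {
    enc <- encode(doc$text, cfg$lexicon)
    m <- scan_encoding(enc, builtin_library())
    phr <- m[m$category == "phrase-based", , drop = FALSE]
    inst <- assemble_instances(phr, enc, cfg$schema, cfg$lab_kb)
    expect_equal(length(inst),
                 sum(vapply(strsplit(phr$letters, ""), function(x)
                   sum(x == "P"), integer(1))))
    for (x in inst)
      expect_true(nzchar(substr(doc$text, x$span[1] + 1, x$span[2])))
  }
})

test_that("evidence spans decode to substrings of the document", {
  corp <- small_corpus(10, seed = 4)
  pred <- recognize_corpus(corp)
  for (x in pred) {
    doc <- corp$docs[[x$doc]]
    expect_gte(x$span[1], 0)
    expect_lte(x$span[2], nchar(doc$text))
    for (a in x$attributes)
      if (!is.null(a$span)) {
        expect_gte(a$span[1], 0)
        expect_lte(a$span[2], nchar(doc$text))
      }
  }
})

test_that("documents of pure filler yield no instances", {
  expect_length(recognize_document("今天查房无特殊记录吗？？",
                                   as_lexicon(data.frame(
                                     surface = "zz", letter = "P",
                                     category = "", normalization = "zz")),
                                   builtin_library(),
                                   schema = fixture_schema), 0)
})

test_that("attribute conflicts resolve to the trigger nearest the phenotype", {
  lex <- tiny_lexicon(data.frame(surface = "terrible", letter = "A",
                                 category = "severity",
                                 normalization = "mild",
                                 stringsAsFactors = FALSE))
  expect_warning(
    inst <- recognize_document("severeterriblecough", lex,
                               builtin_library(), schema = fixture_schema),
    "conflict")
  expect_equal(inst[[1]]$attributes[["severity"]]$value, "mild")
})
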