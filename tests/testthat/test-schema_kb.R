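test_that("the shipped schema has 10 attributes split 7 phrase / 3 logic", {
  sch <- fixture_schema
  expect_length(sch$attributes, 10)
  subtype <- vapply(sch$attributes, `[[`, character(1), "subtype")
  expect_equal(sum(subtype == "phrase-based"), 7)
  expect_equal(sum(subtype == "logic-based"), 3)
  expect_true(all(c("present", "absent") %in%
                    sch$attributes[["assertion"]]$values))
  expect_setequal(sch$attributes[["abnormality"]]$values,
                  c("higher", "lower", "normal"))
  expect_equal(sch$attributes[["assertion"]]$default, "present")
})

test_that("schema validation rejects malformed attribute sets", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- utils::read.delim(phenossu_file("phenossu_schema.tsv"), sep = "\t",
                          check.names = FALSE)
  utils::write.table(df[-3, ], tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_schema(tmp), "10 attributes")

  df2 <- df
  df2$values[df2$attribute == "abnormality"] <- "higher|lower"
  utils::write.table(df2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_schema(tmp), "abnormality")

  df3 <- df
  df3$default[df3$attribute == "assertion"] <- "maybe"
  utils::write.table(df3, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_schema(tmp), "default")
})

test_that("schema round-trips through its serialized form", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_schema(fixture_schema, tmp)
  expect_equal(load_schema(tmp), fixture_schema)
})

test_that("lexicon loading validates entries", {
  # a severity trigger row becomes one attribute entry
  lex <- as_lexicon(data.frame(surface = "剧烈", letter = "A",
                               category = "severity",
                               normalization = "severe"),
                    schema = fixture_schema)
  expect_equal(nrow(lex), 1)
  expect_equal(lex$category, "severity")

  # empty lexicon is legal
  empty <- as_lexicon(data.frame(surface = character(0),
                                 letter = character(0),
                                 category = character(0),
                                 normalization = character(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(encode("anything", empty)$letters, "O")

  # closed alphabet
  expect_error(as_lexicon(data.frame(surface = "x", letter = "X",
                                     category = "", normalization = "")),
               "unknown letter")
  # A entries need a category from the schema's phrase-based set
  expect_error(as_lexicon(data.frame(surface = "big", letter = "A",
                                     category = "hue",
                                     normalization = "red"),
                          schema = fixture_schema),
               "unknown phrase-based attribute")
  # duplicates collapse with a warning; cross-letter ambiguity is an error
  expect_warning(
    lex2 <- as_lexicon(data.frame(surface = c("a", "a"),
                                  letter = c("P", "P"), category = "",
                                  normalization = "x")),
    "duplicate")
  expect_equal(nrow(lex2), 1)
  expect_error(as_lexicon(data.frame(surface = c("a", "a"),
                                     letter = c("P", "L"), category = "",
                                     normalization = "x")),
               "more than one letter")
})

test_that("lexicon round-trips through its serialized form", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(zh_lexicon, tmp)
  again <- load_lexicon(tmp)
  expect_equal(as.data.frame(again), as.data.frame(zh_lexicon))
})

test_that("lab KB loads, validates, and converts units", {
  kb <- fixture_kb
  idx <- attr(kb, "synonym_index")
  expect_true(all(c("WBC", "白细胞", "leukocyte") %in% names(idx)))
  wbc <- kb[[idx[["WBC"]][1]]]
  expect_equal(wbc$low, 4)
  expect_equal(wbc$high, 10)
  expect_equal(unname(wbc$snomed["higher"]), "414478003")

  # dimensional round trip through the alternative unit
  v <- 12.5
  there <- convert_unit(wbc, v, from = wbc$unit, to = "/L")
  back <- convert_unit(wbc, there, from = "/L", to = wbc$unit)
  expect_equal(back, v, tolerance = 1e-9)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("analyte\tsynonyms\tspecimen\tunit\tlow\thigh",
               "x\t\tblood\tmmol/L\t5\t5"), tmp)
  expect_error(load_lab_kb(tmp), "low >= high")
  writeLines(c("analyte\tsynonyms\tspecimen\tunit\tlow\thigh",
               "x\t\tblood\t\t4\t10"), tmp)
  expect_error(load_lab_kb(tmp), "canonical unit")
})

test_that("lab KB round-trips through its serialized form", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_lab_kb(fixture_kb, tmp)
  again <- load_lab_kb(tmp)
  expect_equal(unclass(again), unclass(fixture_kb), ignore_attr = TRUE)
})
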