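test_that("run families reduce to the expected pattern classes", {
  expect_equal(reduce_segments(c("AP", "AAP", "AAAP", "AAAAP"))$pattern,
               "A+P")
  expect_equal(reduce_segments(c("SLNU", "LNU"))$pattern, "S*LNU")
  expect_equal(reduce_segments("AP")$pattern, "AP")
  expect_equal(reduce_segments(c("APP", "APPP", "AP", "AAP"))$pattern,
               c("AP+", "A+P"))
  expect_equal(reduce_segments(c("SLR", "LR"))$pattern, "S*LR")
  expect_equal(reduce_segments(c("PCA", "APCA", "PA", "PCAA"))$pattern,
               "A*PC*A+")
})

test_that("conjunction families fold repeated CP into an enumeration", {
  expect_equal(reduce_segments("APCPCP")$pattern, "A+P(CP)+")
  expect_equal(reduce_segments(c("APCP", "AAPCP", "APCPCP"))$pattern,
               "A+P(CP)+")
})

test_that("reduction rejects O and drops uninformative fragments", {
  expect_error(reduce_segments("OAP"), "O-free")
  expect_error(reduce_segments(character(0)), "no segments")
  # punctuation-only edges are trimmed; letters binding no attribute drop
  lib <- reduce_segments(c("APC", "CP", "PP", "NU", "SLN", "PCP"))
  expect_equal(lib$pattern, "AP")
})

test_that("every source segment matches its reduced pattern", {
  pools <- list(c("AP", "AAP", "APP", "SLNU", "LNU", "APCP", "PCA"),
                c("AAAAP", "AP", "APPP", "SLR", "LR", "APCPCP", "APCA"))
  for (segs in pools) {
    lib <- reduce_segments(segs)
    kept <- phenossu:::drop_uninformative(segs)
    for (s in kept)
      expect_true(any(vapply(lib$pattern, function(p)
        phenossu:::pattern_matches_word(p, s), logical(1))),
        info = s)
  }
})

test_that("the built-in library holds the six pattern classes in order", {
  lib <- builtin_library()
  expect_equal(nrow(lib), 6)
  expect_equal(sum(lib$category == "phrase-based"), 4)
  expect_equal(sum(lib$category == "logic-based"), 2)
  expect_true(all(lib$provenance == "builtin"))
  # worked examples from the six classes
  expect_true(phenossu:::pattern_matches_word("A+P(CP)+", "APCP"))
  expect_true(phenossu:::pattern_matches_word("S*LR", "SLR"))
  expect_true(phenossu:::pattern_matches_word("S*LR", "LR"))
  expect_true(phenossu:::pattern_matches_word("A*PC*A+", "PCA"))
  # scan priority: enumeration class outranks its prefix classes
  expect_lt(match("A+P(CP)+", lib$pattern), match("A+P", lib$pattern))
  expect_lt(match("AP+", lib$pattern), match("A+P", lib$pattern))
})

test_that("pattern libraries validate their invariants", {
  expect_error(pattern_library(data.frame(
    pattern = "A+", category = "phrase-based", provenance = "builtin",
    support = 0, review_flag = FALSE)), "without a P")
  expect_error(pattern_library(data.frame(
    pattern = "S*NU", category = "logic-based", provenance = "builtin",
    support = 0, review_flag = FALSE)), "without an L")
  expect_error(pattern_library(data.frame(
    pattern = "A(+P", category = "phrase-based", provenance = "builtin",
    support = 0, review_flag = FALSE)), "compile")
  # duplicates collapse, supports summed
  lib <- pattern_library(data.frame(
    pattern = c("A+P", "A+P"), category = "phrase-based",
    provenance = "discovered", support = c(2L, 3L), review_flag = FALSE))
  expect_equal(nrow(lib), 1)
  expect_equal(lib$support, 5L)
})

test_that("pattern libraries round-trip through their text format", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  lib <- builtin_library()
  write_pattern_library(lib, tmp)
  expect_equal(as.data.frame(read_pattern_library(tmp)),
               as.data.frame(lib))
})

test_that("consolidation drops patterns subsumed by more general ones", {
  lib <- pattern_library(data.frame(
    pattern = c("A+P", "AAP", "S*LNU", "SLNU", "AP+"),
    category = c("phrase-based", "phrase-based", "logic-based",
                 "logic-based", "phrase-based"),
    provenance = "discovered", support = 1L, review_flag = FALSE))
  out <- consolidate_library(lib)
  expect_setequal(out$pattern, c("A+P", "S*LNU", "AP+"))
})
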