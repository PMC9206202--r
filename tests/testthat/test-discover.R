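test_that("discovery recovers two distinct planted words", {
  bg <- skewed_background()
  p1 <- generate_planted_sequences(bg, "AAP", copies = 24, n_seqs = 8,
                                   seq_len = 50, seed = 31)
  p2 <- generate_planted_sequences(bg, "LNU", copies = 24, n_seqs = 8,
                                   seq_len = 50, seed = 32)
  seqs <- c(p1$sequences, p2$sequences)
  motifs <- discover_motifs(seqs, min_w = 2, max_w = 4, n_motifs = 4,
                            n_shuffles = 99, seed = 5)
  consensi <- vapply(motifs, `[[`, character(1), "consensus")
  expect_true(all(c("AAP", "LNU") %in% consensi))
  for (word in c("AAP", "LNU")) {
    m <- motifs[[match(word, consensi)]]
    pl <- if (word == "AAP") p1 else p2
    offset_shift <- if (word == "AAP") 0L else length(p1$sequences)
    planted <- paste(pl$sites$seq + offset_shift, pl$sites$offset)
    found <- paste(m$sites$seq, m$sites$offset)
    expect_gte(mean(planted %in% found), 0.9)
  }
})

test_that("discovered motifs are sorted by E-value and below threshold", {
  bg <- skewed_background()
  pl <- generate_planted_sequences(bg, "AAP", copies = 24, n_seqs = 8,
                                   seq_len = 50, seed = 33)
  motifs <- discover_motifs(pl$sequences, min_w = 2, max_w = 4,
                            n_motifs = 3, n_shuffles = 99, seed = 5)
  ev <- vapply(motifs, `[[`, numeric(1), "evalue")
  expect_true(all(diff(ev) >= 0))
  expect_true(all(ev < 0.05))
})

test_that("sequence order does not change the discovered consensus", {
  bg <- skewed_background()
  pl <- generate_planted_sequences(bg, "APC", copies = 20, n_seqs = 10,
                                   seq_len = 40, seed = 8)
  m1 <- discover_motifs(pl$sequences, min_w = 2, max_w = 4, n_motifs = 1,
                        n_shuffles = 19, seed = 3,
                        evalue_threshold = Inf)
  m2 <- discover_motifs(rev(pl$sequences), min_w = 2, max_w = 4,
                        n_motifs = 1, n_shuffles = 19, seed = 3,
                        evalue_threshold = Inf)
  expect_equal(m1[[1]]$consensus, m2[[1]]$consensus)
})

test_that("short or empty inputs give an empty motif list", {
  expect_equal(discover_motifs(character(0)), list())
  expect_equal(discover_motifs("A", min_w = 2, max_w = 4,
                               n_shuffles = 9), list())
})

test_that("compute_evalue is a seeded rank statistic", {
  bg <- skewed_background()
  pl <- generate_planted_sequences(bg, "AAP", copies = 24, n_seqs = 8,
                                   seq_len = 50, seed = 13)
  m <- em_fit(pl$sequences, 3, "AAP")
  # a strongly planted motif beats every shuffle: minimum attainable value
  m1 <- compute_evalue(m, pl$sequences, n_shuffles = 99, seed = 2,
                       n_widths = 1)
  expect_equal(m1$evalue, 1 / 100)
  m3 <- compute_evalue(m, pl$sequences, n_shuffles = 99, seed = 2,
                       n_widths = 3)
  expect_equal(m3$evalue, 3 / 100)
  # deterministic given the seed
  m1b <- compute_evalue(m, pl$sequences, n_shuffles = 99, seed = 2,
                        n_widths = 1)
  expect_equal(m1b$evalue, m1$evalue)
  expect_error(compute_evalue(m, pl$sequences, n_shuffles = 0), "n_shuffles")
})

test_that("a motif refit on its own shuffled corpus is not significant", {
  bg <- skewed_background()
  pl <- generate_planted_sequences(bg, "AAP", copies = 24, n_seqs = 8,
                                   seq_len = 50, seed = 21)
  shuffled <- withr::with_seed(99, phenossu:::shuffle_corpus(pl$sequences))
  m <- phenossu:::best_motif_for_width(shuffled, 3, fit_background(shuffled))
  pvals <- vapply(1:10, function(r)
    compute_evalue(m, shuffled, n_shuffles = 19, seed = 100 + r,
                   n_widths = 1)$pvalue, numeric(1))
  # calibration: the observed rank among nulls is roughly uniform
  expect_gt(mean(pvals), 0.15)
})
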