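test_that("background frequencies use a 0.1 pseudocount per letter", {
  bg <- fit_background("AAAA")
  expect_equal(unname(bg["A"]), 4.1 / 4.9)
  expect_equal(unname(bg["P"]), 0.1 / 4.9)
  expect_equal(sum(bg), 1)

  # two letters in equal amounts come out symmetric
  bg2 <- fit_background(strrep("AP", 500))
  expect_equal(unname(bg2["A"]), unname(bg2["P"]))
  expect_equal(unname(bg2["A"]), 0.5, tolerance = 1e-3)

  expect_error(fit_background(character(0)), "empty")
  expect_error(fit_background(c("", "")), "empty")
})

test_that("em_fit recovers a planted word and its sites", {
  pl <- generate_planted_sequences(skewed_background(), "AAP", copies = 20,
                                   n_seqs = 10, seq_len = 50,
                                   noise_rate = 0, seed = 7)
  m <- em_fit(pl$sequences, 3, "AAP")
  expect_equal(m$consensus, "AAP")
  planted <- paste(pl$sites$seq, pl$sites$offset)
  found <- paste(m$sites$seq, m$sites$offset)
  expect_gte(sum(planted %in% found), 18)
  expect_true(all(m$sites$posterior > 0.5))
  # PWM rows are proper pseudocounted distributions
  expect_equal(unname(rowSums(m$pwm)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m$pwm > 0))
})

test_that("em_fit degenerate and identity cases behave", {
  # single repeated letter against a non-degenerate background: lambda
  # climbs and the PWM concentrates on that letter (with the background
  # fitted from the same data, motif and background coincide instead)
  m <- em_fit(strrep("P", 40), 2, "PP", background = uniform_background())
  expect_equal(m$consensus, "PP")
  expect_gt(m$lambda, 0.9)
  expect_gt(min(m$pwm[, "P"]), 0.9)

  # infinite tolerance returns the pseudocounted seed PWM unchanged
  m0 <- em_fit(strrep("AP", 20), 2, "AP", tol = Inf)
  expect_equal(unname(m0$pwm[1, "A"]), 1.1 / 1.9, tolerance = 1e-12)
  expect_equal(unname(m0$pwm[2, "P"]), 1.1 / 1.9, tolerance = 1e-12)

  expect_error(em_fit("AP", 5, "AAAAP"), "no window")
  expect_error(em_fit("AP", 1, "A"), "width")
  expect_error(em_fit("AP", 31, strrep("A", 31)), "width")
})

test_that("the EM log-likelihood trace is non-decreasing", {
  for (rep in 1:20) {
    sim <- withr::with_seed(1000 + rep, list(
      seqs = replicate(5, paste(sample(PHENOSSU_ALPHABET, 30,
                                       replace = TRUE), collapse = "")),
      w = sample(2:5, 1)))
    m <- em_fit(sim$seqs, sim$w, substr(sim$seqs[1], 1, sim$w))
    expect_true(all(diff(m$trace) >= -1e-8))
  }
})

test_that("converged EM beats a coarse brute-force PWM grid", {
  # tiny instance: the EM objective (penalized likelihood) at the fitted
  # PWM must be >= its value at every PWM in a coarse grid (probability
  # mass on one letter in {0.05 ... 0.95}, remainder spread evenly),
  # evaluated at the fitted lambda
  seqs <- c("APAPAPAPP", "APAP", "PPA")
  w <- 2
  m <- em_fit(seqs, w, "AP")
  win <- phenossu:::enumerate_windows(seqs, w)
  bg <- fit_background(seqs)
  logbg <- phenossu:::window_logbg(win$mat, bg)
  objective <- function(pwm, lambda) {
    lp <- rowSums(matrix(log(pwm)[cbind(rep(seq_len(w),
                                            each = nrow(win$mat)),
                                        as.vector(win$mat))],
                         nrow = nrow(win$mat)))
    sum(log(lambda * exp(lp) + (1 - lambda) * exp(logbg))) +
      0.1 * sum(log(pwm))
  }
  fitted <- objective(m$pwm, m$lambda)
  expect_equal(fitted, m$trace[length(m$trace)], tolerance = 1e-8)
  peaks <- seq(0.05, 0.95, by = 0.1)
  worst <- -Inf
  for (a1 in seq_along(PHENOSSU_ALPHABET)) {
    for (p1 in peaks) {
      for (a2 in seq_along(PHENOSSU_ALPHABET)) {
        for (p2 in peaks) {
          pwm <- rbind(rep((1 - p1) / 8, 9), rep((1 - p2) / 8, 9))
          pwm[1, a1] <- p1; pwm[2, a2] <- p2
          worst <- max(worst, objective(pwm, m$lambda))
        }
      }
    }
  }
  expect_lte(worst, fitted + 1e-6)
})

test_that("split_on_O extracts O-free segments of length >= 2", {
  expect_equal(split_on_O("OAPO"), "AP")
  expect_equal(split_on_O("AAP"), "AAP")
  expect_equal(split_on_O("OOO"), character(0))
  expect_equal(split_on_O("APOOOSLNUOPO"), c("AP", "SLNU"))
})
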