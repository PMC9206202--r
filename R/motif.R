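#' Fit the order-0 background letter model
#'
#' Empirical letter frequencies over the nine-letter alphabet with a
#' pseudocount added to every letter, renormalized. Masked (`X`) positions
#' are ignored.
#'
#' @param sequences Character vector of letter sequences.
#' @param pseudocount Pseudocount added to each letter (default 0.1).
#' @return A named numeric vector of class `phenossu_background`
#'   (probabilities summing to 1).
#' @examples
#' fit_background("AAAA")["A"]  # (4 + 0.1) / (4 + 0.9)
#' @export
fit_background <- function(sequences, pseudocount = 0.1) {
  chars <- unlist(strsplit(sequences, "", fixed = TRUE))
  chars <- chars[chars != MASK_LETTER]
  if (length(chars) == 0)
    stop("cannot fit background: all sequences are empty", call. = FALSE)
  bad <- setdiff(unique(chars), PHENOSSU_ALPHABET)
  if (length(bad) > 0)
    stop("letter '", bad[1], "' is not in the encoding alphabet", call. = FALSE)
  counts <- table(factor(chars, levels = PHENOSSU_ALPHABET))
  freq <- (as.numeric(counts) + pseudocount) /
    (length(chars) + pseudocount * length(PHENOSSU_ALPHABET))
  structure(stats::setNames(freq, PHENOSSU_ALPHABET),
            class = "phenossu_background")
}

# All width-w windows over the sequences, skipping any window that touches
# a masked letter. Returns NULL when no window exists.
enumerate_windows <- function(sequences, w) {
  mats <- list(); seq_id <- list(); offs <- list()
  for (s in seq_along(sequences)) {
    chars <- strsplit(sequences[s], "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (L < w) next
    codes <- unname(ALPHABET_INDEX[chars]) # NA for masked letters
    valid <- !is.na(codes)
    # window starts whose w positions are all valid
    ok <- which(stats::filter(as.numeric(valid), rep(1, w), sides = 1) == w) -
      w + 1L
    ok <- ok[ok >= 1]
    if (length(ok) == 0) next
    idx <- outer(ok, 0:(w - 1L), `+`)
    mats[[length(mats) + 1L]] <- matrix(codes[idx], nrow = length(ok))
    seq_id[[length(seq_id) + 1L]] <- rep(s, length(ok))
    offs[[length(offs) + 1L]] <- ok
  }
  if (length(mats) == 0) return(NULL)
  list(mat = do.call(rbind, mats),
       seq = unlist(seq_id),
       offset = unlist(offs))
}

window_logbg <- function(mat, background) {
  lb <- log(as.numeric(background))
  rowSums(matrix(lb[mat], nrow = nrow(mat)))
}

seed_pwm <- function(seed_codes, A = length(PHENOSSU_ALPHABET),
                     pseudo = 0.1, seed_weight = 1) {
  w <- length(seed_codes)
  pwm <- matrix(pseudo / (seed_weight + A * pseudo), nrow = w, ncol = A)
  pwm[cbind(seq_len(w), seed_codes)] <-
    (seed_weight + pseudo) / (seed_weight + A * pseudo)
  pwm
}

default_lambda0 <- function(n_windows) {
  min(0.1, sqrt(n_windows) / n_windows)
}

#' Fit one motif by expectation-maximization
#'
#' Fits the two-component mixture ("any number of repetitions") motif
#' model: every length-`w` window of the encoded sequences is
#' independently either a motif site (probability `lambda`, letters drawn
#' from the position weight matrix) or background. The E-step computes
#' per-window site posteriors; the M-step re-estimates the pseudocounted
#' PWM and `lambda`. The EM objective — the penalized log-likelihood
#' corresponding to the pseudocounted update — is non-decreasing over
#' iterations (available as `$trace`). Final sites are chosen
#' greedily by descending posterior, skipping windows that overlap an
#' already chosen site, keeping those with posterior above 0.5.
#'
#' @param sequences Character vector of letter sequences.
#' @param w Motif width, between 2 and 30.
#' @param seed_word A length-`w` letter word used to initialize the PWM.
#' @param background A `phenossu_background` (fitted from `sequences`
#'   when `NULL`).
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6); `Inf` returns the pseudocounted seed PWM unchanged.
#' @param pseudo PWM pseudocount per cell (default 0.1).
#' @param lambda0 Initial site prior; default
#'   `min(0.1, sqrt(n_windows)/n_windows)`.
#' @return An object of class `phenossu_motif`: width, `pwm`, `lambda`,
#'   `sites` (sequence index, 1-based offset, posterior), `llr`
#'   (log-likelihood ratio of the selected sites vs background),
#'   `consensus`, `trace`, `evalue` (`NA` until scored).
#' @export
em_fit <- function(sequences, w, seed_word, background = NULL,
                   max_iter = 200, tol = 1e-6, pseudo = 0.1,
                   lambda0 = NULL) {
  if (w < 2 || w > 30) stop("motif width must be in [2, 30]", call. = FALSE)
  if (nchar(seed_word) != w)
    stop("seed word length must equal the motif width", call. = FALSE)
  win <- enumerate_windows(sequences, w)
  if (is.null(win))
    stop("no window of length ", w, " in the input sequences", call. = FALSE)
  if (is.null(background)) background <- fit_background(sequences)
  logbg <- window_logbg(win$mat, background)
  if (is.null(lambda0)) lambda0 <- default_lambda0(nrow(win$mat))
  pwm0 <- seed_pwm(letters_to_codes(seed_word), pseudo = pseudo)
  fit <- em_tcm_cpp(win$mat, logbg, pwm0, lambda0, as.integer(max_iter),
                    tol, pseudo)
  finish_motif(fit, win, w, background)
}

finish_motif <- function(fit, win, w, background) {
  pwm <- fit$pwm
  dimnames(pwm) <- list(NULL, PHENOSSU_ALPHABET)
  consensus <- paste(PHENOSSU_ALPHABET[apply(pwm, 1, which.max)],
                     collapse = "")
  sites <- select_sites(fit$z, win, w)
  # log-likelihood ratio of the selected sites under the motif model
  # versus the background model
  llr <- if (nrow(sites) == 0) 0 else
    sum(fit$logpm[sites$window] - window_logbg(
      win$mat[sites$window, , drop = FALSE], background))
  site_words <- if (nrow(sites) == 0) character(0) else
    apply(win$mat[sites$window, , drop = FALSE], 1, codes_to_letters)
  structure(list(width = w, pwm = pwm, lambda = fit$lambda,
                 sites = sites[, c("seq", "offset", "posterior")],
                 site_words = site_words,
                 llr = llr, evalue = NA_real_, consensus = consensus,
                 trace = fit$trace, nsites = nrow(sites)),
            class = "phenossu_motif")
}

select_sites <- function(z, win, w, cutoff = 0.5) {
  cand <- which(z > cutoff)
  cand <- cand[order(-z[cand])]
  taken <- list()
  keep <- integer(0)
  for (i in cand) {
    s <- win$seq[i]; a <- win$offset[i]; b <- a + w - 1L
    iv <- taken[[as.character(s)]]
    if (!is.null(iv) && any(a <= iv[, 2] & b >= iv[, 1])) next
    taken[[as.character(s)]] <- rbind(iv, c(a, b))
    keep <- c(keep, i)
  }
  keep <- keep[order(win$seq[keep], win$offset[keep])]
  data.frame(seq = win$seq[keep], offset = win$offset[keep],
             posterior = z[keep], window = keep)
}

#' @export
print.phenossu_motif <- function(x, ...) {
  cat(sprintf("Motif  width=%d  consensus=%s  sites=%d  lambda=%.4g  llr=%.2f",
              x$width, x$consensus, x$nsites, x$lambda, x$llr))
  if (!is.na(x$evalue)) cat(sprintf("  E=%.4g", x$evalue))
  cat("\n")
  invisible(x)
}

#' Split a motif consensus on the filler letter
#'
#' Motifs frequently straddle stretches of non-phenotype text (`O`).
#' This extracts the maximal `O`-free substrings of a consensus word,
#' dropping fragments shorter than two letters.
#'
#' @param consensus A letter word (or vector of words).
#' @return Character vector of `O`-free segments, in order.
#' @examples
#' split_on_O("OAPO")  # "AP"
#' @export
split_on_O <- function(consensus) {
  segs <- unlist(strsplit(consensus, "O+", perl = TRUE))
  segs[!is.na(segs) & nchar(segs) >= 2]
}
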