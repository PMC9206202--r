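# Corpus as one flat integer code vector (NA at masked letters and
# sequence boundaries are kept apart via the per-sequence index map).
flatten_corpus <- function(sequences) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  codes <- unname(ALPHABET_INDEX[unlist(chars)])
  lens <- lengths(chars)
  list(codes = codes, lens = lens, starts = cumsum(lens) - lens + 1L)
}

# window start positions (into the flat code vector) for width w,
# independent of letter identity except for masking
window_index <- function(flat, w) {
  valid <- !is.na(flat$codes)
  ok <- integer(0); seq_id <- integer(0); offs <- integer(0)
  for (s in seq_along(flat$lens)) {
    L <- flat$lens[s]
    if (L < w) next
    v <- valid[flat$starts[s]:(flat$starts[s] + L - 1L)]
    runs <- which(stats::filter(as.numeric(v), rep(1, w), sides = 1) == w) -
      w + 1L
    runs <- runs[runs >= 1]
    if (length(runs) == 0) next
    ok <- c(ok, flat$starts[s] + runs - 1L)
    seq_id <- c(seq_id, rep(s, length(runs)))
    offs <- c(offs, runs)
  }
  if (length(ok) == 0) return(NULL)
  list(idx = outer(ok, 0:(w - 1L), `+`), seq = seq_id, offset = offs, w = w)
}

# most frequent distinct w-mers among the window rows (the EM warm-start
# seeds); exact integer keys for w <= 16, string keys beyond
top_seed_rows <- function(mat, seed_cap) {
  w <- ncol(mat)
  if (w <= 16) {
    key <- as.vector(mat %*% 9^(0:(w - 1)))
  } else {
    key <- do.call(paste, c(lapply(seq_len(w), function(k) mat[, k]),
                            list(sep = ".")))
  }
  ord <- order(key)
  r <- rle(key[ord])
  # tie-break frequency ties on the key itself so that seed choice does
  # not depend on the order the sequences were supplied in
  top <- order(-r$lengths, r$values)[seq_len(min(length(r$lengths),
                                                 seed_cap))]
  first_of_run <- cumsum(r$lengths) - r$lengths + 1L
  mat[ord[first_of_run[top]], , drop = FALSE]
}

# The `refine_top` best warm starts are run to convergence and the fit
# with the largest site LLR wins; a single EM basin can absorb a genuine
# motif into a diffuse high-likelihood fit, and refining a handful of
# starts makes the search robust to that.
best_motif_fit <- function(windows, logbg, seed_cap, max_iter, tol, pseudo,
                           wi = NULL, refine_top = 5) {
  seeds <- top_seed_rows(windows, seed_cap)
  lambda0 <- default_lambda0(nrow(windows))
  scores <- warm_start_scores_cpp(windows, logbg, seeds, lambda0, pseudo,
                                  1.0, length(PHENOSSU_ALPHABET))
  if (is.null(wi))
    wi <- list(seq = rep(1L, nrow(windows)),
               offset = seq_len(nrow(windows)), w = ncol(windows))
  cand <- order(-scores)[seq_len(min(refine_top, nrow(seeds)))]
  best_fit <- NULL
  best_llr <- -Inf
  for (ci in cand) {
    pwm0 <- seed_pwm(seeds[ci, ], pseudo = pseudo)
    fit <- em_tcm_cpp(windows, logbg, pwm0, lambda0, as.integer(max_iter),
                      tol, pseudo)
    llr <- fit_llr(fit, windows, wi, logbg)
    if (llr > best_llr) {
      best_llr <- llr
      best_fit <- fit
    }
  }
  best_fit
}

# Best motif for one width: every distinct w-mer present in the data seeds
# a one-iteration EM warm start (capped at the seed_cap most frequent
# w-mers on large inputs); the best warm start by likelihood is run to
# convergence.
best_motif_for_width <- function(sequences, w, background,
                                 seed_cap = 100, max_iter = 200,
                                 tol = 1e-6, pseudo = 0.1) {
  win <- enumerate_windows(sequences, w)
  if (is.null(win)) return(NULL)
  logbg <- window_logbg(win$mat, background)
  fit <- best_motif_fit(win$mat, logbg, seed_cap, max_iter, tol, pseudo,
                        wi = list(seq = win$seq, offset = win$offset,
                                  w = w))
  finish_motif(fit, win, w, background)
}

background_from_codes <- function(codes, pseudocount = 0.1) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0)
    stop("cannot fit background: all sequences are empty", call. = FALSE)
  counts <- tabulate(codes, nbins = length(PHENOSSU_ALPHABET))
  freq <- (counts + pseudocount) /
    (length(codes) + pseudocount * length(PHENOSSU_ALPHABET))
  structure(stats::setNames(freq, PHENOSSU_ALPHABET),
            class = "phenossu_background")
}

# site-sum LLR of a fit without building the full motif object
fit_llr <- function(fit, mat, wi, logbg) {
  sites <- select_sites(fit$z, list(seq = wi$seq, offset = wi$offset), wi$w)
  if (nrow(sites) == 0) return(0)
  sum(fit$logpm[sites$window] - logbg[sites$window])
}

# Composition-preserving shuffle: permute all unmasked letters across the
# corpus, keeping sequence lengths and mask positions fixed.
shuffle_corpus <- function(sequences) {
  split_seqs <- strsplit(sequences, "", fixed = TRUE)
  pool <- unlist(split_seqs)
  free <- which(pool != MASK_LETTER)
  pool[free] <- pool[sample(free)]
  lens <- lengths(split_seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(lens), function(i)
    paste(pool[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Discover motifs by sequential EM with a Monte-Carlo significance test
#'
#' For each width in `[min_w, max_w]` (restricted to widths for which at
#' least one window exists), every distinct w-mer in the data seeds a
#' one-iteration EM warm start and the best warm start is run to
#' convergence. Each width's converged motif is scored against a
#' composition-preserving shuffle null: the same per-width search is rerun
#' on `n_shuffles` letter-permuted corpora and the motif's E-value is
#' `p * n_widths` with `p = (1 + #null LLR >= observed LLR) /
#' (n_shuffles + 1)`. The motif with the smallest E-value (ties broken by
#' the null z-score of the LLR) is reported, its sites are masked with the
#' reserved letter `X`, and the search repeats until `n_motifs` motifs are
#' found or no motif passes `evalue_threshold`.
#'
#' @param sequences Character vector of encoded letter sequences.
#' @param min_w,max_w Width bounds (defaults 2 and 30).
#' @param n_motifs Maximum number of motifs to report (default 20).
#' @param n_shuffles Monte-Carlo null size per round (default 199). The
#'   smallest attainable E-value is `n_widths / (n_shuffles + 1)`, so the
#'   null must be large enough for the significance threshold to be
#'   reachable.
#' @param evalue_threshold Stop when the best E-value reaches this
#'   (default 0.05).
#' @param seed Integer seed; all randomness (the null shuffles) flows from
#'   it.
#' @param seed_cap Maximum number of warm-start seed words per width
#'   (the most frequent w-mers are kept; default 100).
#' @param max_iter,tol,pseudo EM controls passed to the fitter.
#' @param width_penalty Per-parameter penalty used to break E-value ties
#'   between widths: the selected motif maximizes
#'   `llr - width_penalty * w * (A - 1)` among minimal-E widths. The
#'   default 1 is the AIC-style penalty; `"bic"` uses
#'   `0.5 * log(n_windows)` instead.
#' @return A list of `phenossu_motif` objects sorted by ascending
#'   E-value, each carrying `evalue`, `pvalue`, `null_mean`, `null_sd`,
#'   and `widths_scanned`.
#' @export
discover_motifs <- function(sequences, min_w = 2, max_w = 30, n_motifs = 20,
                            n_shuffles = 199, evalue_threshold = 0.05,
                            seed = 1, seed_cap = 100, max_iter = 200,
                            tol = 1e-6, pseudo = 0.1,
                            width_penalty = 1) {
  if (length(sequences) == 0 || all(!nzchar(sequences)))
    return(list())
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  flat <- flatten_corpus(sequences)
  motifs <- list()
  lb_alpha <- function(bg) log(as.numeric(bg))
  with_seed(seed, {
    for (round in seq_len(n_motifs)) {
      if (all(is.na(flat$codes))) break
      background <- background_from_codes(flat$codes)
      lb <- lb_alpha(background)
      wins <- list()
      for (w in min_w:max_w) {
        wi <- window_index(flat, w)
        if (!is.null(wi)) wins[[as.character(w)]] <- wi
      }
      if (length(wins) == 0) break
      widths <- as.integer(names(wins))
      obs <- vector("list", length(widths))
      obs_llr <- numeric(length(widths))
      for (j in seq_along(widths)) {
        wi <- wins[[j]]
        mat <- matrix(flat$codes[wi$idx], nrow = nrow(wi$idx))
        logbg <- rowSums(matrix(lb[mat], nrow = nrow(mat)))
        fit <- best_motif_fit(mat, logbg, seed_cap, max_iter, tol, pseudo,
                              wi = wi)
        obs[[j]] <- finish_motif(fit, list(mat = mat, seq = wi$seq,
                                           offset = wi$offset),
                                 widths[j], background)
        obs_llr[j] <- obs[[j]]$llr
      }
      null_llr <- matrix(NA_real_, nrow = n_shuffles, ncol = length(widths))
      free <- which(!is.na(flat$codes))
      for (s in seq_len(n_shuffles)) {
        codes_s <- flat$codes
        codes_s[free] <- codes_s[sample(free)]
        for (j in seq_along(widths)) {
          wi <- wins[[j]]
          mat <- matrix(codes_s[wi$idx], nrow = nrow(wi$idx))
          logbg <- rowSums(matrix(lb[mat], nrow = nrow(mat)))
          fit <- best_motif_fit(mat, logbg, seed_cap, max_iter, tol, pseudo,
                                wi = wi)
          null_llr[s, j] <- fit_llr(fit, mat, wi, logbg)
        }
      }
      pvals <- vapply(seq_along(widths), function(j)
        (1 + sum(null_llr[, j] >= obs_llr[j])) / (n_shuffles + 1), numeric(1))
      evals <- pvals * length(widths)
      nmu <- colMeans(null_llr)
      nsd <- apply(null_llr, 2, stats::sd)
      zsc <- ifelse(nsd > 0, (obs_llr - nmu) / nsd,
                    ifelse(obs_llr > nmu, Inf, 0))
      # E-values from a rank null saturate for every strongly supported
      # width; break ties by penalized likelihood (BIC-style penalty on
      # the w x (A-1) free PWM parameters, against the number of windows
      # the model was fitted on), then by the narrower width
      A <- length(PHENOSSU_ALPHABET)
      n_win <- vapply(wins, function(x) nrow(x$idx), integer(1))
      pen <- if (identical(width_penalty, "bic")) 0.5 * log(n_win) else
        as.numeric(width_penalty)
      score <- obs_llr - pen * widths * (A - 1)
      best <- order(evals, -score, widths)[1]
      if (evals[best] >= evalue_threshold) break
      motif <- obs[[best]]
      motif$evalue <- evals[best]
      motif$pvalue <- pvals[best]
      motif$null_mean <- nmu[best]
      motif$null_sd <- nsd[best]
      motif$zscore <- zsc[best]
      motif$widths_scanned <- length(widths)
      motifs[[length(motifs) + 1L]] <- motif
      if (nrow(motif$sites) == 0) break
      for (i in seq_len(nrow(motif$sites))) {
        a <- flat$starts[motif$sites$seq[i]] + motif$sites$offset[i] - 1L
        flat$codes[a:(a + motif$width - 1L)] <- NA_integer_
      }
    }
  })
  motifs[order(vapply(motifs, `[[`, numeric(1), "evalue"))]
}

#' Monte-Carlo E-value of a fitted motif
#'
#' Estimates the motif's statistical significance from its log-likelihood
#' ratio: the corpus letters are permuted (composition-preserving)
#' `n_shuffles` times, the width-`w` best-warm-start EM search is rerun on
#' each permuted corpus, and the rank of the observed LLR among the null
#' LLRs gives `p = (1 + #null >= observed) / (n_shuffles + 1)`. The
#' E-value is `p * n_widths`, the Bonferroni factor for the number of
#' widths scanned during discovery.
#'
#' @param motif A `phenossu_motif`.
#' @param sequences The sequences the motif was fitted on.
#' @param background A `phenossu_background` (refitted when `NULL`).
#' @param n_shuffles Number of null permutations (at least 1).
#' @param seed Integer seed.
#' @param n_widths Bonferroni width factor; defaults to the motif's
#'   recorded `widths_scanned`, else 1.
#' @param ... Passed to the per-width search (`seed_cap`, `max_iter`,
#'   `tol`, `pseudo`).
#' @return The motif with `evalue`, `pvalue`, `null_mean`, `null_sd`
#'   filled in.
#' @export
compute_evalue <- function(motif, sequences, background = NULL,
                           n_shuffles = 99, seed = 1, n_widths = NULL, ...) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  if (is.null(background)) background <- fit_background(sequences)
  if (is.null(n_widths)) n_widths <- motif$widths_scanned %||% 1
  null_llr <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      shuf <- shuffle_corpus(sequences)
      m <- best_motif_for_width(shuf, motif$width, background, ...)
      if (is.null(m)) -Inf else m$llr
    }, numeric(1))
  })
  p <- (1 + sum(null_llr >= motif$llr)) / (n_shuffles + 1)
  motif$pvalue <- p
  motif$evalue <- p * n_widths
  motif$null_mean <- mean(null_llr)
  motif$null_sd <- stats::sd(null_llr)
  motif
}
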