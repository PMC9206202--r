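# number grammar: optional sign, digits (ASCII or full-width), optional
# decimal part, then optionally a power-of-ten suffix ("x10^9", "x109",
# full-width multiplication sign accepted) or e-notation. The whole token
# becomes one N letter whose payload is the evaluated value.
NUMBER_RE <- paste0(
  "^[-+]?[0-9０-９]+",
  "(?:[.．][0-9０-９]+)?",
  "(?:",
    "(?:\\s*[×xX*]\\s*10(?:\\^[-+]?[0-9０-９]+|[0-9０-９]+)?)",
    "|(?:[eE][-+][0-9]+)|(?:[eE][0-9]+)",
  ")?"
)

normalize_digits <- function(s) {
  chartr(paste0("０１２３４５６７８９",
                "．×"),
         "0123456789.x", s)
}

parse_number_token <- function(s) {
  s <- gsub("\\s+", "", normalize_digits(s))
  if (grepl("[xX*]", s)) {
    parts <- strsplit(s, "[xX*]10", perl = TRUE)[[1]]
    base <- as.numeric(parts[1])
    expo <- if (length(parts) < 2 || !nzchar(parts[2])) 1 else
      as.numeric(sub("^\\^", "", parts[2]))
    base * 10^expo
  } else {
    as.numeric(s)
  }
}

#' Encode free text as a single-letter sequence
#'
#' Scans the text left to right. At every position the longest lexicon
#' surface form starting there wins (leftmost-longest keyword matching);
#' failing that, a numeric literal is consumed as one `N` letter with its
#' evaluated value (so `12.5x10^9` is a single `N` with payload 1.25e10).
#' Every maximal run of remaining characters collapses to a single `O`
#' letter; runs consisting only of whitespace are absorbed into the span
#' of the neighbouring letter, so the letter spans always tile the source
#' text exactly. Which characters count as pattern punctuation (`C`) is
#' controlled entirely by `C` entries in the lexicon.
#'
#' @param text A length-one UTF-8 character string (may be empty).
#' @param lexicon A `phenossu_lexicon`.
#' @return An object of class `phenossu_encoding` with elements
#'   `letters` (single string over the alphabet), `start`/`end`
#'   (0-based half-open character offsets per letter), `payload`
#'   (per-letter list: lexicon normalization for `P`/`A`/`S`/`L`/`R`/`U`,
#'   numeric value for `N`, `NULL` for `C`/`O`), and `source`.
#' @examples
#' lex <- as_lexicon(data.frame(
#'   surface = c("severe", "cough"), letter = c("A", "P"),
#'   category = c("severity", ""), normalization = c("severe", "cough")))
#' enc <- encode("severe cough today", lex)
#' enc$letters
#' @export
encode <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1)
  text <- enc2utf8(text)
  n <- nchar(text)
  surfaces <- lexicon$surface
  by_first <- list()
  if (length(surfaces) > 0) {
    firsts <- substr(surfaces, 1, 1)
    by_first <- lapply(split(seq_along(surfaces), firsts), function(ix)
      ix[order(-nchar(surfaces[ix]))])  # longest surface tried first
  }

  tok_letter <- character(0); tok_start <- integer(0); tok_end <- integer(0)
  tok_payload <- list()
  gap_start <- integer(0); gap_end <- integer(0) # unmatched runs, 1-based incl.
  pos <- 1L
  open_gap <- NA_integer_
  close_gap <- function(upto) {
    if (!is.na(open_gap)) {
      gap_start <<- c(gap_start, open_gap)
      gap_end <<- c(gap_end, upto)
      open_gap <<- NA_integer_
    }
  }
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    hit <- NULL
    for (i in by_first[[ch]] %||% integer(0)) {
      nc <- nchar(surfaces[i])
      if (pos + nc - 1L <= n && substr(text, pos, pos + nc - 1L) == surfaces[i]) {
        hit <- i
        break
      }
    }
    if (!is.null(hit)) {
      close_gap(pos - 1L)
      letter <- lexicon$letter[hit]
      tok_letter <- c(tok_letter, letter)
      tok_start <- c(tok_start, pos)
      tok_end <- c(tok_end, pos + nchar(surfaces[hit]) - 1L)
      tok_payload[[length(tok_letter)]] <- lexicon_payload(lexicon, hit)
      pos <- pos + nchar(surfaces[hit])
      next
    }
    m <- regexpr(NUMBER_RE, substring(text, pos), perl = TRUE)
    if (m[1] == 1L && attr(m, "match.length") > 0) {
      len <- attr(m, "match.length")
      tokstr <- substr(text, pos, pos + len - 1L)
      close_gap(pos - 1L)
      tok_letter <- c(tok_letter, "N")
      tok_start <- c(tok_start, pos)
      tok_end <- c(tok_end, pos + len - 1L)
      tok_payload[[length(tok_letter)]] <- parse_number_token(tokstr)
      pos <- pos + len
      next
    }
    if (is.na(open_gap)) open_gap <- pos
    pos <- pos + 1L
  }
  close_gap(n)

  # weave gaps back in: whitespace-only runs widen a neighbouring span,
  # anything else becomes one O letter per maximal run
  out_letter <- character(0); out_start <- integer(0); out_end <- integer(0)
  out_payload <- list()
  push <- function(letter, s, e, payload) {
    out_letter <<- c(out_letter, letter)
    out_start <<- c(out_start, s)
    out_end <<- c(out_end, e)
    # list assignment that keeps NULL payloads as elements
    out_payload[length(out_letter)] <<- list(payload)
  }
  all_events <- order(c(tok_start, gap_start))
  ev_kind <- c(rep("tok", length(tok_start)), rep("gap", length(gap_start)))
  ev_idx <- c(seq_along(tok_start), seq_along(gap_start))
  pending_ws_start <- NA_integer_
  for (k in all_events) {
    if (ev_kind[k] == "tok") {
      i <- ev_idx[k]
      s <- tok_start[i]
      if (!is.na(pending_ws_start)) {
        s <- pending_ws_start
        pending_ws_start <- NA_integer_
      }
      push(tok_letter[i], s, tok_end[i], tok_payload[[i]])
    } else {
      i <- ev_idx[k]
      run <- substr(text, gap_start[i], gap_end[i])
      if (grepl("^\\s+$", run)) {
        if (length(out_letter) > 0)
          out_end[length(out_letter)] <- gap_end[i]  # widen previous letter
        else
          pending_ws_start <- gap_start[i]           # widen the next letter
      } else {
        s <- gap_start[i]
        if (!is.na(pending_ws_start)) {
          s <- pending_ws_start
          pending_ws_start <- NA_integer_
        }
        push("O", s, gap_end[i], NULL)
      }
    }
  }
  if (!is.na(pending_ws_start)) # whitespace-only document
    push("O", pending_ws_start, n, NULL)

  structure(list(letters = paste(out_letter, collapse = ""),
                 start = out_start - 1L,    # 0-based half-open
                 end = out_end,
                 payload = out_payload,
                 source = text),
            class = "phenossu_encoding")
}

lexicon_payload <- function(lexicon, i) {
  cat_i <- lexicon$category[i]
  list(normalization = lexicon$normalization[i],
       category = if (!is.na(cat_i) && nzchar(cat_i)) cat_i else NULL,
       surface = lexicon$surface[i])
}

#' @export
print.phenossu_encoding <- function(x, ...) {
  cat("Encoded sequence:", x$letters, "\n")
  df <- encoding_to_df(x)
  print(df, ...)
  invisible(x)
}

#' Tabular view of an encoded sequence
#' @param enc A `phenossu_encoding`.
#' @return A data frame with one row per letter: `letter`, `start`, `end`
#'   (0-based half-open), `surface`, `payload` (character rendering).
#' @export
encoding_to_df <- function(enc) {
  letters_v <- strsplit(enc$letters, "", fixed = TRUE)[[1]]
  surf <- vapply(seq_along(letters_v), function(i)
    substr(enc$source, enc$start[i] + 1L, enc$end[i]), character(1))
  pay <- vapply(enc$payload, function(p) {
    if (is.null(p)) "" else if (is.numeric(p)) format(p) else
      p$normalization %||% ""
  }, character(1))
  data.frame(letter = letters_v, start = enc$start, end = enc$end,
             surface = surf, payload = pay, stringsAsFactors = FALSE)
}

#' Map letter positions back to the source text
#'
#' Returns the smallest character interval covering letters `from..to`
#' of the encoding, as 0-based half-open offsets (the convention used by
#' brat standoff annotation), together with the covered substring.
#'
#' @param enc A `phenossu_encoding`.
#' @param from,to 1-based letter indices, `from <= to`.
#' @return A list with `start`, `end` (0-based half-open character
#'   offsets) and `text` (the substring `source[start:end]`).
#' @export
decode_span <- function(enc, from, to = from) {
  n <- nchar(enc$letters)
  if (!(from >= 1 && to >= from && to <= n))
    stop("index error: letter indices out of range [1, ", n, "]", call. = FALSE)
  start <- enc$start[from]
  end <- enc$end[to]
  list(start = start, end = end,
       text = substr(enc$source, start + 1L, end))
}
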