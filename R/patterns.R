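# ---- pattern library container ---------------------------------------------

literal_skeleton <- function(pattern) {
  gsub("[^PACOSLNUR]", "", pattern)
}

#' Build a linguistic-pattern library
#'
#' A pattern library is an ordered set of regular expressions over the
#' encoding alphabet. Scan priority is longest literal skeleton first
#' (the letters of the pattern with operators removed), then insertion
#' order, so that specific patterns such as `A+P(CP)+` win over their
#' prefixes such as `A+P`. Duplicate pattern texts are collapsed
#' (supports summed, earliest provenance kept).
#'
#' @param patterns Data frame with columns `pattern`, `category`
#'   (`phrase-based`/`logic-based`), `provenance`
#'   (`builtin`/`discovered`/`enriched`), `support`, `review_flag`.
#' @return A data frame of class `phenossu_pattern_library`, in scan
#'   priority order.
#' @export
pattern_library <- function(patterns) {
  df <- data.frame(pattern = as.character(patterns$pattern),
                   category = as.character(patterns$category),
                   provenance = as.character(patterns$provenance %||% "discovered"),
                   support = as.integer(patterns$support %||% 0L),
                   review_flag = as.logical(patterns$review_flag %||% FALSE),
                   stringsAsFactors = FALSE)
  for (p in df$pattern) {
    ok <- tryCatch({grepl(paste0("^(?:", p, ")$"), "", perl = TRUE); TRUE},
                   error = function(e) FALSE,
                   warning = function(e) FALSE)
    if (!ok) stop("pattern does not compile: '", p, "'", call. = FALSE)
  }
  bad <- df$pattern[df$category == "phrase-based" &
                      !grepl("P", df$pattern, fixed = TRUE)]
  if (length(bad) > 0)
    stop("phrase-based pattern without a P letter: '", bad[1], "'",
         call. = FALSE)
  bad <- df$pattern[df$category == "logic-based" &
                      !grepl("L", df$pattern, fixed = TRUE)]
  if (length(bad) > 0)
    stop("logic-based pattern without an L letter: '", bad[1], "'",
         call. = FALSE)
  if (anyDuplicated(df$pattern)) {
    agg <- split(seq_len(nrow(df)), df$pattern)
    keep <- vapply(agg, `[`, integer(1), 1)
    supp <- vapply(agg, function(ix) sum(df$support[ix]), integer(1))
    df_first <- df[sort(keep), , drop = FALSE]
    df_first$support <- supp[df_first$pattern]
    df <- df_first
  }
  ord <- order(-nchar(literal_skeleton(df$pattern)), seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phenossu_pattern_library", "data.frame")
  df
}

#' The six built-in linguistic-pattern classes
#'
#' Four phrase-based classes — `A+P(CP)+` (attributes distributed over an
#' enumerated list of phenotypes), `AP+` (one attribute over several
#' phenotypes), `A+P` (stacked attributes before one phenotype),
#' `A*PC*A+` (trailing attributes after the phenotype) — and two
#' logic-based classes — `S*LNU` (specimen, analyte, number, unit) and
#' `S*LR` (specimen, analyte, result direction word).
#'
#' @return A `phenossu_pattern_library` of the six classes,
#'   provenance `builtin`.
#' @export
builtin_library <- function() {
  pattern_library(data.frame(
    pattern = c("A+P(CP)+", "AP+", "A+P", "A*PC*A+", "S*LNU", "S*LR"),
    category = c(rep("phrase-based", 4), rep("logic-based", 2)),
    provenance = "builtin",
    support = 0L,
    review_flag = FALSE,
    stringsAsFactors = FALSE))
}

#' Combine two pattern libraries
#' @param library A `phenossu_pattern_library`.
#' @param new_patterns A data frame of additional patterns.
#' @return The combined, re-prioritized library.
#' @export
library_add <- function(library, new_patterns) {
  pattern_library(rbind(as.data.frame(library),
                        as.data.frame(pattern_library(new_patterns))))
}

pattern_matches_word <- function(pattern, word) {
  grepl(paste0("^(?:", pattern, ")$"), word, perl = TRUE)
}

# ---- reduction: segments -> pattern classes ---------------------------------

# Tokenize a letter word into runs, folding enumeration conjunctions:
# any repetition of (C P) pairs following a P becomes one "(CP)+" token.
tokenize_word <- function(word) {
  r <- rle(strsplit(word, "", fixed = TRUE)[[1]])
  toks <- list()
  seen_p <- FALSE
  i <- 1
  while (i <= length(r$values)) {
    v <- r$values[i]; n <- r$lengths[i]
    if (seen_p && v == "C" && n == 1 && i < length(r$values) &&
        r$values[i + 1] == "P" && r$lengths[i + 1] == 1) {
      # consume all (C,P) pairs
      while (i < length(r$values) && r$values[i] == "C" &&
             r$lengths[i] == 1 && r$values[i + 1] == "P" &&
             r$lengths[i + 1] == 1) {
        i <- i + 2
      }
      toks[[length(toks) + 1]] <- list(label = "CP", count = NA_integer_)
      next
    }
    if (v == "P") seen_p <- TRUE
    toks[[length(toks) + 1]] <- list(label = v, count = n)
    i <- i + 1
  }
  toks
}

token_skeleton <- function(toks) {
  paste(vapply(toks, `[[`, character(1), "label"), collapse = "|")
}

# A reduction family: one skeleton plus the set of observed run counts at
# every token position, and the source words it covers.
new_family <- function(skeleton, counts, words) {
  list(skeleton = strsplit(skeleton, "|", fixed = TRUE)[[1]],
       counts = counts,   # list of integer vectors, one per token
       words = words)
}

family_pattern <- function(fam) {
  sk <- fam$skeleton
  has_cp <- any(sk == "CP")
  first_p <- match("P", sk)
  out <- character(length(sk))
  for (i in seq_along(sk)) {
    if (sk[i] == "CP") { out[i] <- "(CP)+"; next }
    cts <- sort(unique(fam$counts[[i]]))
    letter <- sk[i]
    if (has_cp && letter == "A" && !is.na(first_p) && i < first_p) {
      # conjunction rule: the attribute block distributes over an open
      # list of phenotypes, so its repetition is open-ended too
      out[i] <- if (0 %in% cts) paste0(letter, "*") else paste0(letter, "+")
    } else if (0 %in% cts) {
      out[i] <- paste0(letter, "*")
    } else if (length(cts) == 1) {
      out[i] <- strrep(letter, cts)
    } else {
      out[i] <- paste0(letter, "+")
    }
  }
  paste(out, collapse = "")
}

# can skeleton `fs` be aligned into `gs` deleting only eligible positions
# of gs? returns the aligned gs-position for each fs token, or NULL.
align_skeleton <- function(fs, gs, eligible) {
  rec <- function(i, j) {
    if (i > length(fs)) {
      if (j > length(gs)) return(integer(0))
      if (all(eligible[j:length(gs)])) return(integer(0))
      return(NULL)
    }
    if (j > length(gs)) return(NULL)
    if (fs[i] == gs[j]) {
      rest <- rec(i + 1, j + 1)
      if (!is.null(rest)) return(c(j, rest))
    }
    if (eligible[j]) return(rec(i, j + 1))
    NULL
  }
  rec(1, 1)
}

# positions of gs that may be absent in family members: specimen and
# punctuation runs, and attribute runs occurring before the first P
eligible_positions <- function(sk) {
  first_p <- match("P", sk)
  vapply(seq_along(sk), function(i)
    sk[i] %in% c("S", "C") ||
      (sk[i] == "A" && !is.na(first_p) && i < first_p), logical(1))
}

drop_uninformative <- function(words) {
  words <- gsub("^C+|C+$", "", words)      # edge punctuation binds nothing
  words <- words[nchar(words) >= 2]
  is_logic <- grepl("L", words, fixed = TRUE)
  keep_logic <- is_logic & grepl("(NU|R)", words, perl = TRUE)
  keep_phrase <- !is_logic & grepl("P", words, fixed = TRUE) &
    grepl("A", words, fixed = TRUE)
  words[keep_logic | keep_phrase]
}

#' Reduce letter segments to regular-expression pattern classes
#'
#' Each segment is decomposed into maximal letter runs; repetitions of
#' `CP` pairs after a phenotype fold into a `(CP)+` enumeration group.
#' Segments with the same run skeleton form a family; within a family a
#' run whose length varies across members abstracts to `X+`, a constant
#' run stays literal. When several run positions vary within one
#' skeleton, the family is split so that each resulting family varies in
#' one position only (this is what separates `A+P` from `AP+`). Families
#' whose skeleton differs from a larger family's only by absent
#' specimen/punctuation runs or absent pre-phenotype attribute runs are
#' merged, the absent runs becoming `X*`. Segments that bind no
#' attribute-bearing letter (no `A`/`S`/`L`/`R`), or that carry a number
#' with no following unit, are dropped: they cannot drive attribute
#' prediction. Every surviving source segment matches its output pattern.
#'
#' @param segments Character vector of `O`-free letter words.
#' @param provenance Provenance recorded on the output patterns.
#' @param review_flag Review flag recorded on the output patterns.
#' @return A `phenossu_pattern_library` (possibly empty).
#' @examples
#' reduce_segments(c("AP", "AAP", "AAAP", "AAAAP"))$pattern  # "A+P"
#' @export
reduce_segments <- function(segments, provenance = "discovered",
                            review_flag = FALSE) {
  if (length(segments) == 0)
    stop("no segments to reduce", call. = FALSE)
  if (any(grepl("O", segments, fixed = TRUE)))
    stop("segments must be O-free (use split_on_O first)", call. = FALSE)
  words <- drop_uninformative(unique(segments))
  if (length(words) == 0) return(empty_library())

  toks <- lapply(words, tokenize_word)
  skels <- vapply(toks, token_skeleton, character(1))

  families <- list()
  for (sk in unique(skels)) {
    ix <- which(skels == sk)
    sk_v <- strsplit(sk, "|", fixed = TRUE)[[1]]
    counts_by_word <- lapply(toks[ix], function(tt)
      vapply(tt, function(t) t$count %||% NA_integer_, integer(1)))
    cmat <- do.call(rbind, counts_by_word)   # words x positions (NA for CP)
    run_pos <- which(sk_v != "CP")
    varying <- run_pos[apply(cmat[, run_pos, drop = FALSE], 2, function(x)
      length(unique(x)) > 1)]
    if (length(varying) <= 1) {
      families[[length(families) + 1]] <- new_family(
        sk, lapply(seq_along(sk_v), function(j) unique(cmat[, j])), words[ix])
    } else {
      # split: each member with at most one over-length run joins that
      # run's family; all-ones members join the first varying position
      assign_pos <- vapply(seq_along(ix), function(r) {
        over <- run_pos[cmat[r, run_pos] > 1]
        if (length(over) == 0) varying[1]        # all-ones member
        else if (length(over) == 1) over
        else NA_integer_                          # varies in >1 dimension
      }, integer(1))
      for (p in unique(assign_pos[!is.na(assign_pos)])) {
        rows <- which(assign_pos == p)
        families[[length(families) + 1]] <- new_family(
          sk, lapply(seq_along(sk_v), function(j) unique(cmat[rows, j])),
          words[ix[rows]])
      }
      for (r in which(is.na(assign_pos)))         # own literal pattern
        families[[length(families) + 1]] <- new_family(
          sk, lapply(seq_along(sk_v), function(j) cmat[r, j]),
          words[ix[r]])
    }
  }

  families <- merge_optional_families(families)

  pats <- vapply(families, family_pattern, character(1))
  support <- vapply(families, function(f) length(f$words), integer(1))
  category <- ifelse(grepl("L", pats, fixed = TRUE),
                     "logic-based", "phrase-based")
  lib <- pattern_library(data.frame(
    pattern = pats, category = category, provenance = provenance,
    support = support, review_flag = review_flag, stringsAsFactors = FALSE))
  # soundness: every source word must match its family's pattern
  for (k in seq_along(families)) {
    bad <- families[[k]]$words[!vapply(families[[k]]$words,
      function(wd) pattern_matches_word(pats[k], wd), logical(1))]
    if (length(bad) > 0)
      stop("internal error: segment '", bad[1],
           "' does not match its reduced pattern '", pats[k], "'",
           call. = FALSE)
  }
  lib
}

empty_library <- function() {
  pattern_library(data.frame(pattern = character(0), category = character(0),
                             provenance = character(0), support = integer(0),
                             review_flag = logical(0),
                             stringsAsFactors = FALSE))
}

merge_optional_families <- function(families) {
  repeat {
    merged <- FALSE
    if (length(families) < 2) break
    len <- vapply(families, function(f) length(f$skeleton), integer(1))
    ord_small <- order(len)
    for (fi in ord_small) {
      cand <- which(len > len[fi])
      cand <- cand[order(-vapply(families[cand], function(f)
        length(f$words), integer(1)))]
      for (gi in cand) {
        g <- families[[gi]]; f <- families[[fi]]
        if (!identical(setdiff(f$skeleton, g$skeleton), character(0))) next
        map <- align_skeleton(f$skeleton, g$skeleton,
                              eligible_positions(g$skeleton))
        if (is.null(map)) next
        # aligned positions take the union of counts; deleted positions
        # gain a zero (the run may be absent)
        counts <- g$counts
        for (j in seq_along(g$skeleton)) {
          k <- match(j, map)
          counts[[j]] <- if (!is.na(k))
            unique(c(counts[[j]], f$counts[[k]])) else
            unique(c(counts[[j]], 0L))
        }
        families[[gi]] <- new_family(paste(g$skeleton, collapse = "|"),
                                     counts, c(g$words, f$words))
        families[[fi]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  families
}

# ---- persistence ------------------------------------------------------------

#' Write a pattern library as a line-oriented text file
#' @param library A `phenossu_pattern_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_library <- function(library, path) {
  df <- as.data.frame(library)
  lines <- c("category\tpattern\tprovenance\tsupport\treview_flag",
             paste(df$category, df$pattern, df$provenance, df$support,
                   ifelse(df$review_flag, "true", "false"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pattern library written by [write_pattern_library()]
#' @param path Input path.
#' @return A `phenossu_pattern_library`.
#' @export
read_pattern_library <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("category", "pattern", "provenance"), path)
  pattern_library(data.frame(
    pattern = df$pattern, category = df$category,
    provenance = df$provenance,
    support = as.integer(df$support %||% 0L),
    review_flag = tolower(as.character(df$review_flag %||% "false")) == "true",
    stringsAsFactors = FALSE))
}
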