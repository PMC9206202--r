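# ---- pattern containment (library consolidation) ---------------------------

# enumerate the words a simple alphabet regex can generate, with bounded
# repetition ("X+" -> 1..4, "X*" -> 0..3, "(CP)+" -> 1..3); patterns
# produced by reduce_segments only ever use these operators
enumerate_pattern_words <- function(pattern, max_rep = 4) {
  toks <- regmatches(pattern,
                     gregexpr("\\(CP\\)\\+|[PACOSLNUR][+*]?", pattern))[[1]]
  if (paste(toks, collapse = "") != pattern) return(NULL) # unsupported shape
  opts <- lapply(toks, function(t) {
    if (t == "(CP)+") vapply(1:(max_rep - 1), function(k)
      strrep("CP", k), character(1))
    else if (grepl("\\+$", t)) vapply(1:max_rep, function(k)
      strrep(substr(t, 1, 1), k), character(1))
    else if (grepl("\\*$", t)) vapply(0:(max_rep - 1), function(k)
      strrep(substr(t, 1, 1), k), character(1))
    else t
  })
  words <- Reduce(function(acc, o) as.vector(outer(acc, o, paste0)), opts,
                  accumulate = FALSE, "")
  unique(words[nzchar(words)])
}

pattern_subsumed_by <- function(p, q) {
  if (identical(p, q)) return(FALSE)
  words <- enumerate_pattern_words(p)
  if (is.null(words)) return(FALSE)
  all(vapply(words, function(wd) pattern_matches_word(q, wd), logical(1)))
}

#' Drop patterns whose language is contained in another pattern's
#'
#' A pattern that matches only words already matched by a more general
#' pattern in the same library contributes nothing to recognition and is
#' removed (e.g. a literal `AAP` next to `A+P`).
#'
#' @param library A `phenossu_pattern_library`.
#' @return The consolidated library.
#' @export
consolidate_library <- function(library) {
  if (nrow(library) < 2) return(library)
  drop <- logical(nrow(library))
  for (i in seq_len(nrow(library))) {
    for (j in seq_len(nrow(library))) {
      if (i == j || drop[j]) next
      if (pattern_subsumed_by(library$pattern[i], library$pattern[j])) {
        drop[i] <- TRUE
        break
      }
    }
  }
  pattern_library(as.data.frame(library)[!drop, , drop = FALSE])
}

# ---- end-to-end pattern learning --------------------------------------------

#' Encode every corpus document as a letter sequence
#' @param corpus A `phenossu_corpus`.
#' @param lexicon Lexicon to encode with (defaults to the generator's).
#' @return Character vector of letter sequences, one per document.
#' @export
corpus_sequences <- function(corpus, lexicon = corpus$config$lexicon) {
  vapply(corpus$docs, function(d) encode(d$text, lexicon)$letters,
         character(1))
}

#' Learn a linguistic-pattern library from an annotated corpus
#'
#' The full discovery pipeline: encode the documents, mine motifs with
#' the EM discoverer, split the motif consensus and site words on `O`,
#' reduce the segments to pattern classes, then run gap-driven
#' enrichment against the gold annotations until a fixed point. The final library is rebuilt by a
#' single reduction over the union of discovery segments and enrichment
#' words (so that variants of one class discovered through different
#' routes abstract together) and consolidated by dropping patterns whose
#' language another pattern contains. Patterns supported by at least one
#' discovery segment keep provenance `discovered`; patterns supported by
#' enrichment words only are `enriched` and flagged for review.
#'
#' @param corpus A `phenossu_corpus` (or any list of documents with
#'   `text` and gold `instances`, plus a config carrying the lexicon).
#' @param min_w,max_w,n_motifs,n_shuffles,evalue_threshold,seed,seed_cap
#'   Passed to [discover_motifs()].
#' @return A list: `library`, `motifs`, `segments`, `enrichment`
#'   (report/unencodable from the final enrichment pass).
#' @export
learn_patterns <- function(corpus, min_w = 2, max_w = 8, n_motifs = 25,
                           n_shuffles = 149, evalue_threshold = 0.05,
                           seed = 1, seed_cap = 100) {
  lex <- corpus$config$lexicon
  schema <- corpus$config$schema
  kb <- corpus$config$lab_kb
  seqs <- corpus_sequences(corpus, lex)
  motifs <- discover_motifs(seqs, min_w = min_w, max_w = max_w,
                            n_motifs = n_motifs, n_shuffles = n_shuffles,
                            evalue_threshold = evalue_threshold, seed = seed,
                            seed_cap = seed_cap)
  segments <- unlist(lapply(motifs, function(m)
    split_on_O(c(m$consensus, unique(m$site_words)))))
  segments <- as.character(segments %||% character(0))
  docs <- corpus$docs
  lib <- if (length(segments) > 0) reduce_segments(segments) else
    empty_library()
  words <- character(0)
  enr <- NULL
  for (pass in 1:3) {
    enr <- enrich(lib, docs, lex, schema, lab_kb = kb)
    if (length(enr$words) == 0 && pass > 1) break
    words <- c(words, enr$words)
    pool <- c(segments, words)
    if (length(pool) == 0) break
    lib <- rebuild_library(pool, segments)
    if (length(enr$words) == 0) break
  }
  lib <- consolidate_library(lib)
  list(library = lib, motifs = motifs, segments = segments,
       enrichment = enr)
}

rebuild_library <- function(pool, discovery_segments) {
  lib <- reduce_segments(pool)
  kept_discovery <- drop_uninformative(unique(discovery_segments))
  prov <- vapply(lib$pattern, function(p)
    if (any(vapply(kept_discovery, function(s)
      pattern_matches_word(p, s), logical(1)))) "discovered" else "enriched",
    character(1))
  df <- as.data.frame(lib)
  df$provenance <- prov
  df$review_flag <- prov == "enriched"
  pattern_library(df)
}
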