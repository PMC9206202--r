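#' Gap-driven enrichment of the pattern library
#'
#' Recognizes instances in gold-annotated documents with the current
#' library; every gold instance that is not recovered exactly (same
#' evidence span, same phenotype and attribute values) contributes the
#' letter word of the minimal encoding span covering its evidence. The
#' collected words are abstracted with [reduce_segments()] (including
#' the `(CP)+` conjunction rule) and the resulting patterns are added
#' with provenance `enriched` and `review_flag = TRUE`, pending human
#' review. The procedure repeats until a fixed point: re-running on the
#' same documents adds nothing.
#'
#' @param library A `phenossu_pattern_library`.
#' @param gold_docs A list of documents, each a list with `text` and
#'   `instances` (gold `phenossu_instance` objects).
#' @param lexicon A `phenossu_lexicon`.
#' @param schema A `phenossu_schema`.
#' @param lab_kb Optional `phenossu_lab_kb`.
#' @param max_rounds Safety bound on enrichment passes (default 5).
#' @return A list: `library` (enriched), `report` (data frame of new
#'   patterns with exemplar words and sentences), `unencodable`
#'   (character vector of gold spans that encode to nothing usable).
#' @export
enrich <- function(library, gold_docs, lexicon, schema, lab_kb = NULL,
                   max_rounds = 5) {
  all_new <- list()
  all_words <- character(0)
  unencodable <- character(0)
  for (round in seq_len(max_rounds)) {
    words <- character(0)
    exemplar <- character(0)
    for (doc in gold_docs) {
      enc <- encode(doc$text, lexicon)
      pred <- assemble_instances(scan_encoding(enc, library), enc, schema,
                                 lab_kb)
      miss <- unrecovered_gold(pred, doc$instances)
      for (g in miss) {
        spans <- gold_evidence_spans(g)
        lets <- which(enc$end > spans[1] & enc$start < spans[2])
        if (length(lets) == 0) {
          unencodable <- c(unencodable, substr(doc$text, spans[1] + 1,
                                               spans[2]))
          next
        }
        word <- substr(enc$letters, min(lets), max(lets))
        word <- gsub("^O+|O+$", "", word)
        if (!nzchar(word) || grepl("O", word, fixed = TRUE)) {
          unencodable <- c(unencodable, substr(doc$text, spans[1] + 1,
                                               spans[2]))
          next
        }
        words <- c(words, word)
        exemplar <- c(exemplar, substr(doc$text, spans[1] + 1, spans[2]))
      }
    }
    if (length(words) == 0) break
    all_words <- c(all_words, words)
    cand <- reduce_segments(words, provenance = "enriched",
                            review_flag = TRUE)
    cand <- cand[!cand$pattern %in% library$pattern, , drop = FALSE]
    if (nrow(cand) == 0) break
    for (k in seq_len(nrow(cand))) {
      matching <- unique(exemplar[vapply(words, function(wd)
        pattern_matches_word(cand$pattern[k], wd), logical(1))])
      all_new[[length(all_new) + 1L]] <- data.frame(
        pattern = cand$pattern[k], category = cand$category[k],
        support = cand$support[k],
        exemplars = paste(utils::head(matching, 3), collapse = " | "),
        stringsAsFactors = FALSE)
    }
    library <- library_add(library, as.data.frame(cand))
  }
  report <- if (length(all_new) == 0)
    data.frame(pattern = character(0), category = character(0),
               support = integer(0), exemplars = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, all_new)
  list(library = library, report = report, words = all_words,
       unencodable = unique(unencodable))
}

unrecovered_gold <- function(pred, gold) {
  if (length(gold) == 0) return(list())
  pred_sig <- vapply(pred, function(p)
    paste(paste(p$span, collapse = "-"), instance_key(p)), character(1))
  gold[vapply(gold, function(g)
    !(paste(paste(g$span, collapse = "-"), instance_key(g)) %in% pred_sig),
    logical(1))]
}

gold_evidence_spans <- function(inst) {
  starts <- inst$span[1]; ends <- inst$span[2]
  for (a in inst$attributes) {
    if (!is.null(a$span)) {
      starts <- c(starts, a$span[1])
      ends <- c(ends, a$span[2])
    }
  }
  c(min(starts), max(ends))
}

#' Render an enrichment report as Markdown
#' @param result The list returned by [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(result, path) {
  lines <- c("# Pattern enrichment report", "",
             sprintf("New patterns pending review: %d", nrow(result$report)),
             "")
  for (k in seq_len(nrow(result$report))) {
    r <- result$report[k, ]
    lines <- c(lines,
               sprintf("- `%s` (%s, support %d) — e.g. %s",
                       r$pattern, r$category, r$support, r$exemplars))
  }
  if (length(result$unencodable) > 0)
    lines <- c(lines, "", "## Unencodable gold spans", "",
               paste0("- ", result$unencodable))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
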