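# ---- scanning ---------------------------------------------------------------

#' Scan an encoded sequence with the pattern library
#'
#' Left-to-right scan: at each letter position the pattern with the
#' longest (greedy) match is taken, ties broken by library priority
#' order; the scan resumes after the match, so accepted matches never
#' overlap.
#'
#' @param enc A `phenossu_encoding`.
#' @param library A `phenossu_pattern_library`.
#' @return A data frame of matches: `pattern`, `category`, `from`, `to`
#'   (1-based inclusive letter indices), `letters` (the matched letter
#'   substring).
#' @export
scan_encoding <- function(enc, library) {
  letters_s <- enc$letters
  n <- nchar(letters_s)
  res <- list()
  anchored <- paste0("^(?:", library$pattern, ")")
  i <- 1L
  while (i <= n) {
    tail_s <- substring(letters_s, i)
    hit <- 0L; hit_len <- 0L
    for (k in seq_along(anchored)) {
      m <- regexpr(anchored[k], tail_s, perl = TRUE)
      len <- if (m[1] == 1L) attr(m, "match.length") else 0L
      if (len > hit_len) {  # longest match wins; ties keep priority order
        hit <- k
        hit_len <- len
      }
    }
    if (hit > 0L) {
      res[[length(res) + 1L]] <- data.frame(
        pattern = library$pattern[hit], category = library$category[hit],
        from = i, to = i + hit_len - 1L,
        letters = substr(letters_s, i, i + hit_len - 1L),
        stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0)
    return(data.frame(pattern = character(0), category = character(0),
                      from = integer(0), to = integer(0),
                      letters = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# ---- instances --------------------------------------------------------------

new_instance <- function(phenotype, span, attributes, category,
                         snomed = NULL, pattern = NA_character_) {
  structure(list(phenotype = phenotype, span = span,
                 attributes = attributes, category = category,
                 snomed = snomed, pattern = pattern),
            class = "phenossu_instance")
}

#' @export
print.phenossu_instance <- function(x, ...) {
  att <- vapply(names(x$attributes), function(nm) {
    a <- x$attributes[[nm]]
    paste0(nm, "=", a$value, if (isTRUE(a$default)) "(default)" else "")
  }, character(1))
  cat(sprintf("[%s] %s {%s}%s\n", x$category, x$phenotype,
              paste(att, collapse = "; "),
              if (is.null(x$snomed)) "" else paste0(" SNOMED:", x$snomed)))
  invisible(x)
}

#' Canonical identity of an instance (phenotype + attribute values)
#' @param inst A `phenossu_instance`.
#' @return A single string; equal strings mean equal instances at the
#'   phenotype-plus-attribute level (evidence spans are ignored).
#' @export
instance_key <- function(inst) {
  att <- inst$attributes[order(names(inst$attributes))]
  paste0(inst$phenotype, "|",
         paste(names(att), vapply(att, `[[`, character(1), "value"),
               sep = "=", collapse = ";"))
}

# ---- assembly ---------------------------------------------------------------

#' Assemble PhenoSSU instances from pattern matches
#'
#' Phrase-based matches yield one instance per `P` letter. Attribute
#' letters before the first `P` of a match apply to every phenotype in
#' the match (the enumeration classes `A+P(CP)+` and `AP+`); attribute
#' letters after a phenotype attach to the nearest preceding `P` (the
#' trailing class `A*PC*A+`). When two attribute letters of the same
#' category compete for one phenotype, the occurrence nearest the
#' phenotype wins, with a warning. An instance with no assertion trigger
#' receives the schema default `assertion = present`; other phrase-based
#' attributes are only present when evidenced. Logic-based matches are
#' forwarded to the lab normalizer ([interpret_lnu()] / [interpret_lr()]).
#'
#' @param matches Matches from [scan_encoding()] on the same encoding.
#' @param enc The `phenossu_encoding` that was scanned.
#' @param schema A `phenossu_schema`.
#' @param lab_kb A `phenossu_lab_kb`, required when logic-based matches
#'   are present.
#' @return A list of `phenossu_instance` objects.
#' @export
assemble_instances <- function(matches, enc, schema, lab_kb = NULL) {
  out <- list()
  if (nrow(matches) == 0) return(out)
  letters_v <- strsplit(enc$letters, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(matches))) {
    idx <- matches$from[r]:matches$to[r]
    lets <- letters_v[idx]
    if (matches$category[r] == "logic-based") {
      inst <- assemble_logic(idx, lets, enc, schema, lab_kb, matches$pattern[r])
      if (!is.null(inst)) out[[length(out) + 1L]] <- inst
    } else {
      out <- c(out, assemble_phrase(idx, lets, enc, schema,
                                    matches$pattern[r]))
    }
  }
  out
}

assemble_phrase <- function(idx, lets, enc, schema, pattern) {
  p_pos <- idx[lets == "P"]
  a_pos <- idx[lets == "A"]
  instances <- list()
  for (p in p_pos) {
    applicable <- vapply(a_pos, function(a) {
      if (a < min(p_pos)) TRUE                    # leading block: all P
      else if (a > p) p == max(p_pos[p_pos < a])  # trailing: nearest prior P
      else FALSE
    }, logical(1))
    atts <- list()
    for (a in a_pos[applicable]) {
      pay <- enc$payload[[a]]
      if (is.null(pay$category))
        stop("configuration error: attribute trigger '", pay$surface,
             "' names no attribute category", call. = FALSE)
      sp <- decode_span(enc, a)
      cand <- list(value = pay$normalization, span = c(sp$start, sp$end),
                   default = FALSE, dist = abs(a - p))
      prev <- atts[[pay$category]]
      if (!is.null(prev)) {
        warning("attribute conflict for category '", pay$category,
                "': keeping the trigger nearest the phenotype")
        if (cand$dist < prev$dist) atts[[pay$category]] <- cand
      } else {
        atts[[pay$category]] <- cand
      }
    }
    atts <- lapply(atts, function(a) a[c("value", "span", "default")])
    if (is.null(atts[["assertion"]])) {
      dflt <- schema$attributes[["assertion"]]$default %||% "present"
      atts[["assertion"]] <- list(value = dflt, span = NULL, default = TRUE)
    }
    validate_attribute_values(atts, schema, "phrase-based")
    psp <- decode_span(enc, p)
    pay_p <- enc$payload[[p]]
    instances[[length(instances) + 1L]] <- new_instance(
      phenotype = pay_p$normalization %||% psp$text,
      span = c(psp$start, psp$end), attributes = atts,
      category = "phrase-based", pattern = pattern)
  }
  instances
}

assemble_logic <- function(idx, lets, enc, schema, lab_kb, pattern) {
  if (is.null(lab_kb))
    stop("logic-based match found but no lab knowledge base supplied",
         call. = FALSE)
  get_pay <- function(letter) {
    k <- idx[lets == letter]
    if (length(k) == 0) NULL else enc$payload[[k[1]]]
  }
  specimen <- get_pay("S")$normalization
  analyte <- get_pay("L")$normalization
  obs <- if ("R" %in% lets) {
    interpret_lr(analyte, get_pay("R")$normalization, lab_kb,
                 specimen = specimen)
  } else {
    interpret_lnu(analyte, get_pay("N"), get_pay("U")$normalization,
                  lab_kb, specimen = specimen)
  }
  sp_from <- decode_span(enc, idx[1])
  sp_to <- decode_span(enc, idx[length(idx)])
  atts <- list()
  if (!is.null(obs$specimen))
    atts[["specimen"]] <- list(value = obs$specimen, span = NULL,
                               default = is.null(specimen))
  atts[["analyte"]] <- list(value = obs$analyte %||% analyte, span = NULL,
                            default = FALSE)
  if (!is.na(obs$abnormality))
    atts[["abnormality"]] <- list(value = obs$abnormality, span = NULL,
                                  default = FALSE)
  validate_attribute_values(atts, schema, "logic-based")
  new_instance(phenotype = obs$analyte %||% analyte,
               span = c(sp_from$start, sp_to$end), attributes = atts,
               category = "logic-based", snomed = obs$snomed,
               pattern = pattern)
}

validate_attribute_values <- function(atts, schema, subtype) {
  for (nm in names(atts)) {
    ad <- schema$attributes[[nm]]
    if (is.null(ad) || ad$subtype != subtype)
      stop("validation error: attribute category '", nm,
           "' is not a ", subtype, " category", call. = FALSE)
    if (!atts[[nm]]$value %in% ad$values)
      stop("validation error: value '", atts[[nm]]$value,
           "' is outside the closed set of attribute '", nm, "'",
           call. = FALSE)
  }
  invisible(atts)
}

# ---- document-level pipeline ------------------------------------------------

#' Recognize PhenoSSU instances in a document
#'
#' Encodes the text, scans the encoded sequence with the pattern library,
#' and assembles phrase-based and logic-based instances, ordered by
#' evidence start offset.
#'
#' @param text Document text.
#' @param lexicon A `phenossu_lexicon`.
#' @param library A `phenossu_pattern_library`.
#' @param lab_kb A `phenossu_lab_kb` (needed only for logic-based
#'   patterns).
#' @param schema A `phenossu_schema`.
#' @return A list of `phenossu_instance` objects.
#' @examples
#' lex <- load_lexicon(phenossu_file("lexicon_zh.tsv"))
#' kb <- load_lab_kb(phenossu_file("lab_kb.tsv"))
#' sch <- load_schema(phenossu_file("phenossu_schema.tsv"))
#' recognize_document("WBC 12.5 × 10^9/L", lex, builtin_library(),
#'                    lab_kb = kb, schema = sch)
#' @export
recognize_document <- function(text, lexicon, library, lab_kb = NULL,
                               schema) {
  enc <- encode(text, lexicon)
  matches <- scan_encoding(enc, library)
  inst <- assemble_instances(matches, enc, schema, lab_kb)
  if (length(inst) == 0) return(inst)
  inst[order(vapply(inst, function(x) x$span[1], numeric(1)))]
}
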