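# ---- default generator resources -------------------------------------------

#' Default lexicon used by the synthetic-corpus generator
#'
#' ASCII placeholder tokens covering every encoder letter, so that tests
#' do not require CJK-aware tooling; the recognition method itself is
#' script-agnostic once a lexicon is supplied. Surfaces are chosen so
#' that no surface occurs inside any filler phrase.
#'
#' @return A `phenossu_lexicon`.
#' @export
default_generator_lexicon <- function() {
  as_lexicon(data.frame(
    surface = c("denies",
                "severe", "mild",
                "acute", "chronic", "recurrent", "occasional", "persistent",
                "leftsided", "rightsided", "diffuse", "rightlower",
                "abdominal", "thoracic",
                "cough", "fever", "fatigue", "dyspnea", "headache",
                "vomiting", "diarrhea",
                ",",
                "blood", "urine",
                "leukocyte", "glucose", "hemoglobin",
                "elevated", "decreased", "withinrange",
                "gigaperliter", "mmolperliter", "gramperliter", "perliter"),
    letter = c("A",
               "A", "A",
               "A", "A", "A", "A", "A",
               "A", "A", "A", "A",
               "A", "A",
               "P", "P", "P", "P", "P", "P", "P",
               "C",
               "S", "S",
               "L", "L", "L",
               "R", "R", "R",
               "U", "U", "U", "U"),
    category = c("assertion",
                 "severity", "severity",
                 rep("temporal pattern", 5),
                 "laterality", "laterality", "spatial pattern",
                 "quadrant pattern",
                 "body location", "body location",
                 rep("", 7), "", "", "", rep("", 3), rep("", 3), rep("", 4)),
    normalization = c("absent",
                      "severe", "mild",
                      "acute", "chronic", "recurrent", "occasional",
                      "persistent",
                      "left", "right", "diffuse", "right-lower",
                      "abdomen", "chest",
                      "cough", "fever", "fatigue", "dyspnea", "headache",
                      "vomiting", "diarrhea",
                      "",
                      "blood", "urine",
                      "leukocyte", "glucose", "hemoglobin",
                      "higher", "lower", "normal",
                      "gigaperliter", "mmolperliter", "gramperliter",
                      "perliter"),
    stringsAsFactors = FALSE))
}

#' Default lab knowledge base used by the synthetic-corpus generator
#'
#' Three blood analytes with reference ranges in synthetic ASCII units.
#' The leukocyte entry carries the SNOMED CT code for increased blood
#' leukocyte number; other codes are standard concepts for the
#' corresponding abnormalities.
#'
#' @return A `phenossu_lab_kb`.
#' @export
default_generator_lab_kb <- function() {
  entries <- list(
    list(analyte = "leukocyte", synonyms = character(0), specimen = "blood",
         unit = "gigaperliter", low = 4, high = 10,
         conversions = c(perliter = 1e-9),
         snomed = c(higher = "414478003")),
    list(analyte = "glucose", synonyms = character(0), specimen = "blood",
         unit = "mmolperliter", low = 3.9, high = 6.1,
         conversions = c(),
         snomed = c(higher = "80394007", lower = "302866003")),
    list(analyte = "hemoglobin", synonyms = character(0), specimen = "blood",
         unit = "gramperliter", low = 120, high = 160,
         conversions = c(),
         snomed = c(lower = "271737000")))
  kb <- structure(entries, class = "phenossu_lab_kb")
  attr(kb, "synonym_index") <- build_synonym_index(entries)
  kb
}

GENERATOR_FILLERS <- c("ward round notes", "seen overnight", "plan unchanged",
                       "stable today", "family at bedside", "no new orders")

PATTERN_CLASSES <- c("A+P(CP)+", "AP+", "A+P", "A*PC*A+", "S*LNU", "S*LR")

#' Configuration for the synthetic-corpus generator
#'
#' @param n_docs Number of documents (default 500).
#' @param sentences_per_doc Length-2 integer range of sentences per
#'   document (default 2 to 4).
#' @param weights Named probabilities over the six pattern classes
#'   (must sum to 1).
#' @param filler_rate Probability of an extra filler phrase between
#'   sentences (sentences are always separated by at least a stop, which
#'   encodes as `O`).
#' @param noise_rate Per-letter corruption probability used by
#'   [generate_planted_sequences()] (not by the corpus generator).
#' @param lexicon,lab_kb,schema Generator resources.
#' @param seed Integer seed; the corpus is a pure function of the
#'   configuration.
#' @return A list of class `phenossu_generator_config`.
#' @export
generator_config <- function(n_docs = 500, sentences_per_doc = c(2, 4),
                             weights = c("A+P(CP)+" = 0.20, "AP+" = 0.15,
                                         "A+P" = 0.25, "A*PC*A+" = 0.15,
                                         "S*LNU" = 0.15, "S*LR" = 0.10),
                             filler_rate = 0.5, noise_rate = 0,
                             lexicon = default_generator_lexicon(),
                             lab_kb = default_generator_lab_kb(),
                             schema = default_schema(), seed = 42) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("template weights must sum to 1", call. = FALSE)
  if (!setequal(names(weights), PATTERN_CLASSES))
    stop("weights must be named by the six pattern classes", call. = FALSE)
  if (n_docs < 1) stop("n_docs must be >= 1", call. = FALSE)
  if (filler_rate < 0 || filler_rate > 1 || noise_rate < 0 || noise_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  for (f in GENERATOR_FILLERS)
    if (any(vapply(lexicon$surface, function(s)
      grepl(s, f, fixed = TRUE), logical(1))))
      stop("filler phrase '", f, "' collides with a lexicon surface",
           call. = FALSE)
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 weights = weights, filler_rate = filler_rate,
                 noise_rate = noise_rate, lexicon = lexicon,
                 lab_kb = lab_kb, schema = schema, seed = seed),
            class = "phenossu_generator_config")
}

#' The schema shipped with the package
#' @return A `phenossu_schema`.
#' @export
default_schema <- function() {
  load_schema(phenossu_file("phenossu_schema.tsv"))
}

# ---- corpus generation ------------------------------------------------------

pick <- function(x, n = 1) x[sample.int(length(x), n)]

# sample k attribute triggers with pairwise-distinct categories
sample_attributes <- function(pool, k, exclude_categories = character(0)) {
  cats <- setdiff(unique(pool$category), exclude_categories)
  cats <- pick(cats, min(k, length(cats)))
  lapply(cats, function(cc) {
    rows <- which(pool$category == cc)
    pool[pick(rows), , drop = FALSE]
  })
}

#' Generate a synthetic annotated corpus
#'
#' Every sentence instantiates one of the six linguistic-pattern classes:
#' attribute triggers and phenotype mentions (or specimen, analyte,
#' number and unit tokens) drawn from the generator lexicon, concatenated
#' without internal separators so that annotation spans are exact, with
#' sentence stops and optional filler phrases between sentences (these
#' encode as single `O` letters). The gold annotation of each sentence is
#' exactly what the template dictates: one PhenoSSU instance per
#' phenotype with the attribute-propagation rules of the pattern class,
#' and lab abnormalities recomputed from the drawn value against the
#' knowledge-base reference interval. The corpus is byte-identical across
#' calls with the same configuration.
#'
#' @param config A `phenossu_generator_config`.
#' @return A list of class `phenossu_corpus`: `docs` (each with `id`,
#'   `text`, `entities` data frame, `instances` gold list, `classes`
#'   sentence classes) and `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  lex <- config$lexicon
  a_pool <- as.data.frame(lex[lex$letter == "A" &
                                lex$category != "assertion", ])
  assertion_pool <- as.data.frame(lex[lex$letter == "A" &
                                        lex$category == "assertion", ])
  p_pool <- as.data.frame(lex[lex$letter == "P", ])
  r_pool <- as.data.frame(lex[lex$letter == "R", ])
  comma <- lex$surface[lex$letter == "C"][1]
  for (letter in c("A", "P", "C"))
    if (!letter %in% lex$letter)
      stop("generator lexicon lacks letter '", letter, "'", call. = FALSE)
  if (nrow(assertion_pool) == 0)
    stop("generator lexicon lacks an assertion trigger", call. = FALSE)
  kb <- config$lab_kb
  unit_surface <- function(unit) {
    s <- lex$surface[lex$letter == "U" & lex$normalization == unit]
    if (length(s) == 0)
      stop("generator lexicon lacks unit surface '", unit, "'", call. = FALSE)
    s[1]
  }
  analyte_surface <- function(analyte) {
    s <- lex$surface[lex$letter == "L" & lex$normalization == analyte]
    if (length(s) == 0)
      stop("generator lexicon lacks analyte surface '", analyte, "'",
           call. = FALSE)
    s[1]
  }
  specimen_surface <- function(specimen) {
    s <- lex$surface[lex$letter == "S" & lex$normalization == specimen]
    if (length(s) == 0)
      stop("generator lexicon lacks specimen surface '", specimen, "'",
           call. = FALSE)
    s[1]
  }

  docs <- with_seed(config$seed, lapply(seq_len(config$n_docs), function(d) {
    n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1)
    buf <- character(0); cursor <- 0L
    add <- function(piece) {
      buf[[length(buf) + 1L]] <<- piece
      span <- c(cursor, cursor + nchar(piece))
      cursor <<- cursor + nchar(piece)
      span
    }
    entities <- list(); instances <- list(); classes <- character(0)
    add_entity <- function(type, span, surface) {
      entities[[length(entities) + 1L]] <<- data.frame(
        type = type, start = span[1], end = span[2], surface = surface,
        stringsAsFactors = FALSE)
    }
    letter_type <- c(P = "Phenotype", A = "Attribute", S = "Specimen",
                     L = "Analyte", N = "Number", U = "Unit", R = "Result")
    add_token <- function(letter, surface) {
      span <- add(surface)
      add_entity(letter_type[[letter]], span, surface)
      span
    }
    if (stats::runif(1) < config$filler_rate)
      add(paste0(pick(GENERATOR_FILLERS), ". "))
    for (s in seq_len(n_sent)) {
      cls <- sample(names(config$weights), 1, prob = config$weights)
      classes <- c(classes, cls)
      sent <- build_sentence(cls, a_pool, assertion_pool, p_pool, r_pool,
                             comma, kb, analyte_surface, specimen_surface,
                             unit_surface, config$schema)
      spans <- vector("list", length(sent$tokens))
      for (t in seq_along(sent$tokens)) {
        tok <- sent$tokens[[t]]
        spans[[t]] <- if (tok$letter == "C") add(tok$surface) else
          add_token(tok$letter, tok$surface)
      }
      for (inst in sent$instances(spans))
        instances[[length(instances) + 1L]] <- inst
      sep <- if (s < n_sent && stats::runif(1) < config$filler_rate)
        paste0(". ", pick(GENERATOR_FILLERS), ". ") else ". "
      add(sep)
    }
    text <- paste(buf, collapse = "")
    instances <- lapply(instances, function(x) { x$doc <- d; x })
    ent_df <- if (length(entities) == 0)
      data.frame(type = character(0), start = integer(0), end = integer(0),
                 surface = character(0), stringsAsFactors = FALSE)
    else do.call(rbind, entities)
    ent_df$doc <- if (nrow(ent_df)) d else integer(0)
    list(id = sprintf("doc-%04d", d), text = text, entities = ent_df,
         instances = instances, classes = classes)
  }))
  structure(list(docs = docs, config = config), class = "phenossu_corpus")
}

tok <- function(letter, surface, value = NULL, entry = NULL)
  list(letter = letter, surface = surface, value = value, entry = entry)

att_slot <- function(value, span = NULL, default = FALSE)
  list(value = value, span = span, default = default)

build_sentence <- function(cls, a_pool, assertion_pool, p_pool, r_pool,
                           comma, kb, analyte_surface, specimen_surface,
                           unit_surface, schema) {
  if (cls %in% c("A+P(CP)+", "AP+", "A+P", "A*PC*A+"))
    build_phrase_sentence(cls, a_pool, assertion_pool, p_pool, comma, schema)
  else
    build_logic_sentence(cls, r_pool, kb, analyte_surface, specimen_surface,
                         unit_surface)
}

build_phrase_sentence <- function(cls, a_pool, assertion_pool, p_pool,
                                  comma, schema) {
  tokens <- list()
  lead <- list(); trail <- list()
  if (cls == "A+P(CP)+") {
    if (stats::runif(1) < 0.7) lead <- list(assertion_pool[1, , drop = FALSE])
    extra <- if (stats::runif(1) < 0.4) 1 else 0
    if (length(lead) == 0) extra <- max(extra, 1)
    lead <- c(lead, sample_attributes(a_pool, extra))
    n_p <- sample(2:3, 1)
  } else if (cls == "AP+") {
    lead <- if (stats::runif(1) < 0.6)
      list(assertion_pool[1, , drop = FALSE]) else sample_attributes(a_pool, 1)
    n_p <- sample(2:3, 1)
  } else if (cls == "A+P") {
    lead <- sample_attributes(a_pool, sample(1:3, 1))
    n_p <- 1
  } else { # A*PC*A+
    n_trail <- sample(1:2, 1)
    picked <- sample_attributes(a_pool, n_trail +
                                  (if (stats::runif(1) < 0.4) 1 else 0))
    if (length(picked) > n_trail) {
      lead <- picked[1]
      trail <- picked[-1]
    } else trail <- picked
    n_p <- 1
  }
  phens <- p_pool[pick(seq_len(nrow(p_pool)), n_p), , drop = FALSE]
  for (a in lead) tokens[[length(tokens) + 1]] <- tok("A", a$surface)
  lead_meta <- lead
  p_tok_idx <- integer(0)
  for (k in seq_len(n_p)) {
    if (cls == "A+P(CP)+" && k > 1)
      tokens[[length(tokens) + 1]] <- tok("C", comma)
    tokens[[length(tokens) + 1]] <- tok("P", phens$surface[k])
    p_tok_idx <- c(p_tok_idx, length(tokens))
  }
  use_comma <- cls == "A*PC*A+" && stats::runif(1) < 0.7
  if (use_comma) tokens[[length(tokens) + 1]] <- tok("C", comma)
  trail_idx <- integer(0)
  for (a in trail) {
    tokens[[length(tokens) + 1]] <- tok("A", a$surface)
    trail_idx <- c(trail_idx, length(tokens))
  }
  lead_idx <- seq_along(lead)
  instances <- function(spans) {
    lapply(seq_len(n_p), function(k) {
      atts <- list()
      for (j in seq_along(lead_meta)) {
        a <- lead_meta[[j]]
        atts[[a$category]] <- att_slot(a$normalization, spans[[lead_idx[j]]])
      }
      for (j in seq_along(trail)) {
        a <- trail[[j]]
        atts[[a$category]] <- att_slot(a$normalization, spans[[trail_idx[j]]])
      }
      if (is.null(atts[["assertion"]]))
        atts[["assertion"]] <- att_slot(
          schema$attributes[["assertion"]]$default %||% "present",
          default = TRUE)
      new_instance(phenotype = phens$normalization[k],
                   span = spans[[p_tok_idx[k]]],
                   attributes = atts, category = "phrase-based",
                   pattern = cls)
    })
  }
  list(tokens = tokens, instances = instances)
}

build_logic_sentence <- function(cls, r_pool, kb, analyte_surface,
                                 specimen_surface, unit_surface) {
  entry <- kb[[pick(seq_along(kb))]]
  tokens <- list()
  with_specimen <- stats::runif(1) < 0.6
  if (with_specimen)
    tokens[[length(tokens) + 1]] <- tok("S", specimen_surface(entry$specimen))
  tokens[[length(tokens) + 1]] <- tok("L", analyte_surface(entry$analyte))
  span_from_idx <- 1L
  if (cls == "S*LNU") {
    target <- pick(c("lower", "normal", "higher"))
    span_w <- entry$high - entry$low
    v <- switch(target,
      lower = stats::runif(1, 0.5 * entry$low, 0.9 * entry$low),
      normal = stats::runif(1, entry$low + 0.1 * span_w,
                            entry$high - 0.1 * span_w),
      higher = stats::runif(1, 1.1 * entry$high, 1.5 * entry$high))
    v <- round(v, 1)
    abnormality <- if (v > entry$high) "higher" else
      if (v < entry$low) "lower" else "normal"
    alt <- length(entry$conversions) > 0 && stats::runif(1) < 0.3
    if (alt) {
      alt_unit <- names(entry$conversions)[1]
      expo <- -log10(entry$conversions[[1]])
      num_txt <- paste0(format(v, scientific = FALSE), "x10^",
                        format(expo, scientific = FALSE))
      tokens[[length(tokens) + 1]] <- tok("N", num_txt, value = v)
      tokens[[length(tokens) + 1]] <- tok("U", unit_surface(alt_unit))
    } else {
      tokens[[length(tokens) + 1]] <- tok("N", format(v, scientific = FALSE),
                                          value = v)
      tokens[[length(tokens) + 1]] <- tok("U", unit_surface(entry$unit))
    }
  } else { # S*LR
    r_row <- r_pool[pick(seq_len(nrow(r_pool))), , drop = FALSE]
    abnormality <- r_row$normalization
    tokens[[length(tokens) + 1]] <- tok("R", r_row$surface)
  }
  snomed <- {
    code <- unname(entry$snomed[abnormality])
    if (length(code) == 1 && !is.na(code)) code else NULL
  }
  instances <- function(spans) {
    atts <- list(
      specimen = att_slot(entry$specimen, default = !with_specimen),
      analyte = att_slot(entry$analyte),
      abnormality = att_slot(abnormality))
    span <- c(spans[[span_from_idx]][1], spans[[length(spans)]][2])
    list(new_instance(phenotype = entry$analyte, span = span,
                      attributes = atts, category = "logic-based",
                      snomed = snomed, pattern = cls))
  }
  list(tokens = tokens, instances = instances)
}

# ---- planted-motif sequences ------------------------------------------------

#' Generate background sequences with planted motif sites
#'
#' Draws i.i.d. letters from a background distribution and plants
#' non-overlapping copies of a motif word at recorded offsets; each
#' planted letter is independently corrupted (replaced by a different
#' uniformly chosen alphabet letter) with probability `noise_rate`.
#'
#' @param background A `phenossu_background` (or named probability
#'   vector over the alphabet).
#' @param motif_word The letter word to plant.
#' @param copies Total number of planted copies across the corpus.
#' @param n_seqs Number of sequences.
#' @param seq_len Length of each sequence.
#' @param noise_rate Per-letter corruption probability.
#' @param seed Integer seed.
#' @return A list: `sequences`, `sites` (data frame `seq`, `offset`
#'   1-based), `word`.
#' @export
generate_planted_sequences <- function(background, motif_word, copies,
                                       n_seqs, seq_len, noise_rate = 0,
                                       seed = 1) {
  w <- nchar(motif_word)
  if (copies * w > n_seqs * seq_len)
    stop("infeasible packing: copies x width exceeds total length",
         call. = FALSE)
  word_chars <- strsplit(motif_word, "", fixed = TRUE)[[1]]
  if (!all(word_chars %in% PHENOSSU_ALPHABET))
    stop("motif word contains letters outside the alphabet", call. = FALSE)
  probs <- as.numeric(background)[match(PHENOSSU_ALPHABET,
                                        names(background))]
  probs[is.na(probs)] <- 0
  with_seed(seed, {
    seqs <- replicate(n_seqs, sample(PHENOSSU_ALPHABET, seq_len,
                                     replace = TRUE, prob = probs),
                      simplify = FALSE)
    sites <- data.frame(seq = integer(0), offset = integer(0))
    per_seq_slots <- floor(seq_len / w)
    if (copies > 0) {
      target_seq <- rep(seq_len(n_seqs), length.out = copies)
      for (s in unique(target_seq)) {
        k <- sum(target_seq == s)
        if (k > per_seq_slots)
          stop("infeasible packing: too many copies per sequence",
               call. = FALSE)
        # choose k non-overlapping offsets on a width-w grid, then jitter
        slots <- sort(pick(seq_len(per_seq_slots), k))
        offs <- (slots - 1L) * w + 1L
        for (o in offs) {
          planted <- word_chars
          flip <- stats::runif(w) < noise_rate
          if (any(flip))
            planted[flip] <- vapply(planted[flip], function(ch)
              pick(setdiff(PHENOSSU_ALPHABET, ch)), character(1))
          seqs[[s]][o:(o + w - 1L)] <- planted
          sites <- rbind(sites, data.frame(seq = s, offset = o))
        }
      }
    }
    list(sequences = vapply(seqs, paste, character(1), collapse = ""),
         sites = sites[order(sites$seq, sites$offset), , drop = FALSE],
         word = motif_word)
  })
}
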