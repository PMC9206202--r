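PHRASE_ATTRIBUTES <- c("assertion", "severity", "temporal pattern", "laterality",
                       "spatial pattern", "quadrant pattern", "body location")
LOGIC_ATTRIBUTES <- c("specimen", "analyte", "abnormality")

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      stringsAsFactors = FALSE, comment.char = "#",
                      encoding = "UTF-8", check.names = FALSE),
    error = function(e) stop("parse error in '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("parse error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Load and validate a PhenoSSU attribute schema
#'
#' The schema defines the ten attribute categories of the PhenoSSU
#' entity-attribute-value model: seven phrase-based categories (assertion,
#' severity, temporal pattern, laterality, spatial pattern, quadrant
#' pattern, body location) and three logic-based categories (specimen,
#' analyte, abnormality). Each category carries a closed set of normalized
#' value labels; downstream components may only emit values from these
#' sets.
#'
#' @param path Path to a tab-delimited file with columns `attribute`,
#'   `subtype` (`phrase-based` or `logic-based`), `values` (labels
#'   separated by `|`, optionally `label=SNOMEDCODE`), `default`
#'   (optional member of `values`).
#' @return An object of class `phenossu_schema`: a list with elements
#'   `attributes` (named list of attribute definitions) and `version`.
#' @examples
#' sch <- load_schema(phenossu_file("phenossu_schema.tsv"))
#' length(sch$attributes)
#' @export
load_schema <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("attribute", "subtype", "values"), path)
  if (is.null(df$default)) df$default <- NA_character_
  attrs <- lapply(seq_len(nrow(df)), function(i) {
    vals_raw <- strsplit(df$values[i], "|", fixed = TRUE)[[1]]
    vals_raw <- trimws(vals_raw)
    vals_raw <- vals_raw[nzchar(vals_raw)]
    labels <- sub("=.*$", "", vals_raw)
    codes <- ifelse(grepl("=", vals_raw, fixed = TRUE),
                    sub("^[^=]*=", "", vals_raw), NA_character_)
    dflt <- df$default[i]
    if (!is.na(dflt) && !nzchar(trimws(dflt))) dflt <- NA_character_
    list(name = trimws(df$attribute[i]),
         subtype = trimws(df$subtype[i]),
         values = labels,
         codes = stats::setNames(codes, labels),
         default = if (is.na(dflt)) NULL else trimws(dflt))
  })
  names(attrs) <- vapply(attrs, `[[`, character(1), "name")
  schema <- structure(list(attributes = attrs, version = "1"),
                      class = "phenossu_schema")
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  attrs <- schema$attributes
  if (length(attrs) != 10)
    stop("validation error: schema must define exactly 10 attributes, got ",
         length(attrs), call. = FALSE)
  subtype <- vapply(attrs, `[[`, character(1), "subtype")
  bad <- names(attrs)[!subtype %in% c("phrase-based", "logic-based")]
  if (length(bad) > 0)
    stop("validation error: unknown subtype for attribute '", bad[1], "'",
         call. = FALSE)
  phr <- names(attrs)[subtype == "phrase-based"]
  lgc <- names(attrs)[subtype == "logic-based"]
  if (!setequal(phr, PHRASE_ATTRIBUTES))
    stop("validation error: phrase-based attribute set must be {",
         paste(PHRASE_ATTRIBUTES, collapse = ", "), "}", call. = FALSE)
  if (!setequal(lgc, LOGIC_ATTRIBUTES))
    stop("validation error: logic-based attribute set must be {",
         paste(LOGIC_ATTRIBUTES, collapse = ", "), "}", call. = FALSE)
  for (a in attrs) {
    if (length(a$values) == 0)
      stop("validation error: attribute '", a$name, "' has an empty value set",
           call. = FALSE)
    if (!is.null(a$default) && !a$default %in% a$values)
      stop("validation error: default '", a$default, "' of attribute '",
           a$name, "' is not in its value set", call. = FALSE)
  }
  if (!all(c("present", "absent") %in% attrs[["assertion"]]$values))
    stop("validation error: attribute 'assertion' must include values ",
         "'present' and 'absent'", call. = FALSE)
  if (!setequal(attrs[["abnormality"]]$values, c("higher", "lower", "normal")))
    stop("validation error: attribute 'abnormality' value set must be ",
         "{higher, lower, normal}", call. = FALSE)
  invisible(schema)
}

#' @export
print.phenossu_schema <- function(x, ...) {
  subtype <- vapply(x$attributes, `[[`, character(1), "subtype")
  cat("PhenoSSU schema:", length(x$attributes), "attributes (",
      sum(subtype == "phrase-based"), "phrase-based,",
      sum(subtype == "logic-based"), "logic-based )\n")
  for (a in x$attributes)
    cat(sprintf("  %-16s %-12s {%s}%s\n", a$name, a$subtype,
                paste(a$values, collapse = ", "),
                if (is.null(a$default)) "" else paste0(" default=", a$default)))
  invisible(x)
}

#' Serialize a schema back to its tab-delimited form
#' @param schema A `phenossu_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  rows <- vapply(schema$attributes, function(a) {
    vals <- ifelse(is.na(a$codes), a$values, paste0(a$values, "=", a$codes))
    paste(a$name, a$subtype, paste(vals, collapse = "|"),
          a$default %||% "", sep = "\t")
  }, character(1))
  writeLines(c("attribute\tsubtype\tvalues\tdefault", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Load a keyword lexicon
#'
#' A lexicon maps surface strings to encoder letters. `P` entries carry the
#' phenotype concept label in `normalization`; `A` entries name their
#' attribute category in `category` and the normalized value in
#' `normalization`; `S`/`L`/`R`/`U` entries carry specimen, analyte,
#' direction, or unit identifiers. Surface forms must be unique per letter;
#' duplicate rows are collapsed with a warning.
#'
#' @param path Path to a tab-delimited file with columns `surface`,
#'   `letter`, `category`, `normalization`.
#' @param schema Optional `phenossu_schema` used to validate `A` entries
#'   (category must be phrase-based; value must be in its closed set).
#' @return A `data.frame` of class `phenossu_lexicon`.
#' @export
load_lexicon <- function(path, schema = NULL) {
  df <- read_tsv_file(path)
  require_columns(df, c("surface", "letter", "category", "normalization"), path)
  as_lexicon(df, schema = schema)
}

#' Build a lexicon from a data frame
#' @param df Data frame with columns `surface`, `letter`, `category`,
#'   `normalization`.
#' @inheritParams load_lexicon
#' @return A validated `phenossu_lexicon`.
#' @export
as_lexicon <- function(df, schema = NULL) {
  df <- data.frame(surface = as.character(df$surface),
                   letter = as.character(df$letter),
                   category = as.character(df$category %||% NA),
                   normalization = as.character(df$normalization %||% NA),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$surface) | is.na(df$surface)))
      stop("validation error: lexicon contains an empty surface form",
           call. = FALSE)
    bad <- setdiff(unique(df$letter), LEXICON_LETTERS)
    if (length(bad) > 0)
      stop("validation error: unknown letter code '", bad[1],
           "' in lexicon (allowed: ", paste(LEXICON_LETTERS, collapse = ""),
           ")", call. = FALSE)
    key <- paste(df$surface, df$letter, sep = "\r")
    if (anyDuplicated(key)) {
      warning("lexicon: collapsed ", sum(duplicated(key)),
              " duplicate surface+letter row(s)")
      df <- df[!duplicated(key), , drop = FALSE]
    }
    # a surface may not be claimed by two different letters: matching would
    # be ambiguous at encode time
    amb <- unique(df$surface[duplicated(df$surface)])
    if (length(amb) > 0)
      stop("validation error: surface '", amb[1],
           "' is mapped to more than one letter", call. = FALSE)
    a_rows <- df$letter == "A"
    if (any(a_rows)) {
      if (any(is.na(df$category[a_rows]) | !nzchar(df$category[a_rows])))
        stop("validation error: A-entry without an attribute category",
             call. = FALSE)
      if (!is.null(schema)) {
        for (i in which(a_rows)) {
          cat_i <- df$category[i]
          ad <- schema$attributes[[cat_i]]
          if (is.null(ad) || ad$subtype != "phrase-based")
            stop("validation error: A-entry '", df$surface[i],
                 "' names unknown phrase-based attribute category '", cat_i,
                 "'", call. = FALSE)
          if (!df$normalization[i] %in% ad$values)
            stop("validation error: A-entry '", df$surface[i], "' value '",
                 df$normalization[i], "' is not in the closed set of '",
                 cat_i, "'", call. = FALSE)
        }
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("phenossu_lexicon", "data.frame")
  df
}

#' Serialize a lexicon to its tab-delimited form
#' @param lexicon A `phenossu_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- as.data.frame(lexicon)
  df$category[is.na(df$category)] <- ""
  df$normalization[is.na(df$normalization)] <- ""
  lines <- c("surface\tletter\tcategory\tnormalization",
             paste(df$surface, df$letter, df$category, df$normalization,
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load the laboratory-test knowledge base
#'
#' Each entry describes one laboratory test: the analyte and its synonyms,
#' the specimen, the canonical unit, the reference interval in the
#' canonical unit, multiplicative conversion factors for alternative
#' units, and the SNOMED CT concept codes attached to each abnormality
#' value.
#'
#' @param path Path to a tab-delimited file with columns `analyte`,
#'   `synonyms` (`|`-separated, may be empty), `specimen`, `unit`,
#'   `low`, `high`, `conversions` (`unit=factor` pairs, `|`-separated),
#'   `snomed_higher`, `snomed_lower`, `snomed_normal`.
#' @return A list of class `phenossu_lab_kb`; each element is one entry,
#'   with a `$synonym_index` attribute mapping every analyte name and
#'   synonym to candidate entry indices.
#' @export
load_lab_kb <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("analyte", "specimen", "unit", "low", "high"), path)
  chr <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  for (col in c("analyte", "synonyms", "specimen", "unit", "conversions",
                "snomed_higher", "snomed_lower", "snomed_normal"))
    df[[col]] <- if (is.null(df[[col]])) rep("", nrow(df)) else chr(df[[col]])
  entries <- lapply(seq_len(nrow(df)), function(i) {
    low <- as.numeric(df$low[i]); high <- as.numeric(df$high[i])
    if (is.na(low) || is.na(high))
      stop("validation error: non-numeric reference range for analyte '",
           df$analyte[i], "'", call. = FALSE)
    if (low >= high)
      stop("validation error: reference range low >= high for analyte '",
           df$analyte[i], "'", call. = FALSE)
    unit <- trimws(df$unit[i])
    if (!nzchar(unit))
      stop("validation error: missing canonical unit for analyte '",
           df$analyte[i], "'", call. = FALSE)
    conv <- c()
    conv_raw <- trimws(df$conversions[i] %||% "")
    if (nzchar(conv_raw) && !is.na(conv_raw)) {
      parts <- strsplit(conv_raw, "|", fixed = TRUE)[[1]]
      for (p in parts) {
        kv <- strsplit(p, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2 || is.na(suppressWarnings(as.numeric(kv[2]))))
          stop("validation error: malformed unit conversion '", p,
               "' for analyte '", df$analyte[i], "'", call. = FALSE)
        fac <- as.numeric(kv[2])
        if (fac <= 0)
          stop("validation error: non-positive conversion factor for unit '",
               kv[1], "' of analyte '", df$analyte[i], "'", call. = FALSE)
        conv[trimws(kv[1])] <- fac
      }
    }
    syn <- trimws(strsplit(df$synonyms[i] %||% "", "|", fixed = TRUE)[[1]])
    syn <- syn[nzchar(syn)]
    snomed <- c(higher = trimws(as.character(df$snomed_higher[i])),
                lower = trimws(as.character(df$snomed_lower[i])),
                normal = trimws(as.character(df$snomed_normal[i])))
    snomed <- snomed[nzchar(snomed) & !is.na(snomed)]
    spec <- trimws(as.character(df$specimen[i]))
    list(analyte = trimws(df$analyte[i]), synonyms = syn,
         specimen = if (nzchar(spec) && !is.na(spec)) spec else NULL,
         unit = unit, low = low, high = high,
         conversions = conv, snomed = snomed)
  })
  kb <- structure(entries, class = "phenossu_lab_kb")
  attr(kb, "synonym_index") <- build_synonym_index(entries)
  kb
}

build_synonym_index <- function(entries) {
  idx <- list()
  for (i in seq_along(entries)) {
    for (nm in unique(c(entries[[i]]$analyte, entries[[i]]$synonyms)))
      idx[[nm]] <- c(idx[[nm]], i)
  }
  idx
}

#' Serialize a lab knowledge base to its tab-delimited form
#' @param kb A `phenossu_lab_kb`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lab_kb <- function(kb, path) {
  rows <- vapply(kb, function(e) {
    conv <- if (length(e$conversions) == 0) "" else
      paste(names(e$conversions), unname(e$conversions), sep = "=",
            collapse = "|")
    sn <- function(k) {
      v <- unname(e$snomed[k])
      if (length(v) == 0 || is.na(v)) "" else v
    }
    paste(e$analyte, paste(e$synonyms, collapse = "|"), e$specimen %||% "",
          e$unit, format(e$low, scientific = FALSE),
          format(e$high, scientific = FALSE), conv,
          sn("higher"), sn("lower"), sn("normal"), sep = "\t")
  }, character(1))
  writeLines(c(paste("analyte", "synonyms", "specimen", "unit", "low", "high",
                     "conversions", "snomed_higher", "snomed_lower",
                     "snomed_normal", sep = "\t"), rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Path to a file shipped with the package
#' @param ... File name components under the package's `extdata` directory.
#' @return An absolute path.
#' @export
phenossu_file <- function(...) {
  system.file("extdata", ..., package = "phenossu", mustWork = TRUE)
}
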