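# Resolve an analyte mention against the knowledge base. `name` is the
# normalized analyte label from the lexicon; `specimen` (when given)
# disambiguates analytes shared by several specimens.
resolve_analyte <- function(name, specimen, kb) {
  idx <- attr(kb, "synonym_index")[[name]]
  if (is.null(idx)) return(list(entry = NULL, note = "unresolved-analyte"))
  if (length(idx) > 1 && !is.null(specimen)) {
    hit <- idx[vapply(kb[idx], function(e)
      identical(e$specimen, specimen), logical(1))]
    if (length(hit) >= 1) idx <- hit
  }
  if (length(idx) > 1)
    return(list(entry = NULL,
                note = paste0("ambiguous-analyte: candidates ",
                              paste(vapply(kb[idx], function(e)
                                paste0(e$analyte, "/",
                                       e$specimen %||% "?"), character(1)),
                                collapse = ", "))))
  list(entry = kb[[idx]], note = NULL)
}

lab_observation <- function(entry, specimen, value = NULL, unit = NULL,
                            direction = NULL, abnormality = NA_character_,
                            note = NULL) {
  snomed <- NULL
  if (!is.null(entry) && !is.na(abnormality)) {
    code <- unname(entry$snomed[abnormality])
    if (length(code) == 1 && !is.na(code)) snomed <- code
  }
  structure(list(specimen = specimen,
                 analyte = if (is.null(entry)) NULL else entry$analyte,
                 value = value, unit = unit, direction = direction,
                 abnormality = abnormality, snomed = snomed, note = note),
            class = "phenossu_lab_observation")
}

#' Interpret a quantitative lab match (analyte, number, unit)
#'
#' Resolves the analyte against the knowledge base, converts the numeric
#' value to the entry's canonical unit, and compares it to the reference
#' interval: `higher` above the upper bound, `lower` below the lower
#' bound, `normal` inside the closed interval `[low, high]` (a value
#' exactly on a bound is normal). The abnormality is mapped to a SNOMED
#' CT concept code when the entry carries one. Unresolvable analytes or
#' unconvertible units yield an observation with `abnormality = NA` and a
#' diagnostic `note` rather than an error.
#'
#' @param analyte Normalized analyte label (from the `L` letter payload).
#' @param value Numeric value (from the `N` letter payload, exponent
#'   already applied).
#' @param unit Unit label (from the `U` letter payload).
#' @param kb A `phenossu_lab_kb`.
#' @param specimen Optional specimen label (from an `S` letter); when
#'   absent the entry's own specimen is used.
#' @return A `phenossu_lab_observation`.
#' @examples
#' kb <- load_lab_kb(phenossu_file("lab_kb.tsv"))
#' obs <- interpret_lnu("leukocyte", 1.25e10, "/L", kb)
#' obs$abnormality  # "higher"
#' @export
interpret_lnu <- function(analyte, value, unit, kb, specimen = NULL) {
  res <- resolve_analyte(analyte, specimen, kb)
  if (is.null(res$entry))
    return(lab_observation(NULL, specimen, value = value, unit = unit,
                           note = res$note))
  entry <- res$entry
  factor <- if (identical(unit, entry$unit)) 1 else
    unname(entry$conversions[unit])
  if (is.null(factor) || length(factor) == 0 || is.na(factor))
    return(lab_observation(entry, specimen %||% entry$specimen,
                           value = value, unit = unit,
                           note = paste0("unconvertible-unit: '", unit,
                                         "' for analyte '", entry$analyte,
                                         "'")))
  v <- value * factor
  abnormality <- if (v > entry$high) "higher" else
    if (v < entry$low) "lower" else "normal"
  lab_observation(entry, specimen %||% entry$specimen, value = v,
                  unit = entry$unit, abnormality = abnormality)
}

#' Interpret a qualitative lab match (analyte, direction word)
#'
#' The direction word's normalized value (`higher`, `lower` or `normal`)
#' becomes the abnormality directly; the SNOMED code is looked up as for
#' quantitative results.
#'
#' @param analyte Normalized analyte label.
#' @param direction One of `"higher"`, `"lower"`, `"normal"` (from the
#'   `R` letter payload).
#' @param kb A `phenossu_lab_kb`.
#' @param specimen Optional specimen label.
#' @return A `phenossu_lab_observation`.
#' @export
interpret_lr <- function(analyte, direction, kb, specimen = NULL) {
  if (!direction %in% c("higher", "lower", "normal"))
    stop("direction word must normalize to higher/lower/normal, got '",
         direction, "'", call. = FALSE)
  res <- resolve_analyte(analyte, specimen, kb)
  if (is.null(res$entry))
    return(lab_observation(NULL, specimen, direction = direction,
                           abnormality = direction, note = res$note))
  lab_observation(res$entry, specimen %||% res$entry$specimen,
                  direction = direction, abnormality = direction)
}

#' Convert a value between a knowledge-base entry's units
#' @param entry A lab KB entry.
#' @param value Numeric value.
#' @param from,to Unit labels (the canonical unit or any unit with a
#'   conversion factor).
#' @return The converted value.
#' @export
convert_unit <- function(entry, value, from, to) {
  fac <- function(u) {
    if (identical(u, entry$unit)) return(1)
    f <- unname(entry$conversions[u])
    if (length(f) == 0 || is.na(f))
      stop("no conversion for unit '", u, "'", call. = FALSE)
    f
  }
  value * fac(from) / fac(to)
}
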