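INSTANCES_HEADER <- "# phenossu instances v1"

instance_to_list <- function(inst) {
  list(doc = inst$doc %||% NA,
       phenotype = inst$phenotype,
       category = inst$category,
       span = inst$span,
       snomed = inst$snomed,
       pattern = inst$pattern,
       attributes = lapply(inst$attributes, function(a)
         list(value = a$value, span = a$span, default = isTRUE(a$default))))
}

#' Write instances as JSON lines
#'
#' One instance per line, preceded by a schema-versioned header comment.
#' When a schema is supplied, every attribute value is validated against
#' its closed set before writing.
#'
#' @param instances List of `phenossu_instance` objects.
#' @param path Output path.
#' @param schema Optional `phenossu_schema` for validation.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path, schema = NULL) {
  if (!is.null(schema))
    for (inst in instances)
      validate_attribute_values(inst$attributes, schema,
                                schema_subtype(schema, inst))
  lines <- vapply(instances, function(inst)
    as.character(jsonlite::toJSON(instance_to_list(inst), auto_unbox = TRUE,
                                  null = "null", digits = NA)),
    character(1))
  writeLines(c(INSTANCES_HEADER, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read instances written by [write_instances()]
#' @param path Input path.
#' @return A list of `phenossu_instance` objects.
#' @export
read_instances <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    atts <- lapply(x$attributes, function(a)
      list(value = a$value,
           span = if (is.null(a$span)) NULL else as.numeric(a$span),
           default = isTRUE(a$default)))
    inst <- new_instance(phenotype = x$phenotype, span = as.numeric(x$span),
                         attributes = atts, category = x$category,
                         snomed = x$snomed,
                         pattern = x$pattern %||% NA_character_)
    if (!is.null(x$doc) && !is.na(x$doc)) inst$doc <- x$doc
    inst
  })
}

#' Write motifs in a minimal MEME-like text format
#'
#' An alphabet line, then per motif a header (width, site count, E-value,
#' log-likelihood ratio, consensus) followed by the letter-probability
#' matrix, one row per motif position.
#'
#' @param motifs List of `phenossu_motif` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  lines <- c("MEME-like motif file (phenossu)",
             paste0("ALPHABET= ", paste(PHENOSSU_ALPHABET, collapse = "")),
             "")
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    lines <- c(lines,
               sprintf("MOTIF m%d %s", i, m$consensus),
               sprintf(paste("letter-probability matrix: alength= %d w= %d",
                             "nsites= %d E= %s llr= %s"),
                       ncol(m$pwm), m$width, m$nsites,
                       format(m$evalue, digits = 15),
                       format(m$llr, digits = 15)),
               apply(m$pwm, 1, function(r)
                 paste(format(r, digits = 15, scientific = TRUE),
                       collapse = " ")),
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read motifs written by [write_motifs()]
#' @param path Input path.
#' @return A list of `phenossu_motif` objects (PWM, width, site count,
#'   E-value, LLR, consensus; site lists are not persisted).
#' @export
read_motifs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  starts <- grep("^MOTIF ", lines)
  lapply(starts, function(s) {
    hdr <- strsplit(lines[s + 1], "\\s+")[[1]]
    grab <- function(key) {
      i <- which(hdr == key)
      as.numeric(hdr[i + 1])
    }
    w <- as.integer(grab("w="))
    pwm <- do.call(rbind, lapply(lines[(s + 2):(s + 1 + w)], function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    colnames(pwm) <- PHENOSSU_ALPHABET
    structure(list(width = w, pwm = pwm, lambda = NA_real_,
                   sites = data.frame(seq = integer(0), offset = integer(0),
                                      posterior = numeric(0)),
                   llr = grab("llr="), evalue = grab("E="),
                   consensus = strsplit(lines[s], " ", fixed = TRUE)[[1]][3],
                   trace = numeric(0), nsites = as.integer(grab("nsites="))),
              class = "phenossu_motif")
  })
}
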