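brat_attr_name <- function(category) {
  gsub(" ", "_", category)
}

brat_attr_category <- function(name) {
  gsub("_", " ", name)
}

#' Read a brat standoff document
#'
#' Parses the `.txt`/`.ann` pair of the brat rapid annotation tool:
#' `T` lines are typed entities with 0-based half-open character offsets,
#' `A` lines attach an attribute value to an entity. Unknown line types
#' are skipped with a warning. Every entity's quoted surface must equal
#' the corresponding text slice.
#'
#' @param txt_path Path to the document text.
#' @param ann_path Path to the annotation file.
#' @return A list of class `phenossu_brat_document`: `text`, `entities`
#'   (data frame `id`, `type`, `start`, `end`, `surface`), `attributes`
#'   (data frame `id`, `name`, `entity`, `value`).
#' @export
read_brat <- function(txt_path, ann_path) {
  if (!file.exists(txt_path)) stop("file not found: ", txt_path, call. = FALSE)
  if (!file.exists(ann_path)) stop("file not found: ", ann_path, call. = FALSE)
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  ents <- list(); atts <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- fields[1]
    if (startsWith(id, "T")) {
      hdr <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      start <- as.integer(hdr[2]); end <- as.integer(hdr[3])
      surface <- if (length(fields) >= 3) fields[3] else ""
      slice <- substr(text, start + 1L, end)
      if (!identical(slice, surface))
        stop("integrity error: entity ", id, " surface '", surface,
             "' does not match text slice '", slice, "'", call. = FALSE)
      ents[[length(ents) + 1L]] <- data.frame(
        id = id, type = hdr[1], start = start, end = end, surface = surface,
        stringsAsFactors = FALSE)
    } else if (startsWith(id, "A")) {
      parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      atts[[length(atts) + 1L]] <- data.frame(
        id = id, name = parts[1], entity = parts[2],
        value = if (length(parts) >= 3) parts[3] else "true",
        stringsAsFactors = FALSE)
    } else {
      warning("skipping unknown annotation line type: ",
              substr(ln, 1, 20))
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else
    data.frame(id = character(0), type = character(0), start = integer(0),
               end = integer(0), surface = character(0),
               stringsAsFactors = FALSE)
  attributes <- if (length(atts)) do.call(rbind, atts) else
    data.frame(id = character(0), name = character(0), entity = character(0),
               value = character(0), stringsAsFactors = FALSE)
  bad <- setdiff(attributes$entity, entities$id)
  if (length(bad) > 0)
    stop("integrity error: attribute references unknown entity ", bad[1],
         call. = FALSE)
  structure(list(text = text, entities = entities, attributes = attributes),
            class = "phenossu_brat_document")
}

#' Write a document and annotations in brat standoff format
#'
#' @param text Document text.
#' @param entities Data frame with `type`, `start`, `end` (0-based
#'   half-open) and optionally `surface`.
#' @param attributes Optional data frame with `name`, `entity` (row index
#'   into `entities` or a `T` id), `value`.
#' @param txt_path,ann_path Output paths.
#' @return `ann_path`, invisibly.
#' @export
write_brat <- function(text, entities, attributes = NULL, txt_path,
                       ann_path) {
  writeLines(text, txt_path, useBytes = TRUE, sep = "")
  ann <- character(0)
  for (i in seq_len(nrow(entities))) {
    surface <- substr(text, entities$start[i] + 1L, entities$end[i])
    ann <- c(ann, sprintf("T%d\t%s %d %d\t%s", i, entities$type[i],
                          entities$start[i], entities$end[i], surface))
  }
  if (!is.null(attributes) && nrow(attributes) > 0) {
    for (j in seq_len(nrow(attributes))) {
      ref <- attributes$entity[j]
      tid <- if (grepl("^T", ref)) ref else paste0("T", ref)
      ann <- c(ann, sprintf("A%d\t%s %s %s", j, attributes$name[j], tid,
                            attributes$value[j]))
    }
  }
  writeLines(ann, ann_path, useBytes = TRUE)
  invisible(ann_path)
}

#' Write a synthetic corpus to a directory
#'
#' Emits one `.txt`/`.ann` pair per document (entities plus instance
#' attribute annotations anchored on the phenotype entity) and a single
#' `instances.jsonl` with the gold instances of all documents.
#'
#' @param corpus A `phenossu_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_instances <- list()
  for (doc in corpus$docs) {
    ent <- doc$entities
    atts <- list()
    for (inst in doc$instances) {
      anchor <- which(ent$start == inst$span[1] &
                        ent$type %in% c("Phenotype", "Analyte"))
      if (length(anchor) == 0) next
      for (nm in names(inst$attributes))
        atts[[length(atts) + 1L]] <- data.frame(
          name = brat_attr_name(nm), entity = anchor[1],
          value = inst$attributes[[nm]]$value, stringsAsFactors = FALSE)
    }
    att_df <- if (length(atts)) do.call(rbind, atts) else NULL
    write_brat(doc$text, ent, att_df,
               file.path(dir, paste0(doc$id, ".txt")),
               file.path(dir, paste0(doc$id, ".ann")))
    all_instances <- c(all_instances, doc$instances)
  }
  write_instances(all_instances, file.path(dir, "instances.jsonl"))
  invisible(dir)
}
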