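# ---- entity-level exact-span F1 --------------------------------------------

#' Exact-span entity precision, recall and F1
#'
#' A predicted entity counts as a true positive only when its document,
#' character span and type all coincide with a gold entity (one-to-one
#' matching). Precision is TP over predicted, recall TP over gold, F1
#' their harmonic mean (0 when both are empty of matches).
#'
#' @param pred,gold Data frames with columns `start`, `end`, `type` and
#'   optionally `doc` (defaults to one document).
#' @return A list with `precision`, `recall`, `f1`, `tp`.
#' @export
entity_f1 <- function(pred, gold) {
  key <- function(df) {
    doc <- df$doc %||% rep(1L, nrow(df))
    paste(doc, df$start, df$end, df$type, sep = "\r")
  }
  kp <- key(pred); kg <- key(gold)
  if (anyDuplicated(kg)) {
    warning("duplicate gold entities deduplicated")
    kg <- unique(kg)
  }
  tp <- sum(kg %in% unique(kp))  # one-to-one on exact (doc, span, type)
  precision <- if (length(kp) == 0) 0 else tp / length(kp)
  recall <- if (length(kg) == 0) 0 else tp / length(kg)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, tp = tp)
}

# ---- attribute scores -------------------------------------------------------

pair_instances <- function(pred, gold) {
  pdoc <- vapply(pred, function(x) as.character(x$doc %||% 1), character(1))
  pspan <- vapply(pred, function(x)
    paste(x$span, collapse = "-"), character(1))
  pkey <- paste(pdoc, pspan)
  used <- logical(length(pred))
  vapply(gold, function(g) {
    k <- paste(as.character(g$doc %||% 1), paste(g$span, collapse = "-"))
    hit <- which(pkey == k & !used)
    if (length(hit) == 0) return(NA_integer_)
    used[hit[1]] <<- TRUE
    hit[1]
  }, integer(1))
}

#' Attribute-prediction accuracies
#'
#' Gold instances are paired with predictions by exact phenotype span
#' (unpaired gold instances count every attribute slot wrong). For every
#' attribute value `v`, `acc_v` is the fraction of gold slots carrying
#' `v` that were predicted exactly. The average accuracy is the mean of
#' the per-category accuracies; the weighted average is
#' `sum_v w_v * acc_v` with `w_v` proportional to the value's support
#' (set `weighting = "uniform"` for equal weight per value; both are
#' returned in the report).
#'
#' @param pred,gold Lists of `phenossu_instance` objects (optionally
#'   carrying `$doc`).
#' @param schema A `phenossu_schema`; predicted values outside its closed
#'   sets raise a validation error.
#' @param weighting `"frequency"` (default) or `"uniform"`, selecting
#'   which weighted average is reported as `weighted_average`.
#' @return A list: `per_value` (data frame value/category/support/acc),
#'   `per_category`, `average`, `weighted_average`,
#'   `weighted_average_frequency`, `weighted_average_uniform`.
#' @export
attribute_scores <- function(pred, gold, schema,
                             weighting = c("frequency", "uniform")) {
  weighting <- match.arg(weighting)
  for (p in pred)
    validate_attribute_values(p$attributes, schema,
                              schema_subtype(schema, p))
  pairing <- pair_instances(pred, gold)
  rows <- list()
  for (i in seq_along(gold)) {
    g <- gold[[i]]
    p <- if (is.na(pairing[i])) NULL else pred[[pairing[i]]]
    for (cat_nm in names(g$attributes)) {
      gv <- g$attributes[[cat_nm]]$value
      pv <- if (is.null(p)) NA_character_ else
        (p$attributes[[cat_nm]]$value %||% NA_character_)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_nm, value = gv,
        correct = !is.na(pv) && identical(pv, gv),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no gold attribute slots to score", call. = FALSE)
  slots <- do.call(rbind, rows)
  per_value <- do.call(rbind, lapply(
    split(slots, paste(slots$category, slots$value, sep = "\r")),
    function(d) data.frame(category = d$category[1], value = d$value[1],
                           support = nrow(d), acc = mean(d$correct),
                           stringsAsFactors = FALSE)))
  per_value <- per_value[order(per_value$category, per_value$value), ]
  rownames(per_value) <- NULL
  per_category <- do.call(rbind, lapply(split(slots, slots$category),
    function(d) data.frame(category = d$category[1], support = nrow(d),
                           acc = mean(d$correct), stringsAsFactors = FALSE)))
  rownames(per_category) <- NULL
  w_freq <- per_value$support / sum(per_value$support)
  wa_freq <- sum(w_freq * per_value$acc)
  wa_unif <- mean(per_value$acc)
  list(per_value = per_value, per_category = per_category,
       average = mean(per_category$acc),
       weighted_average = if (weighting == "frequency") wa_freq else wa_unif,
       weighted_average_frequency = wa_freq,
       weighted_average_uniform = wa_unif)
}

schema_subtype <- function(schema, inst) {
  if (identical(inst$category, "logic-based")) "logic-based" else "phrase-based"
}

# ---- instance-level accuracy ------------------------------------------------

#' Instance-level accuracy
#'
#' The fraction of gold instances for which a prediction matches the
#' phenotype concept and every attribute slot exactly. Instances are
#' paired by exact evidence span when spans are available, by identity
#' key otherwise; each prediction can satisfy at most one gold instance.
#'
#' @param pred,gold Lists of `phenossu_instance` objects.
#' @return A single number in `[0, 1]`.
#' @export
instance_accuracy <- function(pred, gold) {
  if (length(gold) == 0)
    stop("instance accuracy is undefined for an empty gold set",
         call. = FALSE)
  pairing <- pair_instances(pred, gold)
  pred_keys <- vapply(pred, instance_key, character(1))
  used <- logical(length(pred))
  used[pairing[!is.na(pairing)]] <- TRUE
  correct <- vapply(seq_along(gold), function(i) {
    g <- gold[[i]]
    if (!is.na(pairing[i]))
      return(identical(instance_key(pred[[pairing[i]]]), instance_key(g)))
    hit <- which(pred_keys == instance_key(g) & !used)
    if (length(hit) == 0) return(FALSE)
    used[hit[1]] <<- TRUE
    TRUE
  }, logical(1))
  mean(correct)
}

# ---- inter-annotator agreement ----------------------------------------------

#' Cohen's kappa for two categorical label sequences
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal products. Returns 1 when the
#' observed agreement is perfect (including constant sequences).
#'
#' @param labels_a,labels_b Equal-length vectors of categorical labels.
#' @return Cohen's kappa.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences must have equal length", call. = FALSE)
  if (length(labels_a) == 0) stop("empty label sequences", call. = FALSE)
  po <- mean(labels_a == labels_b)
  if (po == 1) return(1)
  lev <- union(labels_a, labels_b)
  pa <- table(factor(labels_a, lev)) / length(labels_a)
  pb <- table(factor(labels_b, lev)) / length(labels_b)
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  (po - pe) / (1 - pe)
}

# ---- minimum-corpus-size experiment -----------------------------------------

#' Minimum corpus size covering all target patterns
#'
#' Emulates the stepwise-sampling experiment: per repetition, documents
#' are added in a random order and the count at which every target
#' pattern has matched at least once is recorded; the mean and standard
#' deviation over repetitions are returned.
#'
#' @param doc_letters Character vector of encoded letter sequences, one
#'   per document.
#' @param target_patterns Character vector of alphabet regular
#'   expressions; each must match somewhere in the corpus.
#' @param n_reps Number of repetitions (default 1000).
#' @param seed Integer seed.
#' @return A list with `mean`, `sd`, `counts` (per-repetition values)
#'   and `coverage` (documents x patterns logical matrix).
#' @export
min_corpus_size <- function(doc_letters, target_patterns, n_reps = 1000,
                            seed = 1) {
  cov <- vapply(target_patterns, function(p)
    grepl(p, doc_letters, perl = TRUE), logical(length(doc_letters)))
  cov <- matrix(cov, nrow = length(doc_letters),
                dimnames = list(NULL, target_patterns))
  nowhere <- colnames(cov)[colSums(cov) == 0]
  if (length(nowhere) > 0)
    stop("target pattern matches nowhere in the corpus: '", nowhere[1], "'",
         call. = FALSE)
  counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      ord <- sample(nrow(cov))
      seen <- apply(cov[ord, , drop = FALSE], 2, cumsum) > 0
      which(rowSums(seen) == ncol(cov))[1]
    }, numeric(1))
  })
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts,
       coverage = cov)
}

# ---- instance-set comparison (case-study method) ----------------------------

#' Compare two instance sets at the phenotype-plus-attribute level
#'
#' Instances are reduced to their identity keys (phenotype concept and
#' attribute-value map; spans ignored) and compared as sets.
#'
#' @param set_a,set_b Lists of `phenossu_instance` objects.
#' @return A list of sorted key vectors: `shared`, `only_a`, `only_b`.
#' @export
compare_instance_sets <- function(set_a, set_b) {
  ka <- unique(vapply(set_a, instance_key, character(1)))
  kb <- unique(vapply(set_b, instance_key, character(1)))
  list(shared = sort(intersect(ka, kb)),
       only_a = sort(setdiff(ka, kb)),
       only_b = sort(setdiff(kb, ka)))
}
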