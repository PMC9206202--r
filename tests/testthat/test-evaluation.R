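mk_inst <- function(phenotype, values, span = c(0, 1), doc = 1,
                    category = "phrase-based") {
  atts <- lapply(values, function(v) list(value = v, span = NULL,
                                          default = FALSE))
  inst <- phenossu:::new_instance(phenotype, span, atts, category)
  inst$doc <- doc
  inst
}

test_that("exact-span entity F1 matches hand computations", {
  gold <- data.frame(start = c(0, 5, 10), end = c(2, 7, 12),
                     type = "Phenotype")
  expect_equal(entity_f1(gold, gold),
               list(precision = 1, recall = 1, f1 = 1, tp = 3))
  pred_disjoint <- data.frame(start = 20, end = 22, type = "Phenotype")
  r <- entity_f1(pred_disjoint, gold)
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
  # 3 gold, 2 pred, 1 exact match -> P = 1/2, R = 1/3, F1 = 0.4
  pred <- data.frame(start = c(0, 20), end = c(2, 22), type = "Phenotype")
  r2 <- entity_f1(pred, gold)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 1 / 3)
  expect_equal(r2$f1, 0.4)
  expect_equal(r2$f1,
               2 * r2$precision * r2$recall / (r2$precision + r2$recall))
  expect_warning(entity_f1(pred, rbind(gold, gold[1, ])), "duplicate")
})

test_that("attribute accuracies and their weightings match hand values", {
  gold <- c(lapply(1:9, function(i)
    mk_inst("cough", list(severity = "severe"), span = c(i * 10, i * 10 + 2),
            doc = 1)),
    list(mk_inst("fever", list(severity = "mild"), span = c(200, 202))))
  pred <- c(lapply(1:9, function(i)
    mk_inst("cough", list(severity = "severe"), span = c(i * 10, i * 10 + 2),
            doc = 1)),
    list(mk_inst("fever", list(severity = "severe"), span = c(200, 202))))
  sc <- attribute_scores(pred, gold, fixture_schema)
  # severe: 9/9 correct; mild: 0/1 correct
  expect_equal(sc$weighted_average_frequency, 0.9)
  expect_equal(sc$weighted_average_uniform, 0.5)
  expect_equal(sc$average, 0.9)   # one category, 9/10 slots right

  all_right <- attribute_scores(gold, gold, fixture_schema)
  expect_equal(all_right$average, 1)
  expect_equal(all_right$weighted_average, 1)

  wrong <- lapply(gold, function(g) {
    g$attributes$severity$value <- "moderate"
    g
  })
  all_wrong <- attribute_scores(wrong, gold, fixture_schema)
  expect_equal(all_wrong$average, 0)
  expect_equal(all_wrong$weighted_average, 0)

  bad <- list(mk_inst("cough", list(severity = "gigantic"),
                      span = c(0, 2)))
  expect_error(attribute_scores(bad, gold, fixture_schema),
               "closed set")
})

test_that("unmatched gold instances count all their slots wrong", {
  gold <- list(mk_inst("cough", list(severity = "severe"), span = c(0, 2)),
               mk_inst("fever", list(severity = "severe"), span = c(9, 11)))
  pred <- list(mk_inst("cough", list(severity = "severe"), span = c(0, 2)))
  sc <- attribute_scores(pred, gold, fixture_schema)
  expect_equal(sc$per_value$acc, 0.5)
})

test_that("instance accuracy requires every slot to match", {
  a <- mk_inst("cough", list(assertion = "present", severity = "severe"),
               span = c(0, 2))
  b <- mk_inst("fever", list(assertion = "absent"), span = c(10, 12))
  expect_equal(instance_accuracy(list(a, b), list(a, b)), 1)
  b_wrong <- b
  b_wrong$attributes$assertion$value <- "present"
  expect_equal(instance_accuracy(list(a, b_wrong), list(a, b)), 0.5)
  expect_error(instance_accuracy(list(a), list()), "empty gold")
})

test_that("Cohen's kappa matches the contingency-table oracle", {
  expect_equal(cohen_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c")), 1)
  # 2x2 table [[20, 5], [10, 15]]: po = 0.7, pe = 0.5, kappa = 0.4
  a <- c(rep("x", 25), rep("y", 25))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(cohen_kappa(a, b), 0.4)
  # independent labels constructed to have agreement equal to chance
  a2 <- rep(c("x", "y"), 50)
  b2 <- rep(c("x", "x", "y", "y"), 25)
  expect_lt(abs(cohen_kappa(a2, b2)), 0.05)
  expect_error(cohen_kappa(c("a"), c("a", "b")), "equal length")
})

test_that("minimum corpus size is exact on forced constructions", {
  # every document covers all patterns
  r1 <- min_corpus_size(rep("APSLR", 5), c("A", "P"), n_reps = 50, seed = 1)
  expect_equal(r1$mean, 1)
  expect_equal(r1$sd, 0)
  # two documents covering disjoint halves force both to be drawn
  r2 <- min_corpus_size(c("AAP", "SLR"), c("AP", "LR"), n_reps = 50,
                        seed = 1)
  expect_equal(r2$mean, 2)
  expect_equal(r2$sd, 0)
  expect_error(min_corpus_size(c("AAP"), c("LR")), "matches nowhere")
})

test_that("minimum corpus size agrees with exhaustive enumeration", {
  docs <- c("AP", "LR", "APLR", "OOO")
  pats <- c("AP", "LR")
  # exact expectation over all 4! equally likely document orders
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  cov <- cbind(AP = grepl("AP", docs), LR = grepl("LR", docs))
  exact <- mean(apply(perms, 1, function(ord) {
    seen <- apply(cov[ord, , drop = FALSE], 2, cumsum) > 0
    which(rowSums(seen) == 2)[1]
  }))
  mc <- min_corpus_size(docs, pats, n_reps = 4000, seed = 2)
  se <- stats::sd(mc$counts) / sqrt(length(mc$counts))
  expect_lt(abs(mc$mean - exact), 3 * se + 1e-9)
})

test_that("enriching coverage cannot increase the expected corpus size", {
  sparse <- c("AP", "LR", "OO", "OO")
  rich <- c("APLR", "APLR", "AP", "LR")
  m1 <- min_corpus_size(sparse, c("AP", "LR"), n_reps = 400, seed = 3)$mean
  m2 <- min_corpus_size(rich, c("AP", "LR"), n_reps = 400, seed = 3)$mean
  expect_lte(m2, m1)
})

test_that("instance-set comparison is an exact set operation", {
  g1 <- mk_inst("cough", list(`temporal pattern` = "chronic"))
  g2 <- mk_inst("cough", list(`temporal pattern` = "recurrent"))
  e1 <- mk_inst("cough", list(`temporal pattern` = "occasional"))
  e2 <- mk_inst("cough", list(severity = "severe"))
  guideline <- list(g1, g2)
  ehr <- list(g1, g2, e1, e2)
  cmp <- compare_instance_sets(guideline, ehr)
  expect_length(cmp$shared, 2)
  expect_length(cmp$only_a, 0)
  expect_length(cmp$only_b, 2)
  # mirror symmetry
  rev_cmp <- compare_instance_sets(ehr, guideline)
  expect_equal(rev_cmp$only_a, cmp$only_b)
  expect_equal(rev_cmp$only_b, cmp$only_a)
  expect_equal(compare_instance_sets(guideline, guideline)$only_a,
               character(0))
  sub <- compare_instance_sets(guideline, ehr)
  expect_equal(length(sub$only_b), length(ehr) - length(guideline))
})
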