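test_that("60/20/20 splits are stratified, exhaustive, disjoint, deterministic", {
  ds <- random_dataset(30, 50, seed = 1)  # 50 per class
  sp <- split_dataset(ds, seed = 5)
  per_class <- function(d) table(d$labels)
  expect_equal(unname(per_class(sp$train)), c(30L, 30L), ignore_attr = TRUE)
  expect_equal(unname(per_class(sp$validation)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_equal(unname(per_class(sp$test)), c(10L, 10L), ignore_attr = TRUE)
  all_idx <- sort(unname(unlist(sp$idx)))
  expect_identical(all_idx, seq_len(100L))
  expect_identical(split_dataset(ds, seed = 5)$idx, sp$idx)
  expect_false(identical(split_dataset(ds, seed = 6)$idx, sp$idx))
  tiny <- random_dataset(10, 4, seed = 2)
  expect_error(split_dataset(tiny, seed = 1),
               class = "pathact_validation_error")
})

test_that("rank-statistic AUC matches brute-force concordance and hand values", {
  y <- factor(c("1", "1", "0", "0"), levels = c("0", "1"))
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.1), y), 1)
  expect_equal(auc_score(rep(0.5, 4), y), 0.5)
  expect_true(is.na(auc_score(1:3, factor(rep("0", 3), levels = c("0", "1")))))
  for (s in 1:10) {
    sc <- pathact:::with_seed(s, {
      n <- sample(6:30, 1)
      list(scores = round(runif(n), 2),  # rounding forces ties
           labels = factor(sample(c("0", "1"), n, replace = TRUE,
                                  prob = c(0.5, 0.5)),
                           levels = c("0", "1")))
    })
    if (length(unique(sc$labels)) < 2) next
    expect_identical(auc_score(sc$scores, sc$labels),
                     oracle_auc(sc$scores, sc$labels))
  }
})

test_that("classifier evaluation reports perfect separation and chance correctly", {
  y <- factor(rep(c("normal", "tumour"), each = 10),
              levels = c("normal", "tumour"))
  x <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1,
              dimnames = list(NULL, "F1"))
  for (cl in c("nb", "knn", "lr")) {
    ev <- evaluate_classifier(cl, x, y, x, y)
    expect_equal(ev$auc, 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(unname(ev$confusion[c("TP", "TN")]), c(10, 10))
  }
})

test_that("greedy selection keeps a candidate only on strict AUC improvement", {
  set.seed(42)
  n <- 40
  y <- factor(rep(c("normal", "tumour"), each = n / 2),
              levels = c("normal", "tumour"))
  sig <- ifelse(y == "tumour", 3, -3)
  # candidate 1 separates perfectly: later candidates can never be kept
  x <- cbind(F1 = sig + rnorm(n, sd = 0.1), F2 = rnorm(n), F3 = rnorm(n))
  sel <- forward_select(x, y, x, y, "lr")
  expect_identical(sel$selected, "F1")
  expect_equal(sel$best_auc, 1)
  # a useless first candidate is passed over for the real signal
  x2 <- cbind(F1 = rep(0, n), F2 = sig + rnorm(n, sd = 0.1), F3 = rnorm(n))
  sel2 <- forward_select(x2, y, x2, y, "lr")
  expect_true("F2" %in% sel2$selected)
  expect_false("F1" %in% sel2$selected)
  # trajectory of kept steps is strictly increasing
  expect_true(all(diff(c(0.5, sel2$trajectory)) > 0))
  expect_error(forward_select(x[, 0, drop = FALSE], y, x[, 0, drop = FALSE],
                              y, "lr"),
               class = "pathact_validation_error")
})

test_that("classification-driven marker identification bookkeeping is exact", {
  bench <- small_bench(seed = 5)
  res <- list(sets = bench$sets)
  a2 <- assessment2(bench$dataset, "combiner", res, repeats = 2,
                    n_candidates = 8, seed = 9)
  expect_identical(nrow(a2$records), 2L * 3L)
  expect_identical(sort(unique(a2$records$classifier)),
                   c("knn", "lr", "nb"))
  for (cl in names(a2$mean_accuracy)) {
    expect_equal(a2$mean_accuracy[[cl]],
                 mean(a2$records$accuracy[a2$records$classifier == cl]),
                 tolerance = 1e-12)
  }
  expect_true(a2$best_classifier %in% c("nb", "knn", "lr"))
  b2 <- assessment2(bench$dataset, "combiner", res, repeats = 2,
                    n_candidates = 8, seed = 9)
  expect_identical(a2$records, b2$records)
})

test_that("marker frequencies rank by count then mean selection rank", {
  mk <- function(sel) structure(list(selected = sel), class = "SelectionResult")
  results <- list(mk(c("P1", "P2")), mk(c("P2", "P1")), mk(c("P2", "P3")),
                  mk("P4"))
  ms <- marker_frequency(results, top_k = 3)
  expect_identical(ms$table$pathway[1], "P2")  # freq 3
  # P1 freq 2; ties: none here, P3/P4 freq 1, P3 mean rank 2, P4 rank 1
  expect_identical(ms$top, c("P2", "P1", "P4"))
  expect_true(all(ms$table$frequency <= length(results)))
  # tie broken by mean selection rank
  res2 <- list(mk(c("A", "B")), mk(c("B", "A")), mk(c("B", "A")))
  ms2 <- marker_frequency(res2, top_k = 2)
  expect_identical(ms2$top, c("B", "A"))  # B earlier on average
  expect_error(marker_frequency(list()),
               class = "pathact_validation_error")
})

test_that("query strings are deterministic template instantiations", {
  q <- build_pubmed_query("TP53", "gene", "Breast Cancer")
  expect_identical(q, 'TP53 AND prognostic AND "Breast Cancer"')
  expect_identical(build_pubmed_query("TP53", "gene", "Breast Cancer"), q)
  expect_error(build_pubmed_query("", "gene", "Breast Cancer"),
               class = "pathact_validation_error")
})

test_that("literature indexes round-trip and count informative markers", {
  idx <- literature_index(list("KEGG Apoptosis" = c(123456, 234567),
                               TP53 = 345678),
                          cancer_keyword = "Lung Cancer")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_literature_index(idx, tsv)
  back <- read_literature_index(tsv, "Lung Cancer")
  expect_identical(unclass(back)[names(idx)], unclass(idx)[names(idx)])
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list("kegg apoptosis" = c(123456L, 234567L)), js)
  expect_identical(read_literature_index(js)[["kegg apoptosis"]],
                   c(123456L, 234567L))
  # normalisation: case fold, punctuation stripped, whitespace collapsed
  cnt <- count_informative(c("KEGG_APOPTOSIS", "Unknown Pathway"),
                           list(KEGG_APOPTOSIS = c("TP53", "BAX")),
                           index = idx)
  expect_identical(cnt$n_informative_pathways, 1L)
  expect_identical(cnt$n_informative_genes, 1L)
  empty <- literature_index(stats::setNames(list(), character()))
  cnt0 <- count_informative(c("A", "B"), NULL, empty)
  expect_identical(cnt0$n_informative_pathways, 0L)
  expect_lte(cnt$n_informative_pathways, 2L)
})

test_that("synthetic literature indexes hit the requested coverage exactly", {
  bench <- small_bench(seed = 3)
  truth <- bench$truth
  n_markers <- length(truth$risk_pathways) + nrow(truth$de_genes)
  full <- generate_literature_index(truth, coverage = 1, seed = 1)
  expect_identical(length(full), n_markers)
  none <- generate_literature_index(truth, coverage = 0, seed = 1)
  expect_identical(length(none), 0L)
  # ten markers at half coverage: exactly five indexed
  t10 <- list(risk_pathways = sprintf("P%d", 1:4),
              de_genes = data.frame(gene = sprintf("G%d", 1:6)))
  half <- generate_literature_index(t10, coverage = 0.5, seed = 2)
  expect_identical(length(half), 5L)
  expect_identical(generate_literature_index(truth, 0.4, seed = 7),
                   generate_literature_index(truth, 0.4, seed = 7))
})
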