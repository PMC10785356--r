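# Assessment 2: stratified 60/20/20 splits, AUC-gated greedy forward
# selection over top-ranked pathway features with three classifiers,
# marker-frequency ranking and literature-index validation counts.

#' Stratified train / validation / test split
#'
#' @param dataset An `ExpressionDataset`.
#' @param fractions Portion fractions summing to 1 (default 60/20/20).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List with `train`, `validation`, `test` datasets and the index
#'   vectors `idx`.
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  labels <- dataset$labels
  idx <- with_seed(seed, {
    parts <- list(train = integer(), validation = integer(),
                  test = integer())
    for (lv in levels(labels)) {
      s <- sample(which(labels == lv))
      n <- length(s)
      n_tr <- round(fractions[1L] * n)
      n_va <- round(fractions[2L] * n)
      n_te <- n - n_tr - n_va
      if (min(n_tr, n_va, n_te) < 2L) {
        stop_validation("class '", lv, "' too small for a ",
                        paste(fractions, collapse = "/"), " split with >= 2",
                        " samples per portion")
      }
      parts$train <- c(parts$train, s[seq_len(n_tr)])
      parts$validation <- c(parts$validation, s[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, s[n_tr + n_va + seq_len(n_te)])
    }
    lapply(parts, sort)
  })
  list(train = subset_samples(dataset, idx$train),
       validation = subset_samples(dataset, idx$validation),
       test = subset_samples(dataset, idx$test),
       idx = idx)
}

# ---------------------------------------------------------------------------
# Classifiers: each produces a continuous case-probability score.
# ---------------------------------------------------------------------------

# Ridge-penalised logistic regression by IRLS (intercept unpenalised).
# Keeps coefficients finite on separable activity features, where plain
# maximum likelihood diverges.
ridge_logistic_fit <- function(x, y01, lambda = 1e-2, max_iter = 50L,
                               tol = 1e-8) {
  X <- cbind(1, as.matrix(x))
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zr <- eta + (y01 - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% zr)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

# Continuous case scores on test_x for one classifier tag.
classifier_scores <- function(classifier, train_x, train_y, test_x,
                              knn_k = 5L, ridge_lambda = 1e-2) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  case <- levels(train_y)[2L]
  switch(classifier,
    nb = {
      fit <- e1071::naiveBayes(x = as.data.frame(train_x), y = train_y)
      pr <- stats::predict(fit, as.data.frame(test_x), type = "raw")
      as.vector(pr[, case])
    },
    knn = {
      k <- min(knn_k, nrow(train_x))
      pred <- class::knn(train_x, test_x, train_y, k = k, prob = TRUE,
                         use.all = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == case, pw, 1 - pw)
    },
    lr = {
      beta <- ridge_logistic_fit(train_x, as.numeric(train_y == case),
                                 lambda = ridge_lambda)
      stats::plogis(as.vector(cbind(1, test_x) %*% beta))
    },
    stop_validation("unknown classifier: ", classifier))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with ties counted half; equals the all-pairs
#' concordance proportion. Returns `NA` (flagged) when the labels hold a
#' single class.
#'
#' @param scores Continuous case scores.
#' @param labels Two-level factor (second level = case).
#' @return AUC in \\[0, 1\\], or `NA`.
#' @export
auc_score <- function(scores, labels) {
  y <- labels == levels(labels)[2L]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit, score and evaluate one classifier
#'
#' Fits `classifier` on the training features, scores the evaluation
#' samples, and reports the rank-statistic AUC plus accuracy and confusion
#' counts at the 0.5 score threshold.
#'
#' @param classifier `"nb"`, `"knn"` or `"lr"`.
#' @param train_x,test_x Samples x features matrices.
#' @param train_y,test_y Two-level factors (second level = case).
#' @param ... Passed to the classifier (`knn_k`, `ridge_lambda`).
#' @return List with `auc`, `accuracy`, `confusion` (TP/FP/TN/FN) and the
#'   raw `scores`.
#' @export
evaluate_classifier <- function(classifier, train_x, train_y, test_x,
                                test_y, ...) {
  scores <- classifier_scores(classifier, train_x, train_y, test_x, ...)
  case <- levels(test_y)[2L]
  pred <- scores >= 0.5
  truth <- test_y == case
  conf <- c(TP = sum(pred & truth), FP = sum(pred & !truth),
            TN = sum(!pred & !truth), FN = sum(!pred & truth))
  list(auc = auc_score(scores, test_y),
       accuracy = (conf[["TP"]] + conf[["TN"]]) / length(test_y),
       confusion = conf, scores = scores)
}

#' AUC-gated greedy forward feature selection
#'
#' Starting from an empty set with baseline validation AUC 0.5 (chance),
#' each candidate feature is tried in the given rank order; the classifier
#' is refitted on the kept set plus the candidate and the candidate is
#' retained only if the validation AUC strictly increases. A classifier
#' failure on a step skips that candidate and records it.
#'
#' @param train_x,val_x Samples x features matrices whose columns are the
#'   candidates in rank order.
#' @param train_y,val_y Two-level factors.
#' @param classifier `"nb"`, `"knn"` or `"lr"`.
#' @param ... Passed to the classifier.
#' @return List of class `SelectionResult`: `classifier`, `selected`
#'   (feature names in selection order), `trajectory` (validation AUC after
#'   each kept step), `skipped`.
#' @export
forward_select <- function(train_x, train_y, val_x, val_y, classifier,
                           ...) {
  train_x <- as.matrix(train_x); val_x <- as.matrix(val_x)
  if (ncol(train_x) == 0L) stop_validation("no candidate features")
  kept <- integer()
  best <- 0.5
  trajectory <- numeric()
  skipped <- character()
  for (j in seq_len(ncol(train_x))) {
    feats <- c(kept, j)
    auc <- tryCatch({
      sc <- classifier_scores(classifier, train_x[, feats, drop = FALSE],
                              train_y, val_x[, feats, drop = FALSE], ...)
      auc_score(sc, val_y)
    }, error = function(e) { skipped <<- c(skipped, colnames(train_x)[j]); NA_real_ })
    if (!is.na(auc) && auc > best) {
      kept <- feats
      best <- auc
      trajectory <- c(trajectory, auc)
    }
  }
  structure(list(classifier = classifier,
                 selected = colnames(train_x)[kept],
                 trajectory = trajectory, best_auc = best,
                 skipped = skipped),
            class = "SelectionResult")
}

#' Classification-driven marker identification (Assessment 2)
#'
#' Per repeat: a fresh stratified 60/20/20 split; the activity model fitted
#' on the training portion; activities inferred for all three portions; the
#' top `n_candidates` pathways by absolute training t-score become the
#' candidate features; greedy forward selection per classifier on the
#' validation AUC; the optimised feature set evaluated on the test portion.
#' An empty selection falls back to the majority-class prediction (flagged).
#' The best classifier per method is the one with the highest mean test
#' accuracy, ties broken towards the one selecting more pathways.
#'
#' @param dataset An `ExpressionDataset`.
#' @param method Method tag (see [fit_pathway_model()]).
#' @param resources List with `sets` (and `network`, `sets2`, `network2`).
#' @param classifiers Subset of `c("nb", "knn", "lr")`.
#' @param repeats Number of re-randomised splits (full-scale setting: 10).
#' @param n_candidates Candidate pool size (full-scale setting: top 50).
#' @param seed Master seed.
#' @return List with `selections` (per classifier, a list of
#'   `SelectionResult`s), `records` (one row per repeat x classifier),
#'   `mean_accuracy`, `best_classifier`.
#' @export
assessment2 <- function(dataset, method, resources,
                        classifiers = c("nb", "knn", "lr"), repeats = 10L,
                        n_candidates = 50L, seed = 1L) {
  seeds <- child_seeds(seed, repeats)
  prepared <- prepare_resources(dataset, resources)
  selections <- stats::setNames(
    lapply(classifiers, function(cl) vector("list", repeats)), classifiers)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    sp <- split_dataset(dataset, seed = seeds[rep_i])
    fit <- fit_prepared(sp$train, method, gene_statistics(sp$train),
                        prepared,
                        params = list(p_threshold = 0.05, max_genes = 20L,
                                      restart = 0.7, tol = 1e-10,
                                      max_iter = 1e5L, tau = 1,
                                      kcdf = "ecdf", min_size = 2L))
    prof <- lapply(sp[c("train", "validation", "test")],
                   function(d) infer_activity(fit, d))
    common <- Reduce(intersect, lapply(prof, function(p) rownames(p$activity)))
    t_tr <- pathway_tscores(prof$train$activity[common, , drop = FALSE],
                            sp$train$labels)
    cand <- common[order(-abs(t_tr[common]), common)]
    cand <- cand[seq_len(min(n_candidates, length(cand)))]
    xs <- lapply(prof, function(p) t(p$activity[cand, , drop = FALSE]))
    for (cl in classifiers) {
      sel <- forward_select(xs$train, sp$train$labels, xs$validation,
                            sp$validation$labels, cl)
      if (length(sel$selected) > 0L) {
        ev <- evaluate_classifier(cl, xs$train[, sel$selected, drop = FALSE],
                                  sp$train$labels,
                                  xs$test[, sel$selected, drop = FALSE],
                                  sp$test$labels)
        acc <- ev$accuracy; auc <- ev$auc; fallback <- FALSE
      } else {
        maj <- names(which.max(table(sp$train$labels)))
        acc <- mean(sp$test$labels == maj); auc <- NA_real_; fallback <- TRUE
      }
      sel$test_accuracy <- acc
      sel$test_auc <- auc
      selections[[cl]][[rep_i]] <- sel
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_id = rep_i, classifier = cl,
                   n_selected = length(sel$selected), accuracy = acc,
                   auc = auc, fallback = fallback)
    }
  }
  records <- do.call(rbind, rows)
  mean_acc <- vapply(split(records$accuracy, records$classifier), mean, 0)
  mean_sel <- vapply(split(records$n_selected, records$classifier), mean, 0)
  ord <- order(-mean_acc[classifiers], -mean_sel[classifiers])
  list(selections = selections, records = records,
       mean_accuracy = mean_acc[classifiers],
       best_classifier = classifiers[ord[1L]], seed = seed)
}

#' Marker-frequency ranking across selection experiments
#'
#' Counts how often each pathway was selected across the experiments; ranks
#' by descending frequency, ties by mean selection rank (earlier is better)
#' then pathway id.
#'
#' @param results List of `SelectionResult`s (typically one classifier's
#'   repeats).
#' @param top_k How many top markers to report (full-scale setting: 6, the
#'   minimum predicted marker count across its methods).
#' @return List of class `MarkerSummary` with `table` (pathway, frequency,
#'   mean_rank) and `top` (character vector of `top_k` marker ids).
#' @export
marker_frequency <- function(results, top_k = 6L) {
  if (length(results) == 0L) stop_validation("no selection results")
  sel <- lapply(results, `[[`, "selected")
  all_ids <- unique(unlist(sel))
  freq <- vapply(all_ids, function(id) sum(vapply(sel, function(s) id %in% s, NA)), 0L)
  mean_rank <- vapply(all_ids, function(id) {
    mean(unlist(lapply(sel, function(s) which(s == id))))
  }, 0)
  tab <- data.frame(pathway = all_ids, frequency = freq,
                    mean_rank = mean_rank)
  tab <- tab[order(-tab$frequency, tab$mean_rank, tab$pathway), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 top = utils::head(tab$pathway, top_k),
                 n_experiments = length(results)),
            class = "MarkerSummary")
}

# ---------------------------------------------------------------------------
# Literature-index validation (offline stand-in for PubMed mining)
# ---------------------------------------------------------------------------

normalise_term <- function(term) {
  t <- tolower(term)
  t <- gsub("[[:punct:]]+", " ", t)
  gsub("[[:space:]]+", " ", trimws(t))
}

#' Construct a literature index
#'
#' Maps normalised marker terms (pathway or gene names) to PMID lists;
#' the offline substrate for informative-marker counting.
#'
#' @param terms Named list: term -> integer vector of PMIDs.
#' @param cancer_keyword The cancer-type keyword the index was built for.
#' @return Object of class `LiteratureIndex`.
#' @export
literature_index <- function(terms, cancer_keyword = "Cancer") {
  pmids <- lapply(terms, function(p) {
    p <- as.integer(p)
    if (any(p <= 0L) || anyNA(p)) stop_validation("PMIDs must be positive integers")
    unique(p)
  })
  names(pmids) <- normalise_term(names(terms))
  structure(pmids, cancer_keyword = cancer_keyword,
            class = "LiteratureIndex")
}

#' Read a literature index from TSV or JSON
#'
#' TSV: one `term<TAB>pmid` pair per line (optional `term	pmid` header);
#' JSON: an object mapping terms to PMID arrays.
#'
#' @param path File path (`.json` triggers the JSON reader).
#' @param cancer_keyword Keyword tag to attach.
#' @return A [literature_index()].
#' @export
read_literature_index <- function(path, cancer_keyword = "Cancer") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(literature_index(as.list(raw), cancer_keyword))
  }
  lines <- read_clean_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_format("literature TSV needs term<TAB>pmid per line")
  }
  terms <- vapply(fields, `[[`, "", 1L)
  pmid <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(terms[1L]), "term")) { terms <- terms[-1L]; pmid <- pmid[-1L] }
  literature_index(split(as.integer(pmid), terms)[unique(terms)],
                   cancer_keyword)
}

#' @rdname read_literature_index
#' @param index A `LiteratureIndex`.
#' @export
write_literature_index <- function(index, path) {
  lines <- unlist(lapply(names(index), function(t) paste(t, index[[t]], sep = "\t")))
  writeLines(c("term\tpmid", lines), path)
  invisible(index)
}

#' Deterministic PubMed query string for a marker
#'
#' Combines the marker term, the fixed keyword `prognostic`, and the quoted
#' cancer-type keyword, e.g.
#' `TP53 AND prognostic AND "Breast Cancer"`. Query construction only; no
#' retrieval is performed.
#'
#' @param marker Marker term (pathway or gene name).
#' @param marker_kind `"pathway"` or `"gene"` (recorded, not interpreted).
#' @param cancer_keyword Cancer-type keyword.
#' @return The query string.
#' @export
build_pubmed_query <- function(marker, marker_kind = c("pathway", "gene"),
                               cancer_keyword) {
  marker_kind <- match.arg(marker_kind)
  if (!nzchar(trimws(marker)) || !nzchar(trimws(cancer_keyword))) {
    stop_validation("marker and cancer keyword must be non-empty")
  }
  sprintf('%s AND prognostic AND "%s"', marker, cancer_keyword)
}

#' Count informative markers against a literature index
#'
#' A marker (pathway or gene) is informative iff its normalised term has at
#' least one PMID in the index.
#'
#' @param markers Character vector of pathway marker ids.
#' @param genes_per_marker Optional named list: marker -> member gene ids.
#' @param index A `LiteratureIndex`.
#' @return List with `n_informative_pathways`, `n_informative_genes`,
#'   `pathway_pmids`, `gene_pmids`.
#' @export
count_informative <- function(markers, genes_per_marker = NULL, index) {
  lookup <- function(terms) {
    hits <- index[normalise_term(terms)]
    names(hits) <- terms
    hits[!vapply(hits, is.null, NA)]
  }
  p_hits <- lookup(markers)
  genes <- unique(unlist(genes_per_marker))
  g_hits <- if (length(genes) > 0L) lookup(genes) else list()
  list(n_informative_pathways = length(p_hits),
       n_informative_genes = length(g_hits),
       pathway_pmids = p_hits, gene_pmids = g_hits)
}
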