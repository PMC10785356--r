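# Assessment 1: cross-validated reproducibility power of pathway-level
# t-statistics, and its coefficient of variation.

#' Pathway-level t-scores of an activity profile
#'
#' Pooled-variance two-sample t per pathway row (case minus control), same
#' conventions as [gene_statistics()].
#'
#' @param profile A `PathwayActivityProfile` (or bare matrix).
#' @param labels Two-level factor aligned to the profile's samples.
#' @return Named numeric vector of t-scores with a `pvalue` attribute.
#' @export
pathway_tscores <- function(profile, labels) {
  a <- if (inherits(profile, "PathwayActivityProfile")) profile$activity
       else profile
  ts <- row_tstats(a, labels)
  structure(stats::setNames(ts$tscore, rownames(a)), pvalue = ts$pvalue)
}

#' Reproducibility power of a train/test t-score pair
#'
#' Selects the `top_k` pathways by absolute training t-score (descending,
#' ties by pathway id) and averages the products of training and test
#' t-scores over the selection:
#' `Cscore(N) = (1/N) sum tscore(Pi_train) * tscore(Pi_test)`.
#'
#' @param train_t,test_t Named t-score vectors over the same pathway ids.
#' @param top_k Number of pathways to select (N).
#' @return List of class `ReproducibilityRecord` with `top_k`, `cscore` and
#'   the per-pathway `pairs` data.frame (ordered by descending |train t|).
#' @export
cscore <- function(train_t, test_t, top_k) {
  ids <- intersect(names(train_t), names(test_t))
  if (top_k > length(ids)) {
    stop_validation("top_k (", top_k, ") exceeds available pathways (",
                    length(ids), ")")
  }
  o <- ids[order(-abs(train_t[ids]), ids)][seq_len(top_k)]
  pairs <- data.frame(pathway = o, t_train = unname(train_t[o]),
                      t_test = unname(test_t[o]))
  structure(list(top_k = top_k,
                 cscore = mean(pairs$t_train * pairs$t_test),
                 pairs = pairs),
            class = "ReproducibilityRecord")
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so every fold preserves class proportions within one sample.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated reproducibility power (Assessment 1)
#'
#' Repeatedly partitions the samples into `folds` stratified subsets; each
#' fold in turn is the held-out test portion and the remainder the training
#' portion. Model parameters (gene statistics, DEG membership, walk
#' vectors, edge weights, SVD orientation) are fitted on the training
#' portion only; activities are inferred on both portions with per-portion
#' z-scoring, pathway t-scores computed per portion, and the
#' reproducibility power recorded for each `top_k`. If a fold retains fewer
#' pathways than a requested `top_k`, the selection is capped at the
#' available count and flagged (`capped`).
#'
#' @param dataset An `ExpressionDataset`.
#' @param methods Character vector of method tags (see
#'   [fit_pathway_model()]).
#' @param resources List with `sets` and, for walk-based methods, `network`
#'   (optionally `sets2`, `network2`).
#' @param folds,repeats Partition geometry; the full-scale setting is 5
#'   folds x 100 repeats = 500 experiments per method and top-k.
#' @param top_k Integer vector of selection sizes.
#' @param seed Master seed; each repeat gets a reproducible child seed.
#' @param p_threshold,max_genes,restart,tol,max_iter,tau,kcdf,min_size,entropy_bins
#'   Method parameters, see [fit_pathway_model()]. Gene statistics,
#'   z-matrices and restricted resources are shared across the methods
#'   within each fold.
#' @return List with `records` (one row per method x partition x fold x
#'   top_k), `summary` (mean Cscore per method x top_k) and the call
#'   settings.
#' @export
assessment1 <- function(dataset, methods, resources, folds = 5L,
                        repeats = 100L, top_k = c(50L, 40L, 30L, 20L, 10L),
                        seed = 1L, p_threshold = 0.05, max_genes = 20L,
                        restart = 0.7, tol = 1e-10, max_iter = 1e5L,
                        tau = 1, kcdf = "ecdf", min_size = 2L,
                        entropy_bins = NULL) {
  validate_dataset(dataset)
  tab <- table(dataset$labels)
  if (any(tab < 2L * folds)) {
    stop_validation("stratification infeasible: every fold needs >= 2 ",
                    "samples per class")
  }
  params <- list(p_threshold = p_threshold, max_genes = max_genes,
                 restart = restart, tol = tol, max_iter = max_iter,
                 tau = tau, kcdf = kcdf, min_size = min_size)
  prepared <- prepare_resources(dataset, resources, min_size = min_size)
  seeds <- child_seeds(seed, repeats)
  rows <- vector("list", repeats * folds * length(methods) * length(top_k))
  n_row <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- with_seed(seeds[rep_i],
                         stratified_folds(dataset$labels, folds))
    for (f in seq_len(folds)) {
      train <- subset_samples(dataset, fold_of != f)
      test <- subset_samples(dataset, fold_of == f)
      stats_tr <- gene_statistics(train, entropy_bins = entropy_bins)
      z_tr <- zscore_rows(train)
      z_te <- zscore_rows(test)
      for (m in methods) {
        fit <- fit_prepared(train, m, stats_tr, prepared, params, z = z_tr)
        t_tr <- pathway_tscores(infer_activity(fit, train, z = z_tr),
                                train$labels)
        t_te <- pathway_tscores(infer_activity(fit, test, z = z_te),
                                test$labels)
        avail <- length(intersect(names(t_tr), names(t_te)))
        for (k in top_k) {
          kk <- min(k, avail)
          cs <- cscore(t_tr, t_te, kk)$cscore
          n_row <- n_row + 1L
          rows[[n_row]] <- data.frame(method = m, partition = rep_i,
                                      fold = f, top_k = k,
                                      top_k_used = kk, cscore = cs,
                                      capped = kk < k)
        }
      }
    }
  }
  records <- do.call(rbind, rows[seq_len(n_row)])
  summary <- stats::aggregate(cscore ~ method + top_k, records, mean)
  summary <- summary[order(summary$method, -summary$top_k), ]
  rownames(summary) <- NULL
  list(records = records, summary = summary, folds = folds,
       repeats = repeats, top_k = top_k, seed = seed)
}

#' Coefficient of variation of reproducibility scores
#'
#' Sample standard deviation over mean, in percent. A non-positive mean
#' makes the ratio uninterpretable as a dispersion measure; it is then
#' flagged undefined (`cv = NA`).
#'
#' @param records Numeric vector of scores, or an [assessment1()] records
#'   data.frame (summarised per method).
#' @return A `data.frame` of class `CvSummary` with `mean`, `sd`, `cv`
#'   (percent) and `defined`.
#' @export
coefficient_of_variation <- function(records) {
  one <- function(x, tag) {
    if (length(x) < 2L) stop_validation("CV needs >= 2 records")
    m <- mean(x); s <- stats::sd(x)
    data.frame(method = tag, mean = m, sd = s,
               cv = if (m > 0) 100 * s / m else NA_real_,
               defined = m > 0)
  }
  out <- if (is.data.frame(records)) {
    do.call(rbind, lapply(split(records$cscore, records$method),
                          function(x) one(x, NA)))
  } else {
    one(records, "scores")
  }
  if (is.data.frame(records)) out$method <- names(split(records$cscore, records$method))
  rownames(out) <- NULL
  class(out) <- c("CvSummary", class(out))
  out
}
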