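# Unified fit / infer surface over the seven activity inference schemes.
# "Fitting" captures everything derived from phenotype labels or network
# walks on a training portion (gene statistics, DEG membership, walk
# vectors, edge re-weighting, SVD orientation); inference then scores any
# portion with per-portion z-scoring and the fitted parameters.

METHODS <- c("combiner", "pac", "plage", "gsva", "drw", "sdrw", "edrw")

#' Fit a pathway activity model on a (training) dataset
#'
#' @param dataset An `ExpressionDataset`.
#' @param method One of `"combiner"`, `"pac"`, `"plage"`, `"gsva"`,
#'   `"drw"`, `"sdrw"`, `"edrw"`.
#' @param sets A `GeneSetCollection` (first/only collection).
#' @param network A `DirectedPathwayNetwork` (walk-based methods).
#' @param sets2,network2 Optional second collection/network for the
#'   two-network entropy-walk method.
#' @param p_threshold Differential-expression p cut-off (inclusive for the
#'   signed z-score scheme, strict for the walk-based schemes).
#' @param max_genes Gene cap per pathway for the signed z-score scheme.
#' @param restart,tol,max_iter Walk parameters.
#' @param tau,kcdf Enrichment-walk parameters.
#' @param min_size Minimum gene-set size after restriction to measured genes.
#' @param entropy_bins Histogram bins for gene entropy (default Sturges).
#' @return An object of class `PathwayModel`.
#' @export
fit_pathway_model <- function(dataset, method = METHODS, sets,
                              network = NULL, sets2 = NULL, network2 = NULL,
                              p_threshold = 0.05, max_genes = 20L,
                              restart = 0.7, tol = 1e-10, max_iter = 1e5L,
                              tau = 1, kcdf = "ecdf", min_size = 2L,
                              entropy_bins = NULL) {
  method <- match.arg(method)
  prepared <- prepare_resources(dataset,
                                list(sets = sets, network = network,
                                     sets2 = sets2, network2 = network2),
                                min_size = min_size)
  stats <- gene_statistics(dataset, entropy_bins = entropy_bins)
  fit_prepared(dataset, method, stats, prepared,
               params = list(p_threshold = p_threshold,
                             max_genes = max_genes, restart = restart,
                             tol = tol, max_iter = max_iter, tau = tau,
                             kcdf = kcdf, min_size = min_size))
}

# Restrict gene sets / mark unmeasured network nodes once per gene
# namespace; shared across folds and methods in the assessments.
prepare_resources <- function(dataset, resources, min_size = 2L) {
  out <- list(sets = restrict_to_dataset(resources$sets, dataset,
                                         min_size = min_size))
  if (!is.null(resources$network)) {
    out$network <- restrict_to_dataset(resources$network, dataset)
  }
  if (!is.null(resources$network2)) {
    out$network2 <- restrict_to_dataset(resources$network2, dataset)
    out$sets2 <- restrict_to_dataset(resources$sets2 %||% resources$sets,
                                     dataset, min_size = min_size)
  }
  out
}

# Core fit given precomputed gene statistics and restricted resources.
fit_prepared <- function(dataset, method, stats, prepared, params,
                         z = NULL) {
  model <- list(method = method, stats = stats, sets = prepared$sets,
                p_threshold = params$p_threshold,
                max_genes = params$max_genes, tau = params$tau,
                kcdf = params$kcdf)
  wcfg <- walk_config(params$restart, params$tol, params$max_iter)
  if (method %in% c("drw", "sdrw", "edrw") && is.null(prepared$network)) {
    stop_validation("method '", method, "' requires a network")
  }
  if (method %in% c("drw", "sdrw")) {
    net <- prepared$network
    if (method == "sdrw") {
      net <- sdrw_reweight(net, stats::setNames(abs(stats$tscore),
                                                stats$gene))
    }
    model$network <- net
    model$walk <- random_walk_restart(net,
                                      initial_weight_vector(stats, net,
                                                            "abs_t"),
                                      wcfg)
  } else if (method == "edrw") {
    nets <- list(net1 = prepared$network)
    colls <- list(net1 = prepared$sets)
    if (!is.null(prepared$network2)) {
      nets$net2 <- prepared$network2
      colls$net2 <- prepared$sets2
    }
    model$walks <- lapply(nets, function(nt) {
      random_walk_restart(nt, initial_weight_vector(stats, nt, "entropy"),
                          wcfg)
    })
    model$sets_list <- colls
  } else if (method == "plage") {
    if (is.null(z)) z <- zscore_rows(dataset)
    fit_prof <- plage_activity(z, prepared$sets, min_size = params$min_size)
    model$plage_loadings <- lapply(fit_prof$provenance, `[[`, "loadings")
    model$fit_profile <- fit_prof
    model$fit_samples <- colnames(dataset$values)
  }
  structure(model, class = "PathwayModel")
}

#' @export
print.PathwayModel <- function(x, ...) {
  cat("PathwayModel [", x$method, "]: ", length(x$sets), " gene sets, ",
      nrow(x$stats), " genes\n", sep = "")
  invisible(x)
}

#' Infer pathway activities for a dataset with a fitted model
#'
#' Z-scoring is performed within the supplied portion; DEG membership,
#' signs, walk weights and SVD orientation come from the fitted model.
#'
#' @param model A [fit_pathway_model()] result.
#' @param dataset An `ExpressionDataset` sharing the model's gene namespace.
#' @param z Optional precomputed [zscore_rows()] matrix for `dataset`
#'   (avoids recomputation when several methods score the same portion).
#' @return A `PathwayActivityProfile`.
#' @export
infer_activity <- function(model, dataset, z = NULL) {
  if (model$method == "gsva") {
    return(gsva_activity(dataset, model$sets, tau = model$tau,
                         kcdf = model$kcdf))
  }
  if (model$method == "plage" &&
      identical(colnames(dataset$values), model$fit_samples)) {
    return(model$fit_profile)  # fitting portion: orientation already fixed
  }
  if (is.null(z)) z <- zscore_rows(dataset)
  switch(model$method,
    combiner = combiner_activity(z, model$stats, model$sets,
                                 p_threshold = model$p_threshold,
                                 max_genes = model$max_genes),
    pac = pac_activity(z, model$sets),
    plage = plage_activity(z, model$sets,
                           ref_loadings = model$plage_loadings),
    drw = drw_activity(z, model$stats, model$walk, model$sets,
                       p_threshold = model$p_threshold, method = "drw"),
    sdrw = drw_activity(z, model$stats, model$walk, model$sets,
                        p_threshold = model$p_threshold, method = "sdrw"),
    edrw = edrw_activity(z, model$stats, model$walks, model$sets_list,
                         p_threshold = model$p_threshold))
}

#' One-shot pathway activity inference
#'
#' Fits on and scores the same dataset; the usual entry point outside
#' cross-validation.
#'
#' @inheritParams fit_pathway_model
#' @param ... Passed to [fit_pathway_model()].
#' @return A `PathwayActivityProfile`.
#' @export
pathway_activity <- function(dataset, method, sets, ...) {
  infer_activity(fit_pathway_model(dataset, method, sets, ...), dataset)
}
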