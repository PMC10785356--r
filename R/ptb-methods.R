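# Random-walk-with-restart engine and the three topology-based activity
# schemes (plain, edge-reweighted, entropy-initialised).

#' Walk configuration
#'
#' @param restart Restart probability r in (0, 1]; 0.7 throughout the
#'   package's benchmarks for comparability across the walk-based methods.
#' @param tolerance L1 convergence threshold between successive iterates.
#' @param max_iter Iteration cap.
#' @param closed_form Also compute the closed-form residual
#'   `||w_inf - r (I - (1-r) M~')^-1 w0||` (dense solve; intended for small
#'   networks / verification).
#' @return A list of class `WalkConfig`.
#' @export
walk_config <- function(restart = 0.7, tolerance = 1e-10, max_iter = 1e5L,
                        closed_form = FALSE) {
  if (!(restart > 0 && restart <= 1)) stop_validation("restart must be in (0, 1]")
  if (tolerance <= 0) stop_validation("tolerance must be > 0")
  structure(list(restart = restart, tolerance = tolerance,
                 max_iter = as.integer(max_iter),
                 dangling_policy = "redistribute_to_restart",
                 closed_form = closed_form),
            class = "WalkConfig")
}

#' Initial walk probability vector
#'
#' Seeds the walk over the network's nodes: in `abs_t` mode with the
#' absolute t-score of each measured gene, in `entropy` mode with its
#' expression entropy. Unmeasured nodes get weight 0. The vector is
#' L1-normalised onto the probability simplex.
#'
#' @param stats A [gene_statistics()] frame.
#' @param network A `DirectedPathwayNetwork`.
#' @param mode `"abs_t"` or `"entropy"`.
#' @return Named probability vector over `network$nodes` (sums to 1).
#' @export
initial_weight_vector <- function(stats, network, mode = c("abs_t", "entropy")) {
  mode <- match.arg(mode)
  w <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  idx <- match(stats$gene, network$nodes)
  hit <- !is.na(idx)
  if (!any(hit)) stop_validation("network shares no genes with the dataset")
  w[idx[hit]] <- switch(mode,
                        abs_t = abs(stats$tscore[hit]),
                        entropy = stats$entropy[hit])
  s <- sum(w)
  if (s == 0) stop_validation("all-zero initial weight vector")
  w / s
}

#' Random walk with restart on a directed network
#'
#' Iterates `W_{t+1} = (1 - r) M' W_t + r W_0` (M' the transpose of the
#' row-normalised transition matrix) until the L1 difference between
#' successive iterates falls below the tolerance. Mass leaving through
#' dangling nodes (no out-edges) is redistributed to the restart vector each
#' step, which keeps the iterate on the probability simplex and guarantees a
#' unique stationary point.
#'
#' @param network A `DirectedPathwayNetwork`.
#' @param w0 Named probability vector over the network nodes (sums to 1).
#' @param config A [walk_config()].
#' @return Object of class `WalkResult`: list with `w0`, `w_inf`,
#'   `iterations`, `residual`, `mass_dev` (max deviation of the total mass
#'   from 1 over all iterations) and `closed_form_residual` (NA unless
#'   `config$closed_form`).
#' @export
random_walk_restart <- function(network, w0, config = walk_config()) {
  nodes <- network$nodes
  if (is.null(names(w0))) names(w0) <- nodes
  w0 <- w0[nodes]
  if (anyNA(w0) || any(w0 < 0)) stop_validation("w0 must be non-negative over the network nodes")
  if (abs(sum(w0) - 1) > 1e-8) stop_validation("w0 must sum to 1")
  r <- config$restart
  Mt <- Matrix::t(network$transition)
  dang <- match(network$dangling, nodes)
  w <- w0
  mass_dev <- 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dmass <- if (length(dang) > 0L) sum(w[dang]) else 0
    w_new <- as.vector((1 - r) * (Mt %*% w)) + ((1 - r) * dmass + r) * w0
    mass_dev <- max(mass_dev, abs(sum(w_new) - 1))
    res <- sum(abs(w_new - w))
    w <- w_new
    if (res < config$tolerance) break
    if (iter >= config$max_iter) {
      stop_validation("walk did not converge in ", config$max_iter,
                      " iterations (residual ", format(res), ")")
    }
  }
  names(w) <- nodes
  cf <- NA_real_
  if (isTRUE(config$closed_form)) {
    cf <- max(abs(w - closed_form_walk(network, w0, r)))
  }
  structure(list(w0 = w0, w_inf = w, iterations = iter, residual = res,
                 mass_dev = mass_dev, closed_form_residual = cf,
                 config = config),
            class = "WalkResult")
}

# Direct linear solve of the stationary equation with dangling columns
# replaced by the restart vector: w = r (I - (1-r) M~')^-1 w0.
closed_form_walk <- function(network, w0, r) {
  nodes <- network$nodes
  n <- length(nodes)
  Mt <- as.matrix(Matrix::t(network$transition))
  dang <- match(network$dangling, nodes)
  if (length(dang) > 0L) Mt[, dang] <- w0
  stats::setNames(as.vector(solve(diag(n) - (1 - r) * Mt, r * w0)), nodes)
}

#' Node-weight-averaged edge re-weighting (sDRW scheme)
#'
#' Replaces every edge weight by the mean of its endpoint node weights,
#' `(N1 + N2) / 2`, then re-row-normalises. Nodes whose out-edges all end up
#' with zero weight become dangling. The subsequent walk uses the ordinary
#' restart iteration on the re-weighted transition matrix.
#'
#' @param network A `DirectedPathwayNetwork`.
#' @param node_weight Named non-negative vector (e.g. raw absolute t-scores);
#'   nodes absent from it get weight 0.
#' @return The re-weighted, re-normalised network.
#' @export
sdrw_reweight <- function(network, node_weight) {
  if (any(node_weight < 0)) stop_validation("node weights must be non-negative")
  nw <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  nw[intersect(names(node_weight), network$nodes)] <-
    node_weight[intersect(names(node_weight), network$nodes)]
  network$edges$weight <- (nw[network$edges$source] +
                             nw[network$edges$target]) / 2
  row_normalize(network)
}

#' Walk-weighted pathway activity (DRW scheme)
#'
#' Per pathway, member genes that are differentially expressed
#' (p < `p_threshold`) and present in the walked network contribute
#' `W_inf(gi) * sign(t(gi)) * z(gi)`; the sum is scaled by
#' `sqrt(sum W_inf(gi)^2)`. Pathways with no qualifying gene or a zero
#' denominator are dropped and reported.
#'
#' @param z A [zscore_rows()] matrix.
#' @param stats A [gene_statistics()] frame.
#' @param walk A [random_walk_restart()] result.
#' @param sets A `GeneSetCollection`.
#' @param p_threshold Strict differential-expression cut-off (exclusive).
#' @param method Tag recorded in the profile (`"drw"` or `"sdrw"`).
#' @return A `PathwayActivityProfile`.
#' @export
drw_activity <- function(z, stats, walk, sets, p_threshold = 0.05,
                         method = "drw") {
  deg <- stats$gene[stats$pvalue < p_threshold]
  winf <- walk$w_inf
  picks <- list(); coefs <- list()
  for (pid in names(sets)) {
    g <- intersect(intersect(sets[[pid]], deg), names(winf))
    if (length(g) == 0L) next
    wgt <- winf[g]
    den <- sqrt(sum(wgt^2))
    if (den == 0) next
    picks[[pid]] <- g
    coefs[[pid]] <- wgt * stats[g, "sign"] / den
  }
  weighted_sum_profile(z, picks, coefs, method, names(sets))
}

#' Entropy weights of a pathway's member genes
#'
#' The normalised complement of the converged entropy-walk probabilities:
#' `(1 - H_inf(gi)) / sum_members (1 - H_inf(gj))`.
#'
#' @param h_inf Named converged walk vector.
#' @param genes Member gene ids (must be present in `h_inf`).
#' @return Named weight vector (sums to 1 when all complements are
#'   non-negative).
#' @export
edrw_entropy_weights <- function(h_inf, genes) {
  h <- h_inf[genes]
  comp <- 1 - h
  s <- sum(comp)
  if (s == 0) return(stats::setNames(rep(0, length(genes)), genes))
  stats::setNames(comp / s, genes)
}

#' Entropy-walk pathway activity (e-DRW scheme)
#'
#' Per pathway, qualifying member genes (differentially expressed with
#' p < `p_threshold` and present in the pathway's source network) contribute
#' `H_inf(gi) * PCT(gi) * z(gi)` where `PCT = pbc + t`; the sum is scaled
#' by `sqrt(sum entropy_weight(gi)^2)` with entropy weights per
#' [edrw_entropy_weights()]. Profiles from multiple source networks are
#' concatenated; duplicated pathway ids get a source suffix.
#'
#' @param z A [zscore_rows()] matrix.
#' @param stats A [gene_statistics()] frame.
#' @param walks Named list of [random_walk_restart()] results (one per
#'   source network); a bare `WalkResult` is accepted.
#' @param sets Named list of `GeneSetCollection`s parallel to `walks`, or a
#'   single collection when one walk is supplied.
#' @param p_threshold Strict differential-expression cut-off (exclusive).
#' @return A `PathwayActivityProfile`.
#' @export
edrw_activity <- function(z, stats, walks, sets, p_threshold = 0.05) {
  if (inherits(walks, "WalkResult")) walks <- list(net1 = walks)
  if (inherits(sets, "GeneSetCollection")) {
    sets <- stats::setNames(list(sets), names(walks)[1L])
  }
  stopifnot(length(walks) == length(sets))
  deg <- stats$gene[stats$pvalue < p_threshold]
  parts <- vector("list", length(walks))
  for (k in seq_along(walks)) {
    hinf <- walks[[k]]$w_inf
    coll <- sets[[k]]
    picks <- list(); coefs <- list()
    for (pid in names(coll)) {
      g <- intersect(intersect(coll[[pid]], deg), names(hinf))
      if (length(g) == 0L) next
      ew <- edrw_entropy_weights(hinf, g)
      den <- sqrt(sum(ew^2))
      if (den == 0) next
      picks[[pid]] <- g
      coefs[[pid]] <- hinf[g] * stats[g, "pct"] / den
    }
    parts[[k]] <- weighted_sum_profile(z, picks, coefs, "edrw", names(coll))
  }
  if (length(parts) == 1L) return(parts[[1L]])
  all_ids <- unlist(lapply(parts, function(p) rownames(p$activity)))
  dup <- unique(all_ids[duplicated(all_ids)])
  for (k in seq_along(parts)) {
    ids <- rownames(parts[[k]]$activity)
    ids[ids %in% dup] <- paste0(ids[ids %in% dup], ".", names(walks)[k])
    rownames(parts[[k]]$activity) <- ids
    names(parts[[k]]$provenance) <- ids
  }
  pathway_activity_profile(
    do.call(rbind, lapply(parts, function(p) p$activity)),
    do.call(c, lapply(parts, function(p) p$provenance)),
    "edrw",
    dropped = unlist(lapply(parts, function(p) p$dropped)))
}
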