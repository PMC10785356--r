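# The four gene-set (non-topology) pathway activity inference schemes.

#' COMBINER-style signed z-score pathway activity
#'
#' Per pathway, the member genes that are differentially expressed
#' (p <= `p_threshold`) are ranked by descending absolute t-score (ties by
#' gene id) and at most `max_genes` are kept. The activity of a sample is
#' `sum z(gi) * sign(t(gi)) / sqrt(j)` over those j genes. Pathways with no
#' qualifying gene are dropped and reported.
#'
#' @param z A [zscore_rows()] matrix.
#' @param stats A [gene_statistics()] frame computed on the same genes.
#' @param sets A `GeneSetCollection` (restricted to measured genes).
#' @param p_threshold Differential-expression p-value cut-off (inclusive).
#' @param max_genes Cap on genes used per pathway.
#' @return A `PathwayActivityProfile`.
#' @export
combiner_activity <- function(z, stats, sets, p_threshold = 0.05,
                              max_genes = 20L) {
  deg <- stats$gene[stats$pvalue <= p_threshold]
  picks <- lapply(sets, function(genes) {
    g <- intersect(genes, deg)
    if (length(g) == 0L) return(NULL)
    o <- order(-abs(stats[g, "tscore"]), g)
    g[o][seq_len(min(max_genes, length(g)))]
  })
  picks <- Filter(Negate(is.null), picks)
  coefs <- lapply(picks, function(g) stats[g, "sign"] / sqrt(length(g)))
  weighted_sum_profile(z, picks, coefs, "combiner", names(sets))
}

#' All-member z-score pathway activity (PAC scheme)
#'
#' Aggregates the z-scores of all k member genes of a pathway:
#' `sum z(gij) / sqrt(k)`; the sqrt(k) denominator stabilises the variance
#' of the mean, so independent standard-normal member rows yield unit
#' variance activity.
#'
#' @inheritParams combiner_activity
#' @return A `PathwayActivityProfile`.
#' @export
pac_activity <- function(z, sets) {
  members <- lapply(sets, intersect, y = rownames(z))
  members <- members[lengths(members) > 0L]
  coefs <- lapply(members, function(g) rep(1 / sqrt(length(g)), length(g)))
  weighted_sum_profile(z, members, coefs, "pac", names(sets))
}

#' Singular-value-decomposition factors of a gene-set z sub-matrix
#'
#' @param zsub Numeric matrix (member genes x samples) of z-scores.
#' @return List with `u` (left singular vectors), `d` (singular values,
#'   non-increasing), `v` (right singular vectors, unit L2 columns).
#' @export
plage_factors <- function(zsub) {
  s <- svd(zsub)
  list(u = s$u, d = s$d, v = s$v)
}

#' SVD (PLAGE-style) pathway activity
#'
#' Per pathway, the z-scores of the member genes are decomposed by SVD and
#' the first right singular vector is taken as the per-sample activity
#' (unit L2 norm). Since a singular vector's sign is arbitrary, it is fixed
#' so that the activity correlates non-negatively with the pathway's mean
#' member z profile, or — when `ref_loadings` supplies gene loadings fitted
#' on a training portion — so the gene loadings align with the reference.
#'
#' @inheritParams combiner_activity
#' @param min_size Minimum member count (smaller sets are dropped).
#' @param ref_loadings Optional named list pathway -> named numeric vector of
#'   reference first-left-singular-vector gene loadings.
#' @return A `PathwayActivityProfile`; per-pathway `loadings` (oriented first
#'   left singular vector) are stored in the provenance.
#' @export
plage_activity <- function(z, sets, min_size = 2L, ref_loadings = NULL) {
  members <- lapply(sets, intersect, y = rownames(z))
  keep <- lengths(members) >= min_size
  act <- list(); prov <- list(); dropped <- names(sets)[!keep]
  for (pid in names(sets)[keep]) {
    g <- members[[pid]]
    zsub <- z[g, , drop = FALSE]
    if (all(zsub == 0)) {
      warning("pathway ", pid, " has an all-zero z sub-matrix; dropped")
      dropped <- c(dropped, pid)
      next
    }
    f <- plage_factors(zsub)
    v1 <- f$v[, 1L]
    u1 <- stats::setNames(f$u[, 1L], g)
    s <- if (!is.null(ref_loadings) && !is.null(ref_loadings[[pid]])) {
      ref <- ref_loadings[[pid]]
      common <- intersect(names(ref), g)
      sign(sum(u1[common] * ref[common]))
    } else {
      sign(sum(v1 * colMeans(zsub)))
    }
    if (is.na(s) || s == 0) s <- 1
    act[[pid]] <- s * v1
    prov[[pid]] <- list(genes = g, degs_used = length(g), method = "plage",
                        loadings = s * u1)
  }
  a <- if (length(act) > 0L) do.call(rbind, act)
       else matrix(0, 0, ncol(z))
  dimnames(a) <- list(names(act), colnames(z))
  pathway_activity_profile(a, prov, "plage", dropped = dropped)
}

#' KS-like enrichment-walk pathway activity (GSVA scheme)
#'
#' Label-free single-sample enrichment. Per gene and sample a cumulative
#' density score is computed across samples (empirical CDF, or a
#' Gaussian-kernel CDF with bandwidth sd/4). Per sample the scores are
#' converted to the symmetric rank statistic `|p/2 - rank|`; genes are then
#' walked in decreasing statistic order (ties by gene id), accumulating the
#' difference between the tau-weighted in-set fraction and the out-of-set
#' fraction. The activity is `ESdiff = |ES+| - |ES-|`, the magnitude
#' difference of the largest positive and negative walk deviations from
#' zero.
#'
#' @param dataset An `ExpressionDataset` (>= 2 genes, >= 2 samples).
#' @param sets A `GeneSetCollection`; no set may equal the whole measured
#'   gene universe (the walk needs a non-empty complement).
#' @param tau Rank-weight exponent (default 1).
#' @param kcdf `"ecdf"` or `"gaussian"`.
#' @param keep_walk Record the full deviation sequence v(l) per (set,
#'   sample); intended for small inputs.
#' @return A `PathwayActivityProfile` with an extra `scores` element
#'   (`es_pos`, `es_neg`, `tau`, and `walks` when requested).
#' @export
gsva_activity <- function(dataset, sets, tau = 1, kcdf = c("ecdf", "gaussian"),
                          keep_walk = FALSE) {
  kcdf <- match.arg(kcdf)
  v <- if (inherits(dataset, "ExpressionDataset")) dataset$values else dataset
  p <- nrow(v); ns <- ncol(v)
  if (p < 2L || ns < 2L) stop_validation("need >= 2 genes and >= 2 samples")
  members <- lapply(sets, intersect, y = rownames(v))
  members <- members[lengths(members) > 0L]
  if (any(lengths(members) == p)) {
    stop_validation("a gene set equals the whole gene universe; ",
                    "the enrichment walk needs a non-empty complement")
  }
  score <- kcdf_scores(v, kcdf)
  ids <- rownames(v)
  id_rank <- integer(p)
  id_rank[order(ids)] <- seq_len(p)  # integer tie-break key (lexicographic)
  stat <- matrix(0, p, ns)
  walk_pos <- matrix(0L, p, ns, dimnames = list(ids, colnames(v)))
  for (j in seq_len(ns)) {
    rk <- integer(p)
    rk[order(-score[, j], id_rank, method = "radix")] <- seq_len(p)
    stat[, j] <- abs(p / 2 - rk)
    walk_pos[order(-stat[, j], id_rank, method = "radix"), j] <- seq_len(p)
  }
  w <- if (tau == 1) stat else stat^tau
  es <- lapply(members, function(g) {
    set_walk_extrema(match(g, ids), walk_pos, w, p)
  })
  es_pos <- do.call(rbind, lapply(es, `[[`, "pos"))
  es_neg <- do.call(rbind, lapply(es, `[[`, "neg"))
  act <- abs(es_pos) - abs(es_neg)
  dimnames(act) <- list(names(members), colnames(v))
  dimnames(es_pos) <- dimnames(es_neg) <- dimnames(act)
  prov <- stats::setNames(lapply(members, function(g) {
    list(genes = g, degs_used = length(g), method = "gsva")
  }), names(members))
  out <- pathway_activity_profile(act, prov, "gsva",
                                  dropped = setdiff(names(sets),
                                                    names(members)))
  out$scores <- list(es_pos = es_pos, es_neg = es_neg, tau = tau, kcdf = kcdf)
  if (keep_walk) {
    out$scores$walks <- lapply(members, function(g) {
      full_walks(match(g, ids), walk_pos, w, p)
    })
  }
  out
}

kcdf_scores <- function(v, kcdf) {
  if (kcdf == "ecdf") {
    row_ranks_average(v) / ncol(v)
  } else {
    t(apply(v, 1L, function(x) {
      h <- stats::sd(x) / 4
      if (h == 0) return(rep(0.5, length(x)))
      colMeans(stats::pnorm(outer(x, x, "-") / h))
    }))
  }
}

# Row-wise mid-ranks via one radix sort; falls back to rank() per row when
# within-row ties are present (ties need averaged ranks).
row_ranks_average <- function(v) {
  ng <- nrow(v); n <- ncol(v)
  rid <- rep(seq_len(ng), n)  # column-major row ids
  o <- order(rid, as.vector(v), method = "radix")
  sorted <- as.vector(v)[o]
  same_row <- rid[o][-1L] == rid[o][-length(o)]
  if (any(same_row & sorted[-1L] == sorted[-length(sorted)])) {
    return(t(apply(v, 1L, rank, ties.method = "average")))
  }
  rk <- integer(ng * n)
  rk[o] <- rep(seq_len(n), ng)
  matrix(rk, ng, n, dimnames = dimnames(v))
}

# Extrema of the enrichment walk for one set, vectorised over samples.
# The walk rises only at in-set positions, so its maximum is attained right
# after an in-set gene and its minimum just before one (or at l = p, where
# v = 0 by construction).
set_walk_extrema <- function(mi, walk_pos, w, p) {
  m <- length(mi); ns <- ncol(walk_pos)
  P <- walk_pos[mi, , drop = FALSE]
  W <- w[mi, , drop = FALSE]
  o <- order(rep(seq_len(ns), each = m), as.vector(P))
  Ps <- matrix(as.vector(P)[o], m, ns)
  Ws <- matrix(as.vector(W)[o], m, ns)
  tot <- colSums(Ws)
  cs <- matrix(cumsum(as.vector(Ws)), m, ns)
  cs <- cs - rep(c(0, cumsum(tot)[-ns]), each = m)
  S <- ifelse(tot == 0, 1, tot)
  frac_in <- cs / rep(S, each = m)
  out_at <- (Ps - seq_len(m)) / (p - m)
  v_at <- frac_in - out_at
  v_before <- v_at - Ws / rep(S, each = m)
  list(pos = pmax(0, col_max_rows(v_at)),
       neg = pmin(0, col_min_rows(v_before)))
}

col_max_rows <- function(M) {
  r <- M[1L, ]
  for (i in seq_len(nrow(M))[-1L]) r <- pmax(r, M[i, ])
  r
}

col_min_rows <- function(M) {
  r <- M[1L, ]
  for (i in seq_len(nrow(M))[-1L]) r <- pmin(r, M[i, ])
  r
}

# Full deviation sequences (one ns x p matrix is transposed to p x ns) for
# small fixtures and oracle tests.
full_walks <- function(mi, walk_pos, w, p) {
  ns <- ncol(walk_pos)
  out <- matrix(0, p, ns)
  inset <- rep(FALSE, p)
  inset[mi] <- TRUE
  for (j in seq_len(ns)) {
    ord_genes <- integer(p)
    ord_genes[walk_pos[, j]] <- seq_len(p)  # walk position -> gene index
    wj <- w[ord_genes, j]
    inj <- inset[ord_genes]
    S <- sum(wj[inj]); if (S == 0) S <- 1
    out[, j] <- cumsum(ifelse(inj, wj, 0)) / S -
      cumsum(!inj) / (p - length(mi))
  }
  out
}
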