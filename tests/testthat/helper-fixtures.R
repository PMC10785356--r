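# Shared fixtures, built in code at test time.

# 3 genes x 4 samples, two per class; values chosen so GENE1 is flat,
# GENE2 rises in tumour, GENE3 falls.
tiny_dataset <- function() {
  v <- rbind(GENE1 = c(5, 5, 5, 5),
             GENE2 = c(1, 2, 6, 7),
             GENE3 = c(8, 7, 2, 1))
  colnames(v) <- paste0("S", 1:4)
  expression_dataset(v, c("0", "0", "1", "1"))
}

# Hand-crafted gene statistics frame (only the columns the activity
# formulas read).
make_stats <- function(genes, tscore, pvalue, pbc = rep(0, length(genes)),
                       entropy = rep(1, length(genes))) {
  data.frame(gene = genes, tscore = tscore, pvalue = pvalue,
             sign = ifelse(tscore < 0, -1, 1), pbc = pbc,
             pct = pbc + tscore, entropy = entropy,
             flagged = FALSE, row.names = genes)
}

# Small synthetic benchmark for pipeline smoke tests.
small_bench <- function(seed = 7, ...) {
  generate_dataset(synthetic_design(n_genes = 300, n_samples = c(15, 15),
                                    n_pathways = 15, size_range = c(6, 12),
                                    n_risk = 3, seed = seed, ...))
}

# Random two-class dataset with no planted signal.
random_dataset <- function(n_genes, n_per_class, seed) {
  pathact:::with_seed(seed, {
    v <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%03d", seq_len(2 * n_per_class))))
    expression_dataset(v, rep(c("0", "1"), each = n_per_class))
  })
}

# Independent dense solve of the restarted-walk stationary equation, with
# dangling columns replaced by the restart vector (test-side oracle).
oracle_walk <- function(network, w0, r) {
  nodes <- network$nodes
  Mt <- t(as.matrix(network$transition))
  dang <- match(network$dangling, nodes)
  if (length(dang) > 0L) Mt[, dang] <- w0[nodes]
  drop(solve(diag(length(nodes)) - (1 - r) * Mt, r * w0[nodes]))
}

# Independent brute-force enrichment walk straight from the definitions
# (test-side oracle for the optimised extrema computation).
oracle_gsva <- function(v, sets, tau = 1) {
  p <- nrow(v); ns <- ncol(v); ids <- rownames(v)
  sc <- t(apply(v, 1, rank, ties.method = "average")) / ns
  out <- matrix(0, length(sets), ns,
                dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ns)) {
    rk <- integer(p)
    rk[order(-sc[, j], ids)] <- seq_len(p)
    st <- abs(p / 2 - rk)
    ord <- order(-st, ids)
    w <- st[ord]^tau
    for (si in seq_along(sets)) {
      inset <- ids[ord] %in% sets[[si]]
      S <- sum(w[inset]); if (S == 0) S <- 1
      vwalk <- cumsum(ifelse(inset, w, 0)) / S -
        cumsum(!inset) / (p - sum(inset))
      out[si, j] <- max(0, max(vwalk)) + min(0, min(vwalk))
    }
  }
  out
}

# All-pairs concordance count (test-side AUC oracle).
oracle_auc <- function(scores, labels) {
  case <- labels == levels(labels)[2L]
  pos <- scores[case]; neg <- scores[!case]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
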