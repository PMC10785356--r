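# Synthetic two-class expression benchmark with planted risk pathways, a
# matching gene-set collection and directed network, plus literature-index
# fixtures, so both assessments run fully offline.

#' Design of a synthetic benchmark dataset
#'
#' The defaults define the package's standard benchmark conditions: 2000
#' genes, 50 + 50 samples, 100 overlapping pathways of 10-40 genes, 10 risk
#' pathways in which 60% of member genes receive a +/-1.5 sd mean shift in
#' the tumour class (random sign per gene), plus 2% background
#' differentially expressed genes at half that effect, unit noise, and a
#' directed network with on average 4 edges per gene in which the planted
#' genes are preferential hubs.
#'
#' @param n_genes Number of genes.
#' @param n_samples Length-2 vector: samples per class (normal, tumour).
#' @param n_pathways Number of gene sets.
#' @param size_range Min/max pathway size.
#' @param n_risk Number of risk (signal-carrying) pathways.
#' @param effect Mean shift of planted genes, in noise-sd units.
#' @param de_fraction Fraction of a risk pathway's members that are planted.
#' @param background_de_fraction Fraction of genes outside risk pathways
#'   planted at half effect.
#' @param noise_sd Baseline expression standard deviation.
#' @param network_density Average out-edges per node.
#' @param seed Master seed for the whole benchmark.
#' @return A list of class `SyntheticDesign`.
#' @export
synthetic_design <- function(n_genes = 2000L, n_samples = c(50L, 50L),
                             n_pathways = 100L, size_range = c(10L, 40L),
                             n_risk = 10L, effect = 1.5, de_fraction = 0.6,
                             background_de_fraction = 0.02, noise_sd = 1,
                             network_density = 4, seed = 1L) {
  d <- list(n_genes = as.integer(n_genes),
            n_samples = as.integer(n_samples),
            n_pathways = as.integer(n_pathways),
            size_range = as.integer(size_range),
            n_risk = as.integer(n_risk), effect = effect,
            de_fraction = de_fraction,
            background_de_fraction = background_de_fraction,
            noise_sd = noise_sd, network_density = network_density,
            seed = as.integer(seed))
  if (any(c(d$n_genes, d$n_samples, d$n_pathways, d$size_range) <= 0L)) {
    stop_validation("all design counts must be positive")
  }
  if (d$n_risk > d$n_pathways) stop_validation("n_risk exceeds n_pathways")
  if (!(d$de_fraction > 0 && d$de_fraction <= 1)) {
    stop_validation("de_fraction must be in (0, 1]")
  }
  if (max(d$size_range) > d$n_genes) {
    stop_validation("pathway sizes exceed the gene count")
  }
  structure(d, class = "SyntheticDesign")
}

#' Generate a synthetic benchmark
#'
#' Expression values are Gaussian in z-space (mean 0, sd `noise_sd`); the
#' tumour class mean of each planted gene is shifted by its recorded signed
#' effect. Gene sets are laid out as overlapping windows over a circular
#' gene order (roughly 10% Jaccard overlap between neighbours, so
#' pathway-level statistics are correlated as in real collections). The
#' directed network comes from [generate_synthetic_network()] with planted
#' genes preferentially hubbed. Deterministic per `design$seed`.
#'
#' @param design A [synthetic_design()].
#' @return List with `dataset` (`ExpressionDataset`), `sets`
#'   (`GeneSetCollection`), `network` (`DirectedPathwayNetwork`) and `truth`
#'   (`SyntheticTruth`: risk pathway ids, planted genes with directions and
#'   effects, design echo).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  d <- design
  seeds <- child_seeds(d$seed, 3L)
  genes <- sprintf("G%05d", seq_len(d$n_genes))
  with_seed(seeds[1L], {
    sizes <- sample(seq(d$size_range[1L], d$size_range[2L]), d$n_pathways,
                    replace = TRUE)
    starts <- integer(d$n_pathways)
    pos <- 1L
    for (p in seq_len(d$n_pathways)) {
      starts[p] <- pos
      pos <- pos + max(1L, round(0.82 * sizes[p]))
      # wrap around the circular gene order
      pos <- ((pos - 1L) %% d$n_genes) + 1L
    }
    sets <- lapply(seq_len(d$n_pathways), function(p) {
      idx <- ((starts[p] + seq_len(sizes[p]) - 2L) %% d$n_genes) + 1L
      genes[idx]
    })
    names(sets) <- sprintf("PWY%03d", seq_len(d$n_pathways))
    sets <- gene_set_collection(sets, source = "synthetic")
    risk <- sort(sample(names(sets), d$n_risk))
    de_risk <- unique(unlist(lapply(sets[risk], function(g) {
      sample(g, max(1L, round(d$de_fraction * length(g))))
    })))
    pool <- setdiff(genes, unlist(sets[risk]))
    n_bg <- round(d$background_de_fraction * length(pool))
    de_bg <- if (n_bg > 0L) sort(sample(pool, n_bg)) else character()
    de <- c(de_risk, de_bg)
    dir <- sample(c(-1, 1), length(de), replace = TRUE)
    eff <- d$effect * d$noise_sd *
      c(rep(1, length(de_risk)), rep(0.5, length(de_bg)))
    truth <- structure(list(risk_pathways = risk,
                            de_genes = data.frame(gene = de,
                                                  direction = dir,
                                                  effect = dir * eff,
                                                  background = c(rep(FALSE, length(de_risk)),
                                                                 rep(TRUE, length(de_bg)))),
                            design = unclass(d)),
                       class = "SyntheticTruth")
  })
  n <- sum(d$n_samples)
  labels <- factor(rep(c("normal", "tumour"), d$n_samples),
                   levels = c("normal", "tumour"))
  values <- with_seed(seeds[2L], {
    m <- matrix(stats::rnorm(d$n_genes * n, 0, d$noise_sd), d$n_genes, n,
                dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    ridx <- match(truth$de_genes$gene, genes)
    m[ridx, labels == "tumour"] <- m[ridx, labels == "tumour"] +
      truth$de_genes$effect
    m
  })
  hub <- 1 + 4 * (genes %in% truth$de_genes$gene)
  network <- generate_synthetic_network(
    d$n_genes, round(d$network_density * d$n_genes), seed = seeds[3L],
    node_ids = genes, hub_weight = hub)
  list(dataset = expression_dataset(values, labels), sets = sets,
       network = network, truth = truth)
}

#' Write / read a synthetic truth record (JSON)
#'
#' @param truth A `SyntheticTruth`.
#' @param path JSON file path.
#' @return The truth object (invisibly for the writer).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$de_genes <- as.data.frame(raw$de_genes)
  structure(raw, class = "SyntheticTruth")
}

#' Generate a synthetic literature index over planted markers
#'
#' Assigns synthetic PMIDs to a deterministic fraction of the truth's risk
#' pathways and planted genes (`floor(coverage * n + 0.5)` terms, sampled
#' per seed).
#'
#' @param truth A `SyntheticTruth`.
#' @param coverage Fraction of truth markers to index, in \\[0, 1\\].
#' @param seed Integer seed.
#' @return A [literature_index()].
#' @export
generate_literature_index <- function(truth, coverage, seed = 1L) {
  if (coverage < 0 || coverage > 1) stop_validation("coverage must be in [0, 1]")
  markers <- c(truth$risk_pathways, truth$de_genes$gene)
  n_index <- floor(coverage * length(markers) + 0.5)
  if (n_index == 0L) {
    return(literature_index(stats::setNames(list(), character()),
                            "Synthetic Cancer"))
  }
  with_seed(seed, {
    chosen <- sample(markers, n_index)
    pmids <- lapply(chosen, function(m) {
      sample(10000000:39999999, sample(1:3, 1))
    })
    names(pmids) <- chosen
    literature_index(pmids, "Synthetic Cancer")
  })
}
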