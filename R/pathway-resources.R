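#' Construct a gene-set collection
#'
#' @param sets Named list mapping pathway id to a character vector of member
#'   gene ids. Duplicate members are removed preserving first occurrence;
#'   gene ids are upper-cased.
#' @param source Free-text provenance tag.
#' @return An object of class `GeneSetCollection` (named list).
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_validation("pathway ids must be unique and named")
  }
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0L)) {
    empty <- names(sets)[lengths(sets) == 0L]
    warning("dropping empty gene sets: ", paste(empty, collapse = ", "))
    sets <- sets[lengths(sets) > 0L]
  }
  structure(sets, source = source, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets, sizes",
      paste(range(lengths(x)), collapse = "-"),
      "(source:", attr(x, "source"), ")\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT dialect: one tab-separated line per set — set name, description, then
#' member gene ids. Duplicates within a set are removed; empty sets dropped
#' with a warning; a line with fewer than 3 fields is a format error naming
#' the line number.
#'
#' @param path File path.
#' @return [gene_set_collection()] for `parse_gmt`; the collection invisibly
#'   for `write_gmt`.
#' @export
parse_gmt <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop_format("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_format("GMT line ", short[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- ids
  gene_set_collection(sets, source = basename(path))
}

#' @rdname parse_gmt
#' @param collection A `GeneSetCollection`.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(collection))
  writeLines(paste(names(collection), desc,
                   vapply(collection, paste, "", collapse = "\t"),
                   sep = "\t"),
             path)
  invisible(collection)
}

# ---------------------------------------------------------------------------
# Directed pathway networks
# ---------------------------------------------------------------------------

#' Construct a directed pathway network
#'
#' Nodes are genes; directed edges carry an interaction-type string (kept but
#' not interpreted) and a non-negative weight (1 for unweighted input).
#' Parallel duplicate edges are collapsed to the first occurrence; self-loops
#' are retained. The row-normalised transition matrix is built eagerly; rows
#' of nodes without out-edges (dangling) are all zero and listed.
#'
#' @param edges data.frame with columns `source`, `target`, and optionally
#'   `type`, `weight`.
#' @param nodes Optional character vector of node ids (isolated nodes may be
#'   declared here); the node set is its union with all edge endpoints.
#' @return An object of class `DirectedPathwayNetwork`: list with `nodes`,
#'   `edges`, `transition` (sparse), `dangling`, `unmeasured`.
#' @export
directed_pathway_network <- function(edges, nodes = NULL) {
  edges$source <- toupper(as.character(edges$source))
  edges$target <- toupper(as.character(edges$target))
  if (is.null(edges$type)) edges$type <- "interacts"
  if (is.null(edges$weight)) edges$weight <- 1
  key <- paste(edges$source, edges$target, sep = "\r")
  edges <- edges[!duplicated(key), c("source", "target", "type", "weight")]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(toupper(nodes), edges$source, edges$target)))
  net <- structure(list(nodes = nodes, edges = edges,
                        transition = NULL, dangling = character(),
                        unmeasured = character()),
                   class = "DirectedPathwayNetwork")
  row_normalize(net)
}

#' @export
print.DirectedPathwayNetwork <- function(x, ...) {
  cat("DirectedPathwayNetwork:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$dangling), "dangling\n")
  invisible(x)
}

#' Row-normalise a network's transition matrix
#'
#' Rebuilds `transition[u, v] = weight(u -> v) / sum of u's out-weights` from
#' the current edge weights. Rows of nodes with no (or zero-weight) out-edges
#' sum to 0 and the nodes are recorded in `dangling`. Idempotent.
#'
#' @param network A `DirectedPathwayNetwork`.
#' @return The network with fresh `transition` and `dangling` fields.
#' @export
row_normalize <- function(network) {
  e <- network$edges
  if (any(e$weight < 0)) stop_validation("negative edge weight")
  n <- length(network$nodes)
  i <- match(e$source, network$nodes)
  j <- match(e$target, network$nodes)
  A <- Matrix::sparseMatrix(i = i, j = j, x = e$weight, dims = c(n, n),
                            dimnames = list(network$nodes, network$nodes))
  rs <- Matrix::rowSums(A)
  dangling <- rs == 0
  scale <- ifelse(dangling, 0, 1 / pmax(rs, .Machine$double.xmin))
  network$transition <- Matrix::Diagonal(x = scale) %*% A
  dimnames(network$transition) <- list(network$nodes, network$nodes)
  network$dangling <- network$nodes[dangling]
  network
}

#' Read a directed network from SIF or edge-list TSV
#'
#' SIF lines are `source<WS>interaction<WS>target`; an edge TSV has a header
#' `source<TAB>target<TAB>type`. Single-token lines declare isolated nodes.
#' Duplicate parallel edges collapse to one; self-loops are kept.
#'
#' @param path File path.
#' @return A [directed_pathway_network()].
#' @export
parse_network <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop_validation("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  is_tsv <- identical(tolower(toks[[1L]][1:2]), c("source", "target"))
  if (is_tsv) toks <- toks[-1L]
  iso <- vapply(toks, length, 0L) == 1L
  singles <- unlist(toks[iso])
  toks <- toks[!iso]
  bad <- which(vapply(toks, length, 0L) < 3L)
  if (length(bad) > 0L) {
    stop_format("network line with fewer than 3 fields (entry ", bad[1L], ")")
  }
  if (length(toks) == 0L && length(singles) == 0L) {
    stop_validation("network file declares no nodes or edges: ", path)
  }
  if (is_tsv) {
    edges <- data.frame(source = vapply(toks, `[[`, "", 1L),
                        target = vapply(toks, `[[`, "", 2L),
                        type = vapply(toks, `[[`, "", 3L))
  } else {
    edges <- data.frame(source = vapply(toks, `[[`, "", 1L),
                        target = vapply(toks, `[[`, "", 3L),
                        type = vapply(toks, `[[`, "", 2L))
  }
  directed_pathway_network(edges, nodes = singles)
}

#' @rdname parse_network
#' @param network A `DirectedPathwayNetwork`.
#' @export
write_sif <- function(network, path) {
  e <- network$edges[order(network$edges$source, network$edges$target), ]
  lines <- paste(e$source, e$type, e$target, sep = "\t")
  iso <- setdiff(network$nodes, c(e$source, e$target))
  writeLines(c(lines, iso), path)
  invisible(network)
}

# ---------------------------------------------------------------------------
# Restriction to measured genes
# ---------------------------------------------------------------------------

#' Restrict pathway resources to a dataset's measured genes
#'
#' Gene sets are intersected with the measured genes; sets falling below
#' `min_size` are dropped (ids recorded in the `dropped` attribute).
#' Networks keep all their nodes but record unmeasured ones (these get
#' initial walk weight 0).
#'
#' @param x A `GeneSetCollection` or `DirectedPathwayNetwork`.
#' @param dataset An `ExpressionDataset` (or character vector of gene ids).
#' @param min_size Minimum surviving set size (gene sets only).
#' @return Object of the same type as `x`.
#' @export
restrict_to_dataset <- function(x, dataset, min_size = 2L) {
  UseMethod("restrict_to_dataset")
}

measured_genes <- function(dataset) {
  if (inherits(dataset, "ExpressionDataset")) rownames(dataset$values)
  else toupper(as.character(dataset))
}

#' @export
restrict_to_dataset.GeneSetCollection <- function(x, dataset, min_size = 2L) {
  genes <- measured_genes(dataset)
  sets <- lapply(x, intersect, y = genes)
  keep <- lengths(sets) >= min_size
  out <- structure(sets[keep], source = attr(x, "source"),
                   class = "GeneSetCollection")
  attr(out, "dropped") <- names(sets)[!keep]
  out
}

#' @export
restrict_to_dataset.DirectedPathwayNetwork <- function(x, dataset,
                                                       min_size = 2L) {
  genes <- measured_genes(dataset)
  x$unmeasured <- setdiff(x$nodes, genes)
  x
}

# ---------------------------------------------------------------------------
# Synthetic directed network generator
# ---------------------------------------------------------------------------

#' Generate a synthetic directed gene network
#'
#' Builds a weakly connected directed graph with exactly the requested node
#' and edge counts: a preferential-attachment spanning tree (edge direction
#' randomised) plus degree-biased extra edges, no parallel duplicates.
#' Optional per-node attractiveness weights let callers make chosen nodes
#' (e.g. planted disease genes) into hubs. Deterministic per seed.
#'
#' @param n_nodes,n_edges Requested counts (`n_edges >= n_nodes - 1` and at
#'   most `n_nodes * (n_nodes - 1)`).
#' @param seed Integer RNG seed.
#' @param node_ids Optional node id vector (length `n_nodes`).
#' @param hub_weight Optional non-negative attractiveness per node.
#' @return A [directed_pathway_network()].
#' @export
generate_synthetic_network <- function(n_nodes, n_edges, seed,
                                       node_ids = NULL, hub_weight = NULL) {
  if (n_nodes < 2L) stop_validation("need at least 2 nodes")
  if (n_edges < n_nodes - 1L) {
    stop_validation("n_edges (", n_edges, ") < n_nodes - 1 (", n_nodes - 1L,
                    "): cannot be weakly connected")
  }
  if (n_edges > n_nodes * (n_nodes - 1L)) {
    stop_validation("n_edges exceeds the simple-digraph maximum")
  }
  ids <- node_ids %||% sprintf("N%04d", seq_len(n_nodes))
  attract <- hub_weight %||% rep(1, n_nodes)
  if (any(attract < 0)) stop_validation("hub_weight must be non-negative")
  attract <- attract + 1e-9  # keep sampling probabilities valid
  with_seed(seed, {
    deg <- numeric(n_nodes)
    src <- integer(n_edges); tgt <- integer(n_edges)
    for (i in 2:n_nodes) {
      j <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)] + attract[seq_len(i - 1L)])
      if (stats::runif(1) < 0.5) { src[i - 1L] <- j; tgt[i - 1L] <- i }
      else { src[i - 1L] <- i; tgt[i - 1L] <- j }
      deg[c(i, j)] <- deg[c(i, j)] + 1
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_len(n_nodes - 1L)) {
      assign(paste(src[k], tgt[k]), TRUE, envir = seen)
    }
    k <- n_nodes - 1L
    while (k < n_edges) {
      u <- sample.int(n_nodes, 1L, prob = deg + attract)
      v <- sample.int(n_nodes, 1L, prob = deg + attract)
      key <- paste(u, v)
      if (u != v && !exists(key, envir = seen, inherits = FALSE)) {
        k <- k + 1L
        src[k] <- u; tgt[k] <- v
        assign(key, TRUE, envir = seen)
        deg[c(u, v)] <- deg[c(u, v)] + 1
      }
    }
    types <- sample(c("activation", "inhibition"), n_edges, replace = TRUE)
    directed_pathway_network(
      data.frame(source = ids[src], target = ids[tgt], type = types),
      nodes = ids)
  })
}
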