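#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with a binary phenotype label
#' per sample. This is the universal input of every pathway activity
#' inference method in the package. The second factor level of `labels` is
#' treated as the case (tumour) class throughout: positive t-scores mean
#' up-regulation in that class.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids, unique),
#'   samples in columns (colnames = sample ids).
#' @param labels Factor or vector coercible to a two-level factor, one entry
#'   per sample. Entries `0`/`1` are mapped to `normal`/`tumour`.
#' @param check Validate invariants (two classes, >= 2 samples per class).
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` and `labels`.
#' @export
expression_dataset <- function(values, labels, check = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    stop_validation("expression matrix must have gene ids as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_validation("duplicate gene ids in expression matrix; collapse first")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  labels <- normalize_labels(labels)
  if (length(labels) != ncol(values)) {
    stop_format("label count (", length(labels), ") does not match sample count (",
                ncol(values), ")")
  }
  names(labels) <- colnames(values)
  ds <- structure(list(values = values, labels = labels),
                  class = "ExpressionDataset")
  if (check) validate_dataset(ds)
  ds
}

normalize_labels <- function(labels) {
  if (!is.factor(labels)) {
    lab <- as.character(labels)
    if (all(lab %in% c("0", "1"))) {
      lab <- c("0" = "normal", "1" = "tumour")[lab]
      labels <- factor(lab, levels = c("normal", "tumour"))
    } else {
      labels <- factor(lab, levels = unique(lab))
    }
  }
  labels
}

validate_dataset <- function(ds, min_per_class = 2L) {
  if (nlevels(ds$labels) != 2L) {
    stop_validation("expected exactly 2 phenotype classes, got ",
                    nlevels(ds$labels))
  }
  tab <- table(ds$labels)
  if (any(tab < min_per_class)) {
    stop_validation("each class needs >= ", min_per_class, " samples (",
                    paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  invisible(ds)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Number of genes / samples in a dataset
#' @param dataset An `ExpressionDataset`.
#' @return Integer count.
#' @export
n_genes <- function(dataset) nrow(dataset$values)

#' @rdname n_genes
#' @export
n_samples <- function(dataset) ncol(dataset$values)

#' Subset a dataset by sample index
#'
#' Keeps all genes, retains the label factor levels.
#' @param dataset An `ExpressionDataset`.
#' @param idx Sample indices (integer or sample ids).
#' @param check Re-validate the class balance of the subset.
#' @return An `ExpressionDataset`.
#' @export
subset_samples <- function(dataset, idx, check = TRUE) {
  expression_dataset(dataset$values[, idx, drop = FALSE],
                     dataset$labels[idx], check = check)
}

# ---------------------------------------------------------------------------
# Parsers: GCT v1.2, headered TSV, CLS, two-column label TSV
# ---------------------------------------------------------------------------

#' Read an expression matrix plus labels
#'
#' `matrix_source` may be a GCT v1.2 file (detected by its `#1.2` first line)
#' or a headered TSV with gene ids in the first column. `label_source` may be
#' a GenePattern CLS file or a two-column TSV (`sample<TAB>label`) aligned to
#' the matrix sample order. Duplicate gene rows are collapsed by their mean;
#' CRLF line endings and trailing blank lines are tolerated.
#'
#' @param matrix_source Path to the expression matrix file.
#' @param label_source Path to the label file.
#' @return A validated [expression_dataset()].
#' @export
parse_expression <- function(matrix_source, label_source) {
  mat <- parse_expression_matrix(matrix_source)
  labels <- parse_labels(label_source, sample_ids = colnames(mat))
  if (length(labels) != ncol(mat)) {
    stop_format("label count (", length(labels),
                ") does not match sample count (", ncol(mat), ")")
  }
  expression_dataset(mat, labels)
}

parse_expression_matrix <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop_format("empty expression file: ", path)
  if (trimws(lines[1L]) == "#1.2") {
    parse_gct_lines(lines, path)
  } else {
    parse_tsv_matrix_lines(lines, path)
  }
}

parse_gct_lines <- function(lines, path) {
  if (length(lines) < 3L) stop_format("truncated GCT file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2L]), "[ \t]+")[[1L]])
  if (length(dims) != 2L || anyNA(dims)) {
    stop_format("bad GCT dimension line: '", lines[2L], "'")
  }
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-(1:2)]
  body <- lines[-(1:3)]
  if (length(body) != dims[1L]) {
    stop_format("GCT declares ", dims[1L], " rows but has ", length(body))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  gene_ids <- toupper(vapply(fields, `[[`, "", 1L))
  vals <- t(vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    length(v) <- length(sample_ids)
    v
  }, numeric(length(sample_ids))))
  if (length(sample_ids) != dims[2L]) {
    stop_format("GCT declares ", dims[2L], " samples but header has ",
                length(sample_ids))
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  collapse_duplicate_genes(vals)
}

parse_tsv_matrix_lines <- function(lines, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  body <- fields[-1L]
  if (length(body) == 0L) stop_format("no data rows in ", path)
  gene_ids <- toupper(vapply(body, `[[`, "", 1L))
  vals <- t(vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    length(v) <- length(sample_ids)
    v
  }, numeric(length(sample_ids))))
  dimnames(vals) <- list(gene_ids, sample_ids)
  collapse_duplicate_genes(vals)
}

collapse_duplicate_genes <- function(vals) {
  if (anyDuplicated(rownames(vals))) {
    vals <- rowsum(vals, group = rownames(vals), reorder = FALSE) /
      as.vector(table(rownames(vals))[unique(rownames(vals))])
  }
  vals
}

parse_labels <- function(path, sample_ids = NULL) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop_format("empty label file: ", path)
  first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  looks_cls <- length(first) == 3L &&
    !anyNA(suppressWarnings(as.integer(first)))
  if (looks_cls) parse_cls_lines(lines) else parse_label_tsv_lines(lines, sample_ids)
}

parse_cls_lines <- function(lines) {
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  n_samples <- hdr[1L]; n_classes <- hdr[2L]
  if (n_classes != 2L) {
    stop_validation("CLS declares ", n_classes, " classes; exactly 2 required")
  }
  name_line <- grep("^#", lines)[1L]
  class_names <- if (!is.na(name_line)) {
    nm <- strsplit(trimws(sub("^#", "", lines[name_line])), "[ \t]+")[[1L]]
    nm[nzchar(nm)]
  } else NULL
  lab_line <- setdiff(seq_along(lines)[-1L],
                      if (is.na(name_line)) integer() else name_line)[1L]
  toks <- strsplit(trimws(lines[lab_line]), "[ \t]+")[[1L]]
  if (length(toks) != n_samples) {
    stop_format("CLS declares ", n_samples, " samples but lists ", length(toks))
  }
  if (all(toks %in% c("0", "1"))) {
    if (is.null(class_names) || length(class_names) != 2L) {
      class_names <- c("normal", "tumour")
    }
    factor(class_names[as.integer(toks) + 1L], levels = class_names)
  } else {
    factor(toks, levels = unique(toks))
  }
}

parse_label_tsv_lines <- function(lines, sample_ids) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_format("two-column label TSV requires sample<TAB>label per line")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  labs <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(c(ids[1L], labs[1L])), c("sample", "label"))) {
    ids <- ids[-1L]; labs <- labs[-1L]
  }
  if (!is.null(sample_ids) && all(sample_ids %in% ids)) {
    labs <- labs[match(sample_ids, ids)]
  }
  normalize_labels(labs)
}

# ---------------------------------------------------------------------------
# Writers (deterministic; round-trip partners of the parsers)
# ---------------------------------------------------------------------------

#' Write a dataset as GCT v1.2 + CLS
#'
#' @param dataset An `ExpressionDataset`.
#' @param gct_path,cls_path Output file paths.
#' @return Invisibly, the dataset.
#' @export
write_gct_cls <- function(dataset, gct_path, cls_path) {
  v <- dataset$values
  con <- file(gct_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  writeLines(paste(c("NAME", "Description", colnames(v)), collapse = "\t"), con)
  writeLines(paste(rownames(v), "na",
                   apply(v, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                         scientific = FALSE),
                                                  collapse = "\t")),
                   sep = "\t"), con)
  lab <- dataset$labels
  writeLines(c(paste(length(lab), nlevels(lab), 1),
               paste("#", paste(levels(lab), collapse = " ")),
               paste(as.integer(lab) - 1L, collapse = " ")),
             cls_path)
  invisible(dataset)
}

# ---------------------------------------------------------------------------
# Imputation and z-scoring
# ---------------------------------------------------------------------------

#' Mean-impute missing expression values
#'
#' Each missing entry is replaced by the mean of the non-missing entries of
#' its gene row. Rows that are entirely missing are dropped; their count and
#' ids are attached as attributes `n_dropped` / `dropped_genes`.
#'
#' @param dataset An `ExpressionDataset` possibly containing `NA` values.
#' @return An `ExpressionDataset` without missing values.
#' @export
impute_missing_mean <- function(dataset) {
  v <- dataset$values
  all_missing <- rowSums(!is.na(v)) == 0L
  dropped <- rownames(v)[all_missing]
  v <- v[!all_missing, , drop = FALSE]
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) {
    rm_ <- rowMeans(v, na.rm = TRUE)
    v[na_idx] <- rm_[na_idx[, 1L]]
  }
  out <- expression_dataset(v, dataset$labels, check = FALSE)
  attr(out, "n_dropped") <- length(dropped)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Row-wise z-scores of an expression matrix
#'
#' Standardises each gene row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Constant rows become all-zero and are flagged in the
#' `constant_genes` attribute rather than producing NaN, so downstream
#' weighted sums stay finite.
#'
#' @param dataset An `ExpressionDataset` (or bare matrix with dimnames).
#' @return A numeric matrix with attribute `constant_genes` (ids of flagged
#'   constant rows).
#' @export
zscore_rows <- function(dataset) {
  v <- if (inherits(dataset, "ExpressionDataset")) dataset$values else dataset
  if (ncol(v) < 2L) stop_validation("z-scoring needs >= 2 samples")
  mu <- rowMeans(v)
  sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  const <- sdv == 0 | !is.finite(sdv)
  sdv[const] <- 1
  z <- (v - mu) / sdv
  z[const, ] <- 0
  structure(z, constant_genes = rownames(v)[const])
}

# ---------------------------------------------------------------------------
# Per-gene statistics
# ---------------------------------------------------------------------------

# Vectorised pooled-variance two-sample t over matrix rows.
# Direction: case (second factor level) minus control. Zero pooled variance
# rows get t = 0, p = 1 and are flagged.
row_tstats <- function(values, labels) {
  labels <- normalize_labels(labels)
  stopifnot(nlevels(labels) == 2L)
  case <- labels == levels(labels)[2L]
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < 2L || n0 < 2L) {
    stop_validation("each class needs >= 2 samples for a t-test")
  }
  m1 <- rowMeans(values[, case, drop = FALSE])
  m0 <- rowMeans(values[, !case, drop = FALSE])
  ss1 <- rowSums((values[, case, drop = FALSE] - m1)^2)
  ss0 <- rowSums((values[, !case, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  sp2 <- (ss1 + ss0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  flagged <- se == 0
  t <- ifelse(flagged, 0, (m1 - m0) / ifelse(se == 0, 1, se))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(t), df = df))
  list(tscore = t, pvalue = p, flagged = flagged, df = df)
}

#' Per-gene differential-expression statistics
#'
#' Computes, for every gene row: the pooled-variance two-sample t statistic
#' (case minus control, so positive t means up-regulated in the tumour
#' class), its two-tailed p-value, the sign of t (0 maps to +1), the
#' point-biserial correlation with the 0/1 class label, the combined
#' PCT score `pbc + t` (both terms signed, so up- and down-regulated genes
#' weight coherently), and the Shannon entropy (bits) of the gene's
#' expression histogram.
#'
#' @param dataset An `ExpressionDataset` with two classes of >= 2 samples.
#' @param entropy_bins Histogram bin count for the entropy estimate; default
#'   Sturges' rule `ceiling(log2(n) + 1)`.
#' @return A `data.frame` of class `GeneStatistics` with columns `gene`,
#'   `tscore`, `pvalue`, `sign`, `pbc`, `pct`, `entropy`, `flagged`.
#' @export
gene_statistics <- function(dataset, entropy_bins = NULL) {
  validate_dataset(dataset)
  v <- dataset$values
  ts <- row_tstats(v, dataset$labels)
  y <- as.numeric(dataset$labels == levels(dataset$labels)[2L])
  pbc <- row_pbc(v, y)
  n <- ncol(v)
  bins <- entropy_bins %||% ceiling(log2(n) + 1)
  ent <- row_entropies(v, bins)
  out <- data.frame(gene = rownames(v),
                    tscore = ts$tscore,
                    pvalue = ts$pvalue,
                    sign = ifelse(ts$tscore < 0, -1, 1),
                    pbc = pbc,
                    pct = pbc + ts$tscore,
                    entropy = ent,
                    flagged = ts$flagged,
                    row.names = rownames(v))
  class(out) <- c("GeneStatistics", class(out))
  out
}

# Pearson correlation of each row with a numeric vector; constant rows -> 0.
row_pbc <- function(values, y) {
  yc <- y - mean(y)
  xc <- values - rowMeans(values)
  num <- as.vector(xc %*% yc)
  den <- sqrt(rowSums(xc^2) * sum(yc^2))
  ifelse(den == 0, 0, num / den)
}

#' Shannon entropy of a value vector
#'
#' Equal-width histogram over `[min, max]` with `bins` bins; entropy in bits,
#' zero-count bins contribute nothing. A constant vector has entropy 0.
#'
#' @param values Numeric vector (>= 2 values).
#' @param bins Positive integer bin count.
#' @return Entropy in bits, bounded by `log2(bins)`.
#' @export
gene_entropy <- function(values, bins) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_validation("entropy needs >= 2 values")
  if (bins < 1L) stop_validation("bins must be a positive integer")
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  idx <- findInterval(values, breaks, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Vectorised row-wise histogram entropy; agrees with gene_entropy per row.
row_entropies <- function(v, bins) {
  n <- ncol(v); ng <- nrow(v)
  lo <- as.numeric(do.call(pmin, asplit(v, 2L)))
  hi <- as.numeric(do.call(pmax, asplit(v, 2L)))
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  # left-closed equal-width bins, top edge folded into the last bin
  idx <- pmin(bins, floor((v - lo) / span * bins) + 1L)
  counts <- matrix(tabulate((seq_len(ng) - 1L) * bins + idx, nbins = ng * bins),
                   ng, bins, byrow = TRUE)
  pm <- counts / n
  ent <- -rowSums(ifelse(pm > 0, pm * log2(pm), 0))
  ent[const] <- 0
  ent
}
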