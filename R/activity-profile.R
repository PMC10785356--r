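#' Construct a pathway activity profile
#'
#' The universal method output: a pathways x samples activity matrix plus
#' per-pathway provenance (member genes actually used, number of qualifying
#' differentially expressed genes, method tag).
#'
#' @param activity Numeric matrix (pathways x samples) with dimnames.
#' @param provenance Named list (one entry per retained pathway) of lists
#'   with at least `genes` and `degs_used`.
#' @param method Method tag string.
#' @param dropped Character vector of pathway ids dropped by the method.
#' @return Object of class `PathwayActivityProfile`.
#' @export
pathway_activity_profile <- function(activity, provenance, method,
                                     dropped = character()) {
  stopifnot(is.matrix(activity),
            nrow(activity) == length(provenance),
            all(rownames(activity) == names(provenance)))
  structure(list(activity = activity, provenance = provenance,
                 method = method, dropped = dropped),
            class = "PathwayActivityProfile")
}

#' @export
print.PathwayActivityProfile <- function(x, ...) {
  cat("PathwayActivityProfile [", x$method, "]: ", nrow(x$activity),
      " pathways x ", ncol(x$activity), " samples (", length(x$dropped),
      " dropped)\n", sep = "")
  invisible(x)
}

#' Write / read an activity profile as headered TSV
#'
#' The TSV holds the pathways x samples matrix; a JSON sidecar
#' (`<path>.json`) records the method tag and per-pathway provenance.
#'
#' @param profile A `PathwayActivityProfile`.
#' @param path Output TSV path.
#' @return The profile, invisibly.
#' @export
write_profile <- function(profile, path) {
  a <- profile$activity
  lines <- c(paste(c("pathway", colnames(a)), collapse = "\t"),
             paste(rownames(a),
                   apply(a, 1L, function(r) {
                     paste(format(r, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = "\t")
                   }),
                   sep = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(list(method = profile$method,
                            dropped = profile$dropped,
                            provenance = profile$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(profile)
}

# Shared machinery for the weighted-sum activity formulas: every pathway is a
# linear functional of the z-matrix, activity = sum_i coef(gi) * z(gi) over
# its qualifying genes. Pathways whose gene list is empty or whose
# denominator is zero are dropped and reported.
weighted_sum_profile <- function(z, gene_lists, coefs, method, all_ids,
                                 degs_used = NULL) {
  keep <- names(gene_lists)
  if (length(keep) == 0L) {
    return(pathway_activity_profile(
      matrix(0, 0, ncol(z), dimnames = list(character(), colnames(z))),
      stats::setNames(list(), character()), method, dropped = all_ids))
  }
  i <- rep(seq_along(keep), lengths(gene_lists))
  j <- match(unlist(gene_lists, use.names = FALSE), rownames(z))
  C <- Matrix::sparseMatrix(i = i, j = j, x = unlist(coefs, use.names = FALSE),
                            dims = c(length(keep), nrow(z)))
  act <- as.matrix(C %*% z)
  dimnames(act) <- list(keep, colnames(z))
  prov <- stats::setNames(lapply(seq_along(keep), function(k) {
    list(genes = gene_lists[[k]],
         degs_used = if (is.null(degs_used)) length(gene_lists[[k]])
                     else degs_used[[k]],
         method = method)
  }), keep)
  pathway_activity_profile(act, prov, method,
                           dropped = setdiff(all_ids, keep))
}
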