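test_that("GCT + CLS round-trip reproduces the dataset and label mapping", {
  ds <- tiny_dataset()
  gct <- withr::local_tempfile(fileext = ".gct")
  cls <- withr::local_tempfile(fileext = ".cls")
  write_gct_cls(ds, gct, cls)
  back <- parse_expression(gct, cls)
  expect_equal(back$values, ds$values)
  expect_identical(as.character(back$labels),
                   c("normal", "normal", "tumour", "tumour"))
})

test_that("headered TSV + two-column label file parse to the same dataset", {
  ds <- tiny_dataset()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("gene", colnames(ds$values)), collapse = "\t"),
               paste(rownames(ds$values),
                     apply(ds$values, 1, paste, collapse = "\t"),
                     sep = "\t")), tsv)
  writeLines(paste(colnames(ds$values), c("0", "0", "1", "1"), sep = "\t"),
             lab)
  back <- parse_expression(tsv, lab)
  expect_equal(back$values, ds$values)
  expect_identical(back$labels, ds$labels)
})

test_that("parsers tolerate CRLF endings and trailing blank lines", {
  ds <- tiny_dataset()
  gct <- withr::local_tempfile(fileext = ".gct")
  cls <- withr::local_tempfile(fileext = ".cls")
  write_gct_cls(ds, gct, cls)
  crlf <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(paste0(readLines(gct), "\r"), "", ""), crlf, sep = "\n")
  expect_equal(parse_expression(crlf, cls)$values, ds$values)
})

test_that("duplicate gene rows collapse by mean", {
  gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t4",
               paste(c("NAME", "Description", paste0("S", 1:4)),
                     collapse = "\t"),
               paste(c("TP53", "na", 1, 1, 1, 1), collapse = "\t"),
               paste(c("TP53", "na", 3, 3, 3, 3), collapse = "\t")), gct)
  cls <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 2 1", "# normal tumour", "0 0 1 1"), cls)
  ds <- parse_expression(gct, cls)
  expect_equal(unname(ds$values["TP53", ]), c(2, 2, 2, 2))
  expect_identical(nrow(ds$values), 1L)
})

test_that("label contract violations raise distinct errors", {
  ds <- tiny_dataset()
  gct <- withr::local_tempfile(fileext = ".gct")
  cls <- withr::local_tempfile(fileext = ".cls")
  write_gct_cls(ds, gct, cls)
  cls3 <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("4 3 1", "# a b c", "0 1 2 0"), cls3)
  expect_error(parse_expression(gct, cls3), class = "pathact_validation_error")
  short <- withr::local_tempfile(fileext = ".cls")
  writeLines(c("3 2 1", "# normal tumour", "0 0 1"), short)
  expect_error(parse_expression(gct, short), class = "pathact_format_error")
  expect_error(expression_dataset(ds$values, c("0", "0", "0", "1")),
               class = "pathact_validation_error")
})

test_that("mean imputation fills within rows and drops all-missing rows", {
  v <- rbind(A = c(1, NA, 3), B = c(4, 5, 6), C = c(NA, NA, NA))
  colnames(v) <- paste0("S", 1:3)
  ds <- structure(list(values = v,
                       labels = factor(c("normal", "normal", "tumour"),
                                       levels = c("normal", "tumour"))),
                  class = "ExpressionDataset")
  out <- impute_missing_mean(ds)
  expect_equal(unname(out$values["A", ]), c(1, 2, 3))
  expect_equal(unname(out$values["B", ]), c(4, 5, 6))
  expect_false("C" %in% rownames(out$values))
  expect_identical(attr(out, "n_dropped"), 1L)
})

test_that("row z-scores standardise exactly and flag constant rows", {
  ds <- tiny_dataset()
  z <- zscore_rows(ds)
  expect_equal(unname(z["GENE1", ]), c(0, 0, 0, 0))
  expect_identical(attr(z, "constant_genes"), "GENE1")
  simple <- matrix(c(1, 2, 3), 1, dimnames = list("G", paste0("S", 1:3)))
  expect_equal(unname(zscore_rows(simple)[1, ]), c(-1, 0, 1))
  rds <- random_dataset(50, 5, seed = 3)
  zr <- zscore_rows(rds)
  expect_lt(max(abs(rowMeans(zr))), 1e-9)
  expect_lt(max(abs(apply(zr, 1, sd) - 1)), 1e-9)
  expect_error(zscore_rows(matrix(1, 2, 1, dimnames = list(c("A", "B"), "S1"))),
               class = "pathact_validation_error")
})

test_that("gene t statistics match the reference routine and its conventions", {
  v <- rbind(G1 = c(1, 2, 3, 2, 3, 4))
  colnames(v) <- paste0("S", 1:6)
  ds <- expression_dataset(v, c("0", "0", "0", "1", "1", "1"))
  st <- gene_statistics(ds)
  tt <- t.test(c(2, 3, 4), c(1, 2, 3), var.equal = TRUE)
  expect_equal(st$tscore, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st$tscore, 1.2247, tolerance = 1e-4)
  expect_equal(st$pvalue, tt$p.value, tolerance = 1e-12)
  expect_equal(st$pvalue, 0.2878, tolerance = 1e-3)
  # equal class means: t = 0, sign maps to +1
  v2 <- rbind(G1 = c(1, 2, 3, 3, 2, 1))
  colnames(v2) <- paste0("S", 1:6)
  st2 <- gene_statistics(expression_dataset(v2, c(0, 0, 0, 1, 1, 1)))
  expect_identical(st2$tscore, 0)
  expect_identical(st2$sign, 1)
})

test_that("label swap negates t and pbc but preserves p and entropy", {
  ds <- random_dataset(40, 6, seed = 11)
  st <- gene_statistics(ds)
  swapped <- expression_dataset(ds$values,
                                factor(ifelse(ds$labels == "normal",
                                              "tumour", "normal"),
                                       levels = c("normal", "tumour")))
  st2 <- gene_statistics(swapped)
  expect_equal(st2$tscore, -st$tscore, tolerance = 1e-12)
  expect_equal(st2$pbc, -st$pbc, tolerance = 1e-12)
  expect_equal(st2$pvalue, st$pvalue, tolerance = 1e-12)
  expect_equal(st2$entropy, st$entropy, tolerance = 1e-12)
  # shifting one gene by a constant changes nothing
  shifted <- ds
  shifted$values[1, ] <- shifted$values[1, ] + 100
  expect_equal(gene_statistics(shifted)$tscore[1], st$tscore[1],
               tolerance = 1e-9)
})

test_that("point-biserial correlation equals Pearson correlation with the 0/1 label", {
  ds <- random_dataset(100, 8, seed = 5)
  st <- gene_statistics(ds)
  y <- as.numeric(ds$labels == "tumour")
  oracle <- apply(ds$values, 1, cor, y = y)
  expect_equal(st$pbc, unname(oracle), tolerance = 1e-10)
  expect_true(all(st$pbc >= -1 & st$pbc <= 1))
})

test_that("zero pooled variance is flagged with t = 0 and p = 1", {
  v <- rbind(G1 = c(1, 1, 2, 2), G2 = c(1, 2, 3, 4))
  colnames(v) <- paste0("S", 1:4)
  st <- gene_statistics(expression_dataset(v, c(0, 0, 1, 1)))
  expect_true(st["G1", "flagged"])
  expect_identical(st["G1", "tscore"], 0)
  expect_identical(st["G1", "pvalue"], 1)
  expect_false(st["G2", "flagged"])
})

test_that("histogram entropy obeys its closed forms and bounds", {
  expect_identical(gene_entropy(rep(3.3, 10), bins = 4), 0)
  expect_equal(gene_entropy(c(0, 1, 10, 11), bins = 2), 1, tolerance = 1e-12)
  set.seed(42)
  for (bins in c(2, 5, 8)) {
    x <- rnorm(50)
    e <- gene_entropy(x, bins)
    expect_lte(e, log2(bins))
    expect_gte(e, 0)
    expect_equal(gene_entropy(sample(x), bins), e, tolerance = 1e-12)
  }
})

test_that("vectorised row entropies agree with the per-vector estimator", {
  ds <- random_dataset(60, 10, seed = 9)
  bins <- ceiling(log2(20) + 1)
  vec <- apply(ds$values, 1, gene_entropy, bins = bins)
  expect_equal(unname(pathact:::row_entropies(ds$values, bins)), unname(vec),
               tolerance = 1e-12)
})
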