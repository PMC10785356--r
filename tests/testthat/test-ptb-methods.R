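two_node_cycle <- function() {
  directed_pathway_network(data.frame(source = c("A", "B"),
                                      target = c("B", "A")))
}

test_that("initial weight vectors normalise onto the simplex", {
  st <- make_stats(c("A", "B"), tscore = c(3, -1), pvalue = c(0.01, 0.2),
                   entropy = c(2, 6))
  net <- two_node_cycle()
  w <- initial_weight_vector(st, net, "abs_t")
  expect_equal(w, c(A = 0.75, B = 0.25), tolerance = 1e-12)
  we <- initial_weight_vector(st, net, "entropy")
  expect_equal(we, c(A = 0.25, B = 0.75), tolerance = 1e-12)
  # unmeasured node gets zero weight, vector still sums to 1
  net3 <- directed_pathway_network(data.frame(source = c("A", "B", "C"),
                                              target = c("B", "C", "A")))
  w3 <- initial_weight_vector(st, net3, "abs_t")
  expect_identical(unname(w3["C"]), 0)
  expect_equal(sum(w3), 1, tolerance = 1e-12)
  st0 <- make_stats(c("A", "B"), tscore = c(0, 0), pvalue = c(1, 1))
  expect_error(initial_weight_vector(st0, net, "abs_t"),
               class = "pathact_validation_error")
  stx <- make_stats(c("X", "Y"), tscore = c(1, 1), pvalue = c(0.01, 0.01))
  expect_error(initial_weight_vector(stx, net, "abs_t"),
               class = "pathact_validation_error")
})

test_that("the two-node worked walk value is reproduced", {
  wk <- random_walk_restart(two_node_cycle(), c(A = 1, B = 0),
                            walk_config(restart = 0.7))
  expect_equal(unname(wk$w_inf), c(10 / 13, 3 / 13), tolerance = 1e-9)
  expect_lt(wk$residual, 1e-10)
})

test_that("restart probability 1 returns the seed vector after one step", {
  wk <- random_walk_restart(two_node_cycle(), c(A = 0.6, B = 0.4),
                            walk_config(restart = 1))
  expect_equal(wk$w_inf, c(A = 0.6, B = 0.4), tolerance = 0)
  expect_identical(wk$iterations, 1L)
})

test_that("iterative walk agrees with the dense linear solve on random graphs", {
  for (s in 1:6) {
    n <- 5 + 5 * s
    net <- generate_synthetic_network(n, min(3 * n, n * (n - 1)), seed = s)
    w0 <- pathact:::with_seed(100 + s, {
      x <- runif(n)
      stats::setNames(x / sum(x), net$nodes)
    })
    wk <- random_walk_restart(net, w0, walk_config(0.7))
    expect_lt(max(abs(wk$w_inf - oracle_walk(net, w0, 0.7))), 1e-8)
    expect_lte(wk$mass_dev, 1e-12)
    expect_equal(sum(wk$w_inf), 1, tolerance = 1e-9)
    expect_true(all(wk$w_inf >= 0))
  }
})

test_that("the built-in closed-form check matches the iterate", {
  net <- generate_synthetic_network(20, 60, seed = 4)
  w0 <- stats::setNames(rep(1 / 20, 20), net$nodes)
  wk <- random_walk_restart(net, w0, walk_config(0.7, closed_form = TRUE))
  expect_lt(wk$closed_form_residual, 1e-8)
})

test_that("exceeding the iteration cap is a convergence error", {
  expect_error(random_walk_restart(two_node_cycle(), c(A = 1, B = 0),
                                   walk_config(0.1, tolerance = 1e-12,
                                               max_iter = 2)),
               "converge")
})

test_that("more seed mass at a node never lowers its stationary weight", {
  net <- directed_pathway_network(
    data.frame(source = c("A", "B", "C", "D", "E", "A", "C"),
               target = c("B", "C", "D", "E", "A", "C", "E")))
  prev <- -Inf
  for (mass in seq(0.1, 0.9, by = 0.2)) {
    w0 <- stats::setNames(rep((1 - mass) / 4, 5), net$nodes)
    w0["A"] <- mass
    wk <- random_walk_restart(net, w0, walk_config(0.7))
    expect_gte(wk$w_inf[["A"]], prev)
    prev <- wk$w_inf[["A"]]
  }
})

test_that("edge re-weighting averages node weights and re-normalises", {
  net <- directed_pathway_network(data.frame(source = c("A", "A", "B"),
                                             target = c("B", "C", "C")))
  rw <- sdrw_reweight(net, c(A = 0.4, B = 0.2, C = 0))
  eAB <- rw$edges$weight[rw$edges$source == "A" & rw$edges$target == "B"]
  expect_equal(eAB, 0.3, tolerance = 1e-12)
  # uniform node weights reduce to the unweighted transition
  uni <- sdrw_reweight(net, c(A = 1, B = 1, C = 1))
  expect_lt(max(abs(as.matrix(uni$transition) - as.matrix(net$transition))),
            1e-12)
  # all-zero out-weights create a dangling node
  z <- sdrw_reweight(net, c(A = 0, B = 0, C = 0))
  expect_setequal(z$dangling, c("A", "B", "C"))
  expect_error(sdrw_reweight(net, c(A = -1, B = 1, C = 1)),
               class = "pathact_validation_error")
})

test_that("walk-weighted activity reproduces hand-worked values", {
  z <- rbind(A = c(1, 2), B = c(1, -1))
  colnames(z) <- c("S1", "S2")
  st <- make_stats(c("A", "B"), tscore = c(4, -3), pvalue = c(0.01, 0.01))
  wk <- structure(list(w_inf = c(A = 0.3, B = 0.4)), class = "WalkResult")
  prof <- drw_activity(z, st, wk, gene_set_collection(list(P = c("A", "B"),
                                                           Q = "A")))
  expect_equal(prof$activity["P", "S1"], (0.3 - 0.4) / sqrt(0.25),
               tolerance = 1e-12)
  # single qualifying gene: weight cancels, activity = sign * z
  expect_equal(prof$activity["Q", ], z["A", ], tolerance = 1e-12)
  # all member weights zero: pathway dropped
  wk0 <- structure(list(w_inf = c(A = 0, B = 0)), class = "WalkResult")
  p0 <- drw_activity(z, st, wk0, gene_set_collection(list(P = c("A", "B"))))
  expect_identical(p0$dropped, "P")
})

test_that("uniform walk weights reduce the walk formula to signed z aggregation", {
  bench <- small_bench()
  ds <- bench$dataset
  st <- gene_statistics(ds)
  z <- zscore_rows(ds)
  sets <- restrict_to_dataset(bench$sets, ds)
  wk <- structure(list(w_inf = stats::setNames(rep(0.01, nrow(z)),
                                               rownames(z))),
                  class = "WalkResult")
  pd <- drw_activity(z, st, wk, sets, p_threshold = 0.01)
  pc <- combiner_activity(z, st, sets, p_threshold = 0.01,
                          max_genes = nrow(z))
  common <- intersect(rownames(pd$activity), rownames(pc$activity))
  # identical gene selections imply identical activities
  same <- vapply(common, function(p) {
    setequal(pd$provenance[[p]]$genes, pc$provenance[[p]]$genes)
  }, NA)
  expect_gt(sum(same), 0)
  expect_equal(pd$activity[common[same], ], pc$activity[common[same], ],
               tolerance = 1e-10)
})

test_that("entropy-walk activity matches its hand-worked normalisations", {
  z <- rbind(A = c(1, 0.5), B = c(2, -1))
  colnames(z) <- c("S1", "S2")
  st <- make_stats(c("A", "B"), tscore = c(4, 3), pvalue = c(0.01, 0.01),
                   pbc = c(0.5, 0.25))
  # equal H_inf means equal entropy weights (1/2, 1/2)
  wk <- structure(list(w_inf = c(A = 0.2, B = 0.2)), class = "WalkResult")
  sets <- gene_set_collection(list(P = c("A", "B"), Q = "A"))
  prof <- edrw_activity(z, st, wk, sets)
  den <- sqrt(0.5)
  expect_equal(prof$activity["P", "S1"],
               (0.2 * 4.5 * 1 + 0.2 * 3.25 * 2) / den, tolerance = 1e-12)
  ew <- edrw_entropy_weights(wk$w_inf, c("A", "B"))
  expect_equal(ew, c(A = 0.5, B = 0.5), tolerance = 1e-12)
  # single member: entropy weight 1, activity = H * PCT * z
  expect_equal(prof$activity["Q", ], 0.2 * 4.5 * z["A", ],
               tolerance = 1e-12)
})

test_that("profiles from two source networks concatenate disjointly", {
  z <- rbind(A = c(1, 0), B = c(0, 1), C = c(1, 1))
  colnames(z) <- c("S1", "S2")
  st <- make_stats(c("A", "B", "C"), tscore = c(4, 3, 2),
                   pvalue = c(0.01, 0.01, 0.01), pbc = c(0.3, 0.2, 0.1))
  walks <- list(net1 = structure(list(w_inf = c(A = 0.5, B = 0.5)),
                                 class = "WalkResult"),
                net2 = structure(list(w_inf = c(B = 0.5, C = 0.5)),
                                 class = "WalkResult"))
  sets <- list(net1 = gene_set_collection(list(P = c("A", "B"), R1 = "A")),
               net2 = gene_set_collection(list(P = c("B", "C"), R2 = "C")))
  prof <- edrw_activity(z, st, walks, sets)
  expect_setequal(rownames(prof$activity),
                  c("P.net1", "P.net2", "R1", "R2"))
  expect_identical(anyDuplicated(rownames(prof$activity)), 0L)
})

test_that("walk-based pipelines are deterministic end to end", {
  bench <- small_bench()
  ds <- bench$dataset
  for (m in c("drw", "sdrw", "edrw")) {
    p1 <- pathway_activity(ds, m, sets = bench$sets, network = bench$network)
    p2 <- pathway_activity(ds, m, sets = bench$sets, network = bench$network)
    expect_identical(p1$activity, p2$activity)
  }
})
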