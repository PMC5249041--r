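test_that("generation is deterministic and positive definite", {
  spec <- synthetic_spec(n_mirna = 4, n_mrna = 10, n_edges = 8,
                         n_samples = 50, seed = 31)
  d1 <- simulate_expression(spec)
  d2 <- simulate_expression(spec)
  expect_identical(d1$expression$values, d2$expression$values)
  expect_identical(d1$direct_edges, d2$direct_edges)
  # Cholesky of the implied covariance succeeds (positive definiteness)
  expect_no_error(chol(solve(d1$omega)))
  expect_equal(unname(diag(d1$omega)), rep(1, 14), tolerance = 1e-12)
  # direct edges are exactly the nonzero bipartite precision entries
  blk <- d1$omega[mirna_ids(d1$expression), mrna_ids(d1$expression)]
  nz <- which(blk != 0, arr.ind = TRUE)
  expect_setequal(paste(rownames(blk)[nz[, 1]], colnames(blk)[nz[, 2]]),
                  paste(d1$direct_edges$mirna, d1$direct_edges$mrna))
  # ground truth mirrors the edge list
  expect_equal(attr(d1$truth, "n_pairs"), nrow(d1$direct_edges))
})

test_that("a single strong edge is recovered at its generating value", {
  d <- simulate_expression(synthetic_spec(n_mirna = 2, n_mrna = 2,
                                          n_edges = 1,
                                          weight_range = c(0.4, 0.4),
                                          n_samples = 10000, noise_sd = 0,
                                          seed = 41))
  x <- standardize_expression(d$expression)
  pc <- shrinkage_partial_correlation(x, lambda = 0)
  edge <- d$direct_edges
  est <- pc$values[edge$mirna, edge$mrna]
  expect_lt(abs(abs(est) - 0.4), 0.05)
  expect_equal(sign(est), sign(edge$partial_cor))
})

test_that("an empty graph yields near-zero cross-correlations", {
  d <- simulate_expression(synthetic_spec(n_mirna = 3, n_mrna = 8,
                                          n_edges = 0, n_samples = 2000,
                                          seed = 43))
  r <- cor(t(d$expression$values))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  expect_equal(nrow(indirect_pairs(d)), 0)
})

test_that("the repressive flag forces negative miRNA-mRNA correlations", {
  d <- simulate_expression(synthetic_spec(n_mirna = 3, n_mrna = 8,
                                          n_edges = 6, n_samples = 4000,
                                          seed = 47, repressive = TRUE))
  expect_true(all(d$direct_edges$partial_cor < 0))
  r <- cor(t(d$expression$values))
  marg <- r[cbind(d$direct_edges$mirna, d$direct_edges$mrna)]
  expect_true(all(marg < 0))
})

test_that("indirect pairs match the adjacency-power oracle on toy graphs", {
  toy <- function(n_mirna, n_mrna, edges, seed = 53) {
    # build a dataset object with a prescribed edge set (samples irrelevant)
    d <- simulate_expression(synthetic_spec(n_mirna = n_mirna,
                                            n_mrna = n_mrna,
                                            n_edges = 1, n_samples = 10,
                                            seed = seed))
    d$direct_edges <- edges
    d
  }
  mir <- sprintf("miR-%02d", 1:3)
  gene <- sprintf("gene%03d", 1:3)

  # two miRNAs sharing one mRNA: no bipartite pair is indirectly connected
  star <- toy(3, 3, data.frame(mirna = mir[1:2], mrna = gene[c(1, 1)],
                               partial_cor = 0.3))
  expect_equal(nrow(indirect_pairs(star)), 0)

  # path m1 - g1 - m2 - g2: (m1, g2) is the one 3-step indirect pair
  path <- toy(3, 3, data.frame(mirna = mir[c(1, 2, 2)],
                               mrna = gene[c(1, 1, 2)],
                               partial_cor = 0.3))
  ip <- indirect_pairs(path)
  expect_equal(paste(ip$mirna, ip$mrna), "miR-01 gene002")

  # complete bipartite graph: every pair is direct, none indirect
  full_edges <- expand.grid(mirna = mir, mrna = gene,
                            stringsAsFactors = FALSE)
  full_edges$partial_cor <- 0.1
  expect_equal(nrow(indirect_pairs(toy(3, 3, full_edges))), 0)

  # generic random graphs agree with explicit matrix powers
  for (seed in 1:3) {
    d <- simulate_expression(synthetic_spec(n_mirna = 4, n_mrna = 8,
                                            n_edges = 10, n_samples = 10,
                                            seed = 60 + seed))
    A <- matrix(0, 4, 8, dimnames = list(mirna_ids(d$expression),
                                         mrna_ids(d$expression)))
    A[cbind(d$direct_edges$mirna, d$direct_edges$mrna)] <- 1
    oracle <- A %*% t(A) %*% A
    got <- indirect_pairs(d)
    expect_setequal(paste(got$mirna, got$mrna),
                    paste(rownames(A)[which(oracle > 0 & A == 0,
                                            arr.ind = TRUE)[, 1]],
                          colnames(A)[which(oracle > 0 & A == 0,
                                            arr.ind = TRUE)[, 2]]))
  }
})

test_that("spec validation rejects impossible requests", {
  expect_error(synthetic_spec(n_edges = 500, n_mirna = 2, n_mrna = 3),
               "n_edges")
  expect_error(synthetic_spec(weight_range = c(0.5, 1.5)), "weight_range")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("written synthetic datasets drive the file pipeline unchanged", {
  d <- simulate_expression(synthetic_spec(n_mirna = 3, n_mrna = 6,
                                          n_edges = 5, n_samples = 30,
                                          seed = 71))
  dir <- file.path(tempdir(), "synth-io")
  paths <- write_synthetic_dataset(d, dir)
  mir <- read_expression(paths[["mirna"]], "mirna")
  mr <- read_expression(paths[["mrna"]], "mrna")
  expect_identical(mir$values, d$expression$values[mirna_ids(d$expression), ])
  expect_identical(mr$values, d$expression$values[mrna_ids(d$expression), ])
  gt <- read_ground_truth(paths[["truth"]])
  expect_equal(attr(gt, "n_pairs"), nrow(d$direct_edges))
})
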