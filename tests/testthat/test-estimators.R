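test_that("pearson matrix matches the textbook sum-formula oracle", {
  x <- random_expr(5, 50, seed = 11)
  r <- pearson_matrix(x)
  expect_equal(r$role, "observed")
  expect_equal(unname(diag(r$values)), rep(1, 5))
  # brute-force oracle from centered sums
  oracle <- diag(5)
  for (i in 1:4) for (j in (i + 1):5) {
    a <- x$values[i, ] - mean(x$values[i, ])
    b <- x$values[j, ] - mean(x$values[j, ])
    oracle[i, j] <- oracle[j, i] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  expect_lt(max(abs(unname(r$values) - oracle)), 1e-12)

  # perfectly dependent rows
  v <- rbind(1:10, 1:10, -(1:10)) + 0
  y <- make_expr(v)
  ry <- pearson_matrix(y)$values
  expect_equal(unname(ry[1, 2]), 1)
  expect_equal(unname(ry[1, 3]), -1)
})

test_that("shrinkage partial correlation reduces to pairwise r at p = 2", {
  x <- random_expr(2, 40, seed = 3)
  r12 <- cor(x$values[1, ], x$values[2, ])
  for (lam in c(0, 0.3, 0.8)) {
    pc <- shrinkage_partial_correlation(x, lambda = lam)
    expect_equal(unname(pc$values[1, 2]), (1 - lam) * r12, tolerance = 1e-12)
  }
})

test_that("unshrunk partial correlations match the residual-regression oracle", {
  for (seed in 1:5) {
    p <- sample(4:8, 1)
    x <- random_expr(p, 200, seed = 100 + seed)
    pc <- shrinkage_partial_correlation(x, lambda = 0)
    expect_lt(max(abs(pc$values - pcor_oracle(x$values))), 1e-10)
  }
})

test_that("independent features give near-zero partial correlations", {
  x <- random_expr(4, 500, seed = 21)
  pc <- shrinkage_partial_correlation(x)
  off <- pc$values[upper.tri(pc$values)]
  expect_lt(max(abs(off)), 0.3)
})

test_that("shrinkage intensity is in [0,1] and monotonically shrinks", {
  x <- random_expr(6, 30, seed = 5)
  auto <- shrinkage_partial_correlation(x)
  expect_gte(auto$meta$lambda, 0)
  expect_lte(auto$meta$lambda, 1)
  lams <- c(0.1, 0.4, 0.7, 0.95)
  maxabs <- vapply(lams, function(l) {
    v <- shrinkage_partial_correlation(x, lambda = l)$values
    max(abs(v[upper.tri(v)]))
  }, numeric(1))
  expect_true(all(diff(maxabs) < 1e-12))
  # all outputs symmetric and bounded
  v <- auto$values
  expect_lt(max(abs(v - t(v))), 1e-10)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("mutual information matches hand-computed plug-in values", {
  # n = 4, 2 equal-frequency bins: x bins (1,1,2,2); y = (5,6,8,7) also bins
  # (1,1,2,2), so the joint table is diagonal with counts (2,2) and
  # MI = 2 * (2/4) * log((2/4)/((1/2)(1/2))) = log 2 nats.
  x <- make_expr(rbind(c(0.1, 0.2, 0.3, 0.4), c(5, 6, 8, 7)))
  mi <- mutual_information_matrix(x, bins = 2)
  expect_equal(unname(mi$values[1, 2]), log(2), tolerance = 1e-12)
  expect_equal(unname(diag(mi$values)), c(0, 0))

  # a feature duplicated under another id attains the maximum log(B)
  # (uniform diagonal joint table) when B divides n
  set.seed(8)
  v <- rnorm(100)
  dup <- make_expr(rbind(a = v, b = v))
  mi2 <- mutual_information_matrix(dup, bins = 10)
  expect_equal(unname(mi2$values[1, 2]), log(10), tolerance = 1e-12)
})

test_that("mutual information of independent features is near zero", {
  # The plug-in estimator has upward bias about (B-1)^2/(2n), so the
  # near-zero check uses a modest bin count where the bias is ~0.008 nats;
  # at the auto bin count independence is still far below a real signal.
  set.seed(33)
  x <- make_expr(rbind(runif(1000), runif(1000)))
  mi5 <- mutual_information_matrix(x, bins = 5)
  expect_lt(mi5$values[1, 2], 0.05)
  mi <- mutual_information_matrix(x)  # auto bins = floor(sqrt(1000)) = 31
  expect_equal(mi$meta$bins, 31L)
  expect_true(all(mi$values >= 0))
  expect_lt(mi$values[1, 2], 0.6)  # bias (~0.45) plus sampling slack
  dep <- make_expr(rbind(x$values[1, ], x$values[1, ] +
                           rnorm(1000, sd = 0.1)))
  expect_gt(mutual_information_matrix(dep)$values[1, 2], mi$values[1, 2])
  expect_error(mutual_information_matrix(x, bins = 2000), "exceeds")
})

test_that("network deconvolution inverts the transitive-flow composition", {
  # zero network is a fixed point
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(network_deconvolution(z)$values), unname(z))

  # 2 x 2 single edge: eigenvalues +/- a map to a/(1 +/- a), giving
  # off-diagonal a/(1 - a^2) under composition; deconvolution returns 0.5
  g <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  obs <- compose_observed(g)
  expect_equal(unname(obs[1, 2]), 0.5 / (1 - 0.25), tolerance = 1e-12)
  dec <- network_deconvolution(obs, rescale = FALSE, zero_diag = FALSE)
  expect_equal(unname(dec$values[1, 2]), 0.5, tolerance = 1e-10)
  # the direct formula on the single-edge matrix maps its eigenvalues
  # +/- a to a/(1+a) and -a/(1-a)
  dec2 <- network_deconvolution(g, rescale = FALSE, zero_diag = FALSE)
  expect_equal(eigen(dec2$values, symmetric = TRUE)$values,
               c(0.5 / 1.5, -0.5 / 0.5), tolerance = 1e-12)

  # round trip on a random direct network with spectral radius 0.6
  gd <- random_symmetric(8, seed = 14, radius = 0.6)
  rec <- network_deconvolution(compose_observed(gd), rescale = FALSE,
                               zero_diag = FALSE)
  expect_lt(max(abs(rec$values - gd)), 1e-8)
})

test_that("deconvolution preserves eigenvectors and rescales the spectrum", {
  g <- random_symmetric(6, seed = 9, radius = 3)  # needs rescaling
  dec <- network_deconvolution(g, delta = 0.9, zero_diag = FALSE)
  expect_equal(dec$meta$beta, 0.9 / 3, tolerance = 1e-12)
  eg <- eigen(g, symmetric = TRUE)
  ed <- eigen(dec$values, symmetric = TRUE)
  # mapped eigenvalues lam -> lam/(1+lam) on the scaled input, in order
  # (the map is strictly increasing on lam > -1)
  lam <- dec$meta$beta * eg$values
  expect_equal(ed$values, sort(lam / (1 + lam), decreasing = TRUE),
               tolerance = 1e-10)
  expect_error(network_deconvolution(matrix(c(0, 1, 0.5, 0), 2, 2)),
               "not symmetric")
})

test_that("MIND suppresses transitive association on a chain", {
  # chain m1 - g1 - g2: the (m1, g2) association is purely transitive
  v <- sample_ggm(chain_omega(0.45), 500, seed = 4,
                  ids = c("m1", "g1", "g2"))
  x <- standardize_expression(expr_set(v, c("mirna", "mrna", "mrna")))
  s <- mind(x)
  expect_equal(s$role, "direct")
  expect_lt(abs(s$values["m1", "g2"]),
            min(abs(s$values["m1", "g1"]), abs(s$values["g1", "g2"])))
})

test_that("an isolated correlated pair ranks first under MIND", {
  set.seed(61)
  n <- 1000
  base <- rnorm(n)
  v <- rbind(m1 = base, g1 = base + rnorm(n, sd = 0.4),
             g2 = rnorm(n), g3 = rnorm(n), g4 = rnorm(n))
  x <- standardize_expression(make_expr(v, kind = c("mirna", rep("mrna", 4))))
  s <- mind(x)
  off <- abs(s$values[upper.tri(s$values)])
  expect_equal(max(off), abs(s$values["m1", "g1"]))
  # independent features stay well below the genuine association
  others <- abs(s$values["g2", c("g3", "g4")])
  expect_lt(max(others), 0.5 * abs(s$values["m1", "g1"]))
})
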