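# Shared fixtures and independent oracles, all built in code.

# Small expression set with the given value matrix (features x samples).
make_expr <- function(values, kind = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  if (is.null(kind)) kind <- rep("mrna", nrow(values))
  expr_set(values, kind)
}

# Random expression set from iid standard normals.
random_expr <- function(p, n, seed, kind = NULL) {
  set.seed(seed)
  make_expr(matrix(rnorm(p * n), p, n), kind = kind)
}

# Random symmetric matrix with zero diagonal, scaled to the given spectral
# radius.
random_symmetric <- function(p, seed, radius = 0.6) {
  set.seed(seed)
  m <- matrix(rnorm(p * p), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  m <- m * radius / max(abs(ev))
  dimnames(m) <- list(sprintf("f%02d", 1:p), sprintf("f%02d", 1:p))
  m
}

# Forward model of transitive information flow: the observed network implied
# by a direct network with spectral radius < 1 (sum of all path products).
compose_observed <- function(g_dir) {
  g_dir %*% solve(diag(nrow(g_dir)) - g_dir)
}

# Independent partial-correlation oracle: correlate the residuals of each
# pair after regressing both on all remaining variables.
pcor_oracle <- function(values) {
  p <- nrow(values)
  out <- diag(p)
  dimnames(out) <- list(rownames(values), rownames(values))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others)) {
        design <- cbind(1, t(values[others, , drop = FALSE]))
        ri <- lm.fit(design, values[i, ])$residuals
        rj <- lm.fit(design, values[j, ])$residuals
      } else {
        ri <- values[i, ] - mean(values[i, ])
        rj <- values[j, ] - mean(values[j, ])
      }
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# Draw n samples from the Gaussian with the given precision matrix, as a
# features x samples matrix.
sample_ggm <- function(omega, n, seed, ids = NULL) {
  set.seed(seed)
  p <- nrow(omega)
  ch <- chol(solve(omega))
  v <- t(matrix(rnorm(n * p), n, p) %*% ch)
  if (is.null(ids)) ids <- sprintf("f%02d", seq_len(p))
  dimnames(v) <- list(ids, sprintf("S%04d", seq_len(n)))
  v
}

# 3-variable chain precision matrix: 1-2 and 2-3 are direct, 1-3 is
# conditionally independent (partial correlation exactly 0.4 on each edge).
chain_omega <- function(rho = 0.4) {
  matrix(c(1, -rho, 0, -rho, 1, -rho, 0, -rho, 1), 3, 3)
}

# Count how many of the top-n global pairs are true direct edges.
precision_at <- function(a, edges, n) {
  e <- top_n_edges(a, n)
  sum(paste(e$mirna, e$mrna) %in% paste(edges$mirna, edges$mrna))
}

# Write an expression TSV fixture and return its path.
write_tsv_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
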