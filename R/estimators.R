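# Direct-association estimators operating on an integrated, standardized
# expression set.  Each returns a `score_matrix`: a symmetric feature-by-
# feature association-weight matrix tagged with its role (observed vs direct)
# and estimator metadata.

#' Construct a score matrix
#'
#' Internal container for a symmetric feature-by-feature association matrix.
#'
#' @param values Symmetric numeric matrix with feature dimnames.
#' @param kind Named per-feature kind vector (as in [expr_set]).
#' @param role `"observed"` (raw pairwise association) or `"direct"`
#'   (conditional/deconvolved association).
#' @param estimator Estimator label.
#' @param meta Named list of estimator-specific metadata (shrinkage intensity,
#'   penalty, scaling factor, ...).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, kind, role = c("observed", "direct"),
                         estimator = "unknown", meta = list()) {
  role <- match.arg(role)
  check_symmetric(values, tol = 1e-10, what = "score matrix")
  if (is.null(rownames(values))) {
    stop("score matrix needs feature dimnames", call. = FALSE)
  }
  kind <- kind[rownames(values)]
  structure(list(values = values, kind = kind, role = role,
                 estimator = estimator, meta = meta),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Score matrix (%s, role=%s): %d x %d features\n",
              x$estimator, x$role, nrow(x$values), ncol(x$values)))
  if (length(x$meta)) {
    keys <- vapply(x$meta, function(v)
      paste(format(v, digits = 4), collapse = ","), character(1))
    cat("  ", paste(names(x$meta), keys, sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
as_values <- function(x) {
  if (inherits(x, "expr_set")) x$values else x
}

#' Pearson correlation matrix
#'
#' Plain pairwise Pearson correlation; the conventional observed-association
#' baseline against which the direct estimators are compared. Off-diagonal
#' entries mix direct and transitively induced (indirect) correlation.
#'
#' @param x An [expr_set] with at least 3 samples.
#' @return A `score_matrix` with role `"observed"`, unit diagonal.
#' @export
pearson_matrix <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  if (n_samples(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(x$values, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant features: ",
         paste(feature_ids(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(x$values))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  score_matrix(r, x$kind, role = "observed", estimator = "pearson")
}

# Schafer-Strimmer estimate of the off-diagonal shrinkage intensity:
# lambda* = sum_{i!=j} Var-hat(r_ij) / sum_{i!=j} r_ij^2, clamped to [0, 1],
# with Var-hat(r_ij) = n/(n-1)^3 * sum_s (w_sij - w-bar_ij)^2 and
# w_sij = z_is * z_js on row-standardized data.
#' @keywords internal
#' @noRd
estimate_shrinkage_intensity <- function(z, r) {
  n <- ncol(z)
  wbar <- tcrossprod(z) / n                  # mean_s w_sij
  sw2 <- tcrossprod(z * z)                   # sum_s w_sij^2
  vr <- n / (n - 1)^3 * (sw2 - n * wbar^2)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(vr[off]) / denom))
}

#' Shrinkage partial correlation matrix
#'
#' Estimates the full partial-correlation matrix through a Schafer-Strimmer
#' shrinkage of the empirical correlation matrix: off-diagonal correlations
#' are pulled toward zero with a data-driven intensity
#' \eqn{\lambda = \min(1, \sum \widehat{Var}(r_{ij}) / \sum r_{ij}^2)}, the
#' shrunk matrix is inverted, and the concentration matrix \eqn{\Omega} is
#' scaled to partial correlations
#' \eqn{p_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}. Shrinkage keeps
#' the matrix invertible in the many-features/few-samples regime.
#'
#' @param x An [expr_set] with at least 3 samples and 2 features.
#' @param lambda `"auto"` (estimate the intensity from the data) or a fixed
#'   value in `[0, 1]`. `lambda = 0` is the plain inverse-correlation partial
#'   correlation and can fail when samples do not outnumber features.
#' @return A `score_matrix` with role `"direct"`, unit diagonal, entries in
#'   `[-1, 1]`; the applied intensity is in `$meta$lambda`.
#' @export
shrinkage_partial_correlation <- function(x, lambda = "auto") {
  stopifnot(inherits(x, "expr_set"))
  n <- n_samples(x)
  p <- n_features(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (p < 2L) stop("need at least 2 features", call. = FALSE)
  z <- x$values
  z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)
  r <- tcrossprod(z) / (n - 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (identical(lambda, "auto")) {
    lambda <- estimate_shrinkage_intensity(z, r)
  } else {
    if (!is_scalar_number(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be 'auto' or a number in [0, 1]", call. = FALSE)
    }
  }
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- tryCatch(solve(rs), error = function(e) {
    stop("shrunk correlation matrix is numerically singular (lambda = ",
         format(lambda, digits = 4),
         "); use lambda = 'auto' for a positive-definite estimate",
         call. = FALSE)
  })
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  pc <- (pc + t(pc)) / 2
  diag(pc) <- 1
  pc[pc > 1] <- 1
  pc[pc < -1] <- -1
  md_log(sprintf("shrinkage partial correlation: lambda = %.4f", lambda))
  score_matrix(pc, x$kind, role = "direct", estimator = "shrinkage",
               meta = list(lambda = lambda))
}

#' Mutual information matrix
#'
#' Pairwise mutual information in nats by equal-frequency discretization into
#' `bins` bins per feature and the plug-in estimator
#' \eqn{\sum_{ab} \hat p(a,b) \log(\hat p(a,b) / (\hat p(a)\hat p(b)))}.
#' The diagonal is fixed to 0 (self-information carries no pairwise signal).
#'
#' @param x An [expr_set].
#' @param bins `"auto"` (\eqn{\lfloor\sqrt{n}\rfloor}, at least 2) or an
#'   integer number of bins, at most the number of samples.
#' @return A `score_matrix` with role `"observed"`, non-negative entries,
#'   zero diagonal; bin count in `$meta$bins`.
#' @export
mutual_information_matrix <- function(x, bins = "auto") {
  stopifnot(inherits(x, "expr_set"))
  n <- n_samples(x)
  if (identical(bins, "auto")) {
    bins <- max(2L, floor(sqrt(n)))
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be at least 2", call. = FALSE)
  if (bins > n) {
    stop(sprintf("bins (%d) exceeds the sample count (%d)", bins, n),
         call. = FALSE)
  }
  p <- n_features(x)
  # Equal-frequency bins from within-feature ranks; ties split deterministically.
  disc <- t(apply(x$values, 1, function(v)
    ceiling(rank(v, ties.method = "first") * bins / n)))
  mi <- matrix(0, p, p, dimnames = list(feature_ids(x), feature_ids(x)))
  logn <- log(n)
  marg <- lapply(seq_len(p), function(i) tabulate(disc[i, ], bins))
  for (i in seq_len(p - 1L)) {
    di <- disc[i, ]
    lmi <- log(marg[[i]])
    for (j in (i + 1L):p) {
      joint <- tabulate((di - 1L) * bins + disc[j, ], bins * bins)
      nz <- joint > 0L
      ab <- which(nz) - 1L
      a <- ab %/% bins + 1L
      b <- ab %% bins + 1L
      cnt <- joint[nz]
      mi[i, j] <- sum(cnt * (log(cnt) + logn - lmi[a] - log(marg[[j]][b]))) / n
    }
  }
  mi <- mi + t(mi)
  mi[mi < 0] <- 0  # plug-in MI is non-negative up to rounding
  diag(mi) <- 0
  score_matrix(mi, x$kind, role = "observed", estimator = "mutual_information",
               meta = list(bins = bins))
}

#' Network deconvolution
#'
#' Removes transitively induced association from an observed network under
#' the closed-form model in which observed weights are the sum of direct
#' weights plus all products along indirect paths,
#' \eqn{G_{obs} = G_{dir} + G_{dir}^2 + G_{dir}^3 + \cdots
#'   = G_{dir}(I - G_{dir})^{-1}}, inverted as
#' \eqn{G_{dir} = G_{obs}(I + G_{obs})^{-1}}. The inversion is applied on the
#' eigenvalues: the observed matrix is eigendecomposed and each eigenvalue is
#' mapped \eqn{\lambda \to \lambda/(1+\lambda)}.
#'
#' Because the map diverges at \eqn{\lambda = -1}, the input is first scaled
#' by \eqn{\beta > 0} so its spectral radius is at most `delta` (< 1), which
#' guarantees invertibility and convergence of the path-sum series. Scaling
#' preserves the ranking of direct weights. Set `rescale = FALSE` to apply
#' the exact inverse formula (e.g. when the input is known to satisfy the
#' spectral condition already).
#'
#' @param g_obs A `score_matrix` (or symmetric matrix) of observed weights.
#' @param delta Spectral-radius bound used when rescaling, in (0, 1).
#' @param rescale Scale the input down to spectral radius `delta` when it
#'   exceeds it. Default `TRUE`.
#' @param zero_diag Zero the diagonal before and after deconvolution
#'   (self-association carries no signal and distorts the spectrum). Default
#'   `TRUE`; disable when inverting an exactly composed observed matrix.
#' @return A `score_matrix` with role `"direct"`; the applied scaling factor
#'   is in `$meta$beta`.
#' @export
network_deconvolution <- function(g_obs, delta = 0.9, rescale = TRUE,
                                  zero_diag = TRUE) {
  if (inherits(g_obs, "score_matrix")) {
    vals <- g_obs$values
    kind <- g_obs$kind
  } else {
    vals <- g_obs
    kind <- stats::setNames(rep(MRNA, nrow(vals)), rownames(vals))
  }
  if (!is_scalar_number(delta) || delta <= 0 || delta >= 1) {
    stop("delta must lie strictly between 0 and 1", call. = FALSE)
  }
  check_symmetric(vals, tol = 1e-8, what = "observed network")
  vals <- (vals + t(vals)) / 2
  if (zero_diag) diag(vals) <- 0
  eig <- eigen(vals, symmetric = TRUE)
  rad <- max(abs(eig$values))
  beta <- 1
  if (rad == 0) {
    out <- vals  # zero network is a fixed point
  } else {
    if (rescale && rad > delta) beta <- delta / rad
    lam <- beta * eig$values
    if (any(lam <= -1)) {
      stop("eigenvalue <= -1: the direct-network map diverges; ",
           "enable rescaling", call. = FALSE)
    }
    out <- eig$vectors %*% (lam / (1 + lam) * t(eig$vectors))
    out <- (out + t(out)) / 2
    dimnames(out) <- dimnames(vals)
  }
  if (zero_diag) diag(out) <- 0
  score_matrix(out, kind, role = "direct", estimator = "network_deconvolution",
               meta = list(beta = beta, delta = delta, rescaled = beta != 1))
}

#' Mutual-information-based network deconvolution (MIND)
#'
#' Builds the observed association network from pairwise mutual information
#' and deconvolves it to suppress transitively induced association:
#' [mutual_information_matrix()] followed by [network_deconvolution()].
#'
#' @inheritParams mutual_information_matrix
#' @inheritParams network_deconvolution
#' @return A `score_matrix` with role `"direct"`.
#' @export
mind <- function(x, bins = "auto", delta = 0.9) {
  g <- mutual_information_matrix(x, bins = bins)
  out <- network_deconvolution(g, delta = delta, rescale = TRUE,
                               zero_diag = TRUE)
  out$estimator <- "mind"
  out$meta$bins <- g$meta$bins
  out
}

#' Write a score matrix with a JSON metadata sidecar
#'
#' The matrix is written as TSV with feature ids in the header row and first
#' column; `<path>.json` records the estimator, role and metadata.
#'
#' @param s A `score_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(s, path) {
  stopifnot(inherits(s, "score_matrix"))
  df <- data.frame(feature = rownames(s$values), s$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(estimator = s$estimator, role = s$role, meta = s$meta,
         features = rownames(s$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
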