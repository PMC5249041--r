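# The central model-fitting interface: estimate bootstrap-aggregated direct
# association networks per estimator and their rank-product ensemble, and
# return one classed object carrying everything downstream steps need.

#' Fit direct miRNA-mRNA association networks
#'
#' End-to-end estimator: integrates matched miRNA and mRNA expression
#' profiles over shared samples, standardizes features, runs each selected
#' direct-association estimator under bootstrap resampling (or once on the
#' whole data), and combines the per-estimator networks into a rank-product
#' ensemble. The result is a fitted-model object with `print`, `summary`,
#' `coef` and `plot` methods; edge lists come from [top_n_edges()] /
#' [top_k_per_mirna()] on `coef()`'s source via [scores()].
#'
#' @param mirna,mrna [expr_set] objects (or a single pre-integrated
#'   [expr_set] passed as `mirna` with `mrna = NULL`).
#' @param estimators Subset of `"shrinkage"` (alias `"corpcor"`), `"space"`,
#'   `"mind"`, `"pearson"`.
#' @param bootstrap A [bootstrap_config()], or `NULL` to fit each estimator
#'   once on the whole data.
#' @param ensemble Combine the selected estimators' networks by
#'   [ensemble_aggregate()]; needs at least two estimators (otherwise skipped
#'   with a warning).
#' @param standardize Z-score features before estimation (default `TRUE`).
#' @param estimator_args Named list of per-estimator argument lists, e.g.
#'   `list(space = list(lambda = 50))`.
#' @param signed Rank signed instead of absolute weights (see [to_ranks()]).
#' @return An object of class `mirdirect`.
#' @examples
#' d <- simulate_expression(synthetic_spec(n_mirna = 3, n_mrna = 8,
#'                                         n_edges = 5, n_samples = 60))
#' fit <- mirdirect(d$expression, bootstrap = NULL,
#'                  estimators = c("shrinkage", "mind"))
#' fit
#' head(top_n_edges(scores(fit), 5))
#' @export
mirdirect <- function(mirna, mrna = NULL,
                      estimators = c("shrinkage", "space", "mind"),
                      bootstrap = bootstrap_config(),
                      ensemble = TRUE, standardize = TRUE,
                      estimator_args = list(), signed = FALSE) {
  cl <- match.call()
  if (is.null(mrna)) {
    x <- mirna
    stopifnot(inherits(x, "expr_set"))
  } else {
    x <- integrate_expression(mirna, mrna)
  }
  if (length(mirna_ids(x)) == 0L || length(mrna_ids(x)) == 0L) {
    stop("integrated data must contain both miRNA and mRNA features",
         call. = FALSE)
  }
  if (standardize) x <- standardize_expression(x)
  estimators <- unique(vapply(estimators, resolve_estimator, character(1)))
  if (length(estimators) == 0L) stop("no estimators selected", call. = FALSE)

  mir <- mirna_ids(x)
  mr <- mrna_ids(x)
  nets <- vector("list", length(estimators))
  names(nets) <- estimators
  for (est in estimators) {
    args <- estimator_args[[est]] %||% list()
    nets[[est]] <- if (is.null(bootstrap)) {
      s <- run_estimator(x, est, args)
      out <- inverse_rank_product(list(to_ranks(s, mir, mr, signed = signed)))
      out$meta <- list(estimator = est, iterations = 0L, signed = signed)
      out
    } else {
      bootstrap_estimate(x, est, bootstrap, estimator_args = args,
                         signed = signed)
    }
    md_log("finished estimator ", est)
  }

  ens <- NULL
  if (ensemble) {
    if (length(nets) < 2L) {
      warning("ensemble aggregation needs at least 2 estimators; skipped",
              call. = FALSE)
    } else {
      ens <- ensemble_aggregate(nets, signed = signed)
    }
  }

  structure(list(scores = nets, ensemble = ens, estimators = estimators,
                 bootstrap = bootstrap, mirna_ids = mir, mrna_ids = mr,
                 n_samples = n_samples(x), signed = signed, call = cl),
            class = "mirdirect")
}

#' Extract an aggregated network from a fit
#'
#' @param fit A `mirdirect` object.
#' @param method `"ensemble"` (default when available) or an estimator name.
#' @return An `aggregated_scores` object.
#' @export
scores <- function(fit, method = NULL) {
  stopifnot(inherits(fit, "mirdirect"))
  if (is.null(method)) {
    if (!is.null(fit$ensemble)) return(fit$ensemble)
    method <- fit$estimators[1]
  }
  if (identical(method, "ensemble")) {
    if (is.null(fit$ensemble)) stop("fit has no ensemble network",
                                    call. = FALSE)
    return(fit$ensemble)
  }
  method <- resolve_estimator(method)
  out <- fit$scores[[method]]
  if (is.null(out)) {
    stop("no such estimator in the fit: ", method, call. = FALSE)
  }
  out
}

#' @export
print.mirdirect <- function(x, ...) {
  cat("Direct miRNA-mRNA association network fit\n")
  cat(sprintf("  %d miRNA x %d mRNA (%d pairs), %d samples\n",
              length(x$mirna_ids), length(x$mrna_ids),
              length(x$mirna_ids) * length(x$mrna_ids), x$n_samples))
  cat("  estimators:", paste(x$estimators, collapse = ", "), "\n")
  if (is.null(x$bootstrap)) {
    cat("  whole-data fits (no bootstrap)\n")
  } else {
    cat(sprintf("  bootstrap: %d iterations at rate %.2f (seed %d)\n",
                x$bootstrap$iterations, x$bootstrap$rate, x$bootstrap$seed))
  }
  cat("  ensemble:", if (is.null(x$ensemble)) "none" else
    paste(x$estimators, collapse = " & "), "\n")
  invisible(x)
}

#' @export
summary.mirdirect <- function(object, n_top = 10L, ...) {
  nets <- object$scores
  if (!is.null(object$ensemble)) nets <- c(nets, list(ensemble = object$ensemble))
  tops <- lapply(nets, function(a) top_n_edges(a, min(n_top,
                                                      length(a$weights))))
  structure(list(fit = object, top_edges = tops, n_top = n_top),
            class = "summary.mirdirect")
}

#' @export
print.summary.mirdirect <- function(x, ...) {
  print(x$fit)
  for (nm in names(x$top_edges)) {
    cat(sprintf("\nTop %d edges (%s):\n", nrow(x$top_edges[[nm]]), nm))
    print(x$top_edges[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mirdirect <- function(object, method = NULL, ...) {
  scores(object, method = method)$weights
}

#' Weight-decay plot of a fitted network
#'
#' Plots aggregate weight against global bipartite rank for each estimator
#' and the ensemble, on a log-rank axis. A sharp initial decay indicates a
#' small set of dominant putative direct associations.
#'
#' @param x A `mirdirect` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mirdirect <- function(x, ...) {
  nets <- x$scores
  if (!is.null(x$ensemble)) nets <- c(nets, list(ensemble = x$ensemble))
  cols <- seq_along(nets)
  first <- TRUE
  for (i in seq_along(nets)) {
    w <- sort(as.vector(nets[[i]]$weights), decreasing = TRUE)
    if (first) {
      graphics::plot(seq_along(w), w, type = "l", col = cols[i], log = "x",
                     xlab = "global pair rank", ylab = "aggregate weight",
                     main = "Aggregate weight decay", ...)
      first <- FALSE
    } else {
      graphics::lines(seq_along(w), w, col = cols[i])
    }
  }
  graphics::legend("topright", legend = names(nets), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
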