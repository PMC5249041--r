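# Bootstrap resampling of expression samples and rank-based aggregation of
# the per-replicate networks.

#' Bootstrap configuration
#'
#' @param iterations Number of bootstrap replicates (default 100).
#' @param rate Fraction of samples drawn per replicate, in (0, 1]
#'   (default 0.95).
#' @param seed Integer seed; replicate `i` uses the derived stream
#'   `seed + i`, so replicates are independently reproducible.
#' @param replace Draw with replacement (default `TRUE`).
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(iterations = 100L, rate = 0.95, seed = 1L,
                             replace = TRUE) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("iterations must be a positive integer", call. = FALSE)
  }
  if (!is_scalar_number(rate) || rate <= 0 || rate > 1) {
    stop("rate must lie in (0, 1]", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(iterations = iterations, rate = rate, seed = seed,
                 replace = isTRUE(replace)),
            class = "bootstrap_config")
}

#' Resample the samples of an expression set
#'
#' Draws `ceiling(rate * n)` sample columns uniformly (with replacement by
#' default), deterministically from `(seed, iteration)`. Duplicated sample
#' ids are disambiguated with a `.k` suffix. A draw that produces a constant
#' feature row (which no correlation estimator can handle) is redrawn from a
#' shifted stream, up to 25 times.
#'
#' @param x An [expr_set].
#' @param cfg A [bootstrap_config()].
#' @param iteration Replicate index in `[1, cfg$iterations]`.
#' @return A resampled [expr_set].
#' @export
resample_expression <- function(x, cfg, iteration) {
  stopifnot(inherits(x, "expr_set"), inherits(cfg, "bootstrap_config"))
  iteration <- as.integer(iteration)
  if (is.na(iteration) || iteration < 1L || iteration > cfg$iterations) {
    stop("iteration must lie in [1, ", cfg$iterations, "]", call. = FALSE)
  }
  n <- n_samples(x)
  m <- ceiling(cfg$rate * n)
  max_retries <- 25L
  for (attempt in 0:max_retries) {
    # Retries shift the stream far beyond the replicate range so they can
    # never collide with another iteration's draw.
    idx <- with_seed(cfg$seed + iteration + attempt * 1000003L, {
      if (cfg$replace) {
        sample.int(n, m, replace = TRUE)
      } else {
        if (m == n) seq_len(n) else sample.int(n, m, replace = FALSE)
      }
    })
    vals <- x$values[, idx, drop = FALSE]
    rng <- matrixStats_range(vals)
    if (all(rng[, 2] > rng[, 1])) {
      ids <- colnames(x$values)[idx]
      dup <- ave(seq_along(ids), ids, FUN = seq_along)
      colnames(vals) <- ifelse(dup > 1L, paste0(ids, ".", dup), ids)
      return(expr_set(vals, unname(x$kind)))
    }
    md_log(sprintf("replicate %d draw produced a constant feature; redrawing",
                   iteration), level = "WARN")
  }
  stop("could not draw a replicate without constant features after ",
       max_retries, " retries", call. = FALSE)
}

# Row-wise min/max without extra dependencies.
#' @keywords internal
#' @noRd
matrixStats_range <- function(m) {
  cbind(apply(m, 1, min), apply(m, 1, max))
}

#' @keywords internal
#' @noRd
resolve_estimator <- function(estimator) {
  est <- match.arg(estimator,
                   c("shrinkage", "corpcor", "space", "mind", "pearson"))
  if (est == "corpcor") est <- "shrinkage"  # historical alias
  est
}

#' @keywords internal
#' @noRd
run_estimator <- function(x, estimator, args = list()) {
  fn <- switch(estimator,
               shrinkage = shrinkage_partial_correlation,
               space = space_partial_correlation,
               mind = mind,
               pearson = pearson_matrix)
  do.call(fn, c(list(x), args))
}

#' Bootstrap-aggregated network estimate
#'
#' Re-estimates the association network on each bootstrap replicate of the
#' samples, converts every replicate network to bipartite ranks, and
#' aggregates the rank matrices by the inverse rank product. Rank-based
#' aggregation (rather than weight averaging) makes replicates with
#' incomparable weight scales combinable and yields a variance-reduced
#' consensus ordering. Fully deterministic given the configuration seed.
#'
#' @param x An integrated, standardized [expr_set].
#' @param estimator One of `"shrinkage"` (alias `"corpcor"`), `"space"`,
#'   `"mind"`, `"pearson"`.
#' @param cfg A [bootstrap_config()].
#' @param estimator_args Named list of extra arguments for the estimator.
#' @param signed Passed to [to_ranks()].
#' @return An `aggregated_scores` object; `$meta` records the estimator,
#'   the configuration and the number of failed replicates (failed
#'   replicates are skipped with a warning; all failing is an error).
#' @export
bootstrap_estimate <- function(x, estimator, cfg = bootstrap_config(),
                               estimator_args = list(), signed = FALSE) {
  stopifnot(inherits(x, "expr_set"), inherits(cfg, "bootstrap_config"))
  estimator <- resolve_estimator(estimator)
  mir <- mirna_ids(x)
  mr <- mrna_ids(x)
  if (length(mir) == 0L || length(mr) == 0L) {
    stop("the expression set must contain both miRNA and mRNA features",
         call. = FALSE)
  }
  ranks <- vector("list", cfg$iterations)
  failures <- 0L
  for (i in seq_len(cfg$iterations)) {
    ranks[[i]] <- tryCatch({
      rep_x <- resample_expression(x, cfg, i)
      s <- run_estimator(rep_x, estimator, estimator_args)
      to_ranks(s, mirna_ids = mir, mrna_ids = mr, signed = signed)
    }, error = function(e) {
      warning(sprintf("bootstrap replicate %d (%s) failed: %s",
                      i, estimator, conditionMessage(e)), call. = FALSE)
      NULL
    })
    md_log(sprintf("bootstrap %s replicate %d/%d done", estimator, i,
                   cfg$iterations))
  }
  ranks <- Filter(Negate(is.null), ranks)
  failures <- cfg$iterations - length(ranks)
  if (length(ranks) == 0L) {
    stop("all ", cfg$iterations, " bootstrap replicates failed for ",
         estimator, call. = FALSE)
  }
  out <- inverse_rank_product(ranks)
  out$meta <- list(estimator = estimator, iterations = cfg$iterations,
                   rate = cfg$rate, seed = cfg$seed, replace = cfg$replace,
                   failed_replicates = failures, signed = signed)
  out
}
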