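# Rank-based ensemble aggregation.
#
# Networks are compared on the bipartite miRNA x mRNA block only: each
# network's weights are converted to ranks (1 = strongest), and a set of
# networks is combined by the inverse-rank-product rule
#   w'_ij = 1 / log( prod_m (r^m_ij + 1) ),
# computed as 1 / sum_m log(r^m_ij + 1) so large products never overflow.
# Because ranks are distribution-free, networks from different estimators
# (whose weight scales are incomparable) can be combined directly.

#' Convert a score matrix to bipartite ranks
#'
#' Extracts the miRNA-by-mRNA block and ranks its entries by descending
#' association strength (rank 1 = strongest). By default strength is the
#' absolute weight, so strong negative correlations (the expected sign for
#' miRNA-mediated repression) rank at the top; with `signed = TRUE` the most
#' negative weight ranks first instead. Ties receive the average of the
#' positions they cover, so exact zeros from a sparse estimator share the
#' worst average rank.
#'
#' @param s A `score_matrix`.
#' @param mirna_ids,mrna_ids Row/column id sets of the bipartite block;
#'   default to the ids tagged miRNA/mRNA in the score matrix.
#' @param signed Rank most-negative first instead of largest magnitude first.
#' @return Numeric miRNA-by-mRNA matrix of ranks: a permutation of
#'   `1..(#miRNA * #mRNA)` up to average-rank ties.
#' @export
to_ranks <- function(s, mirna_ids = NULL, mrna_ids = NULL, signed = FALSE) {
  stopifnot(inherits(s, "score_matrix"))
  if (is.null(mirna_ids)) mirna_ids <- names(s$kind)[s$kind == MIRNA]
  if (is.null(mrna_ids)) mrna_ids <- names(s$kind)[s$kind == MRNA]
  if (length(mirna_ids) == 0L || length(mrna_ids) == 0L) {
    stop("both id sets must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(mirna_ids, mrna_ids), rownames(s$values))
  if (length(missing)) {
    stop("ids absent from the score matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  block <- s$values[mirna_ids, mrna_ids, drop = FALSE]
  key <- if (signed) block else -abs(block)
  rk <- matrix(rank(key, ties.method = "average"),
               nrow = length(mirna_ids),
               dimnames = list(mirna_ids, mrna_ids))
  rk
}

#' Aggregate rank matrices by the inverse rank product
#'
#' Combines any number of networks over the same miRNA-mRNA pairs into one
#' weight per pair, \eqn{w'_{ij} = 1/\log\prod_m (r^m_{ij} + 1)} (natural
#' log). Higher weight means a stronger aggregate association; a pair ranked
#' 1 everywhere attains the maximum \eqn{1/(m\log 2)}. The product makes the
#' rule commutative, so the result is invariant to the order of networks.
#'
#' @param ranks List of rank matrices from [to_ranks()] over identical
#'   miRNA/mRNA id sets.
#' @return An `aggregated_scores` object: `$weights` (miRNA-by-mRNA positive
#'   matrix) and `$source_count`.
#' @export
inverse_rank_product <- function(ranks) {
  if (!is.list(ranks) || length(ranks) < 1L) {
    stop("need a non-empty list of rank matrices", call. = FALSE)
  }
  ref <- dimnames(ranks[[1]])
  for (i in seq_along(ranks)) {
    r <- ranks[[i]]
    if (!is.matrix(r)) stop("input ", i, " is not a matrix", call. = FALSE)
    dn <- dimnames(r)
    if (!identical(dn, ref)) {
      diff <- c(setdiff(unlist(dn), unlist(ref)),
                setdiff(unlist(ref), unlist(dn)))
      stop("input ", i, " indexes different pairs than input 1",
           if (length(diff)) paste0(" (differing ids: ",
                                    paste(utils::head(diff, 5), collapse = ", "),
                                    ")"),
           call. = FALSE)
    }
    if (any(r < 1)) stop("ranks must be >= 1", call. = FALSE)
  }
  # Sum each pair's log addends in sorted order so the result is
  # bit-identical under any permutation of the input networks (floating-point
  # addition is not associative).
  logs <- vapply(ranks, function(r) log(as.vector(r) + 1),
                 numeric(length(ranks[[1]])))
  logs <- matrix(logs, nrow = length(ranks[[1]]))
  log_prod <- apply(logs, 1, function(v) sum(sort(v)))
  weights <- matrix(1 / log_prod, nrow = nrow(ranks[[1]]), dimnames = ref)
  aggregated_scores(weights, source_count = length(ranks))
}

#' @rdname inverse_rank_product
#' @param weights Positive miRNA-by-mRNA weight matrix.
#' @param source_count Number of networks aggregated.
#' @param meta Optional metadata list.
#' @export
aggregated_scores <- function(weights, source_count = 1L, meta = list()) {
  stopifnot(is.matrix(weights), all(is.finite(weights)), all(weights > 0))
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("aggregated weights need miRNA row names and mRNA column names",
         call. = FALSE)
  }
  structure(list(weights = weights, source_count = as.integer(source_count),
                 meta = meta),
            class = "aggregated_scores")
}

#' @export
print.aggregated_scores <- function(x, ...) {
  cat(sprintf("Aggregated scores: %d miRNA x %d mRNA pairs from %d network(s)\n",
              nrow(x$weights), ncol(x$weights), x$source_count))
  invisible(x)
}

# Rank any supported network representation over the bipartite block.
#' @keywords internal
#' @noRd
network_to_ranks <- function(net, mirna_ids = NULL, mrna_ids = NULL,
                             signed = FALSE) {
  if (inherits(net, "score_matrix")) {
    to_ranks(net, mirna_ids = mirna_ids, mrna_ids = mrna_ids, signed = signed)
  } else if (inherits(net, "aggregated_scores")) {
    w <- net$weights
    if (!is.null(mirna_ids)) w <- w[mirna_ids, , drop = FALSE]
    if (!is.null(mrna_ids)) w <- w[, mrna_ids, drop = FALSE]
    # aggregate weights are positive with higher = stronger
    matrix(rank(-w, ties.method = "average"), nrow = nrow(w),
           dimnames = dimnames(w))
  } else {
    stop("unsupported network type: ", paste(class(net), collapse = "/"),
         call. = FALSE)
  }
}

#' Ensemble aggregation of inferred networks
#'
#' Integrates networks produced by different estimators (score matrices
#' and/or bootstrap aggregates) into a single consensus network: each input
#' is first re-ranked over the bipartite block, then the rank matrices are
#' combined by [inverse_rank_product()]. Selecting input subsets yields the
#' pairwise and three-way method combinations.
#'
#' @param networks List (length >= 2) of `score_matrix` and/or
#'   `aggregated_scores` objects over the same miRNA/mRNA pairs.
#' @param mirna_ids,mrna_ids Optional explicit bipartite id sets.
#' @param signed Passed to [to_ranks()] for score-matrix inputs.
#' @return An `aggregated_scores` object.
#' @export
ensemble_aggregate <- function(networks, mirna_ids = NULL, mrna_ids = NULL,
                               signed = FALSE) {
  if (!is.list(networks) || length(networks) < 2L) {
    stop("ensemble aggregation needs at least 2 networks", call. = FALSE)
  }
  ranks <- lapply(networks, network_to_ranks, mirna_ids = mirna_ids,
                  mrna_ids = mrna_ids, signed = signed)
  out <- inverse_rank_product(ranks)
  out$meta$sources <- vapply(networks, function(n)
    if (inherits(n, "score_matrix")) n$estimator else
      (n$meta$estimator %||% "aggregate"), character(1))
  out
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write aggregated scores with a JSON metadata sidecar
#'
#' @param a An `aggregated_scores` object.
#' @param path Output TSV path (miRNA rows, mRNA columns).
#' @return `path`, invisibly.
#' @export
write_aggregated_scores <- function(a, path) {
  stopifnot(inherits(a, "aggregated_scores"))
  df <- data.frame(mirna = rownames(a$weights), a$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(source_count = a$source_count, meta = a$meta,
         mirnas = rownames(a$weights), mrnas = colnames(a$weights)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read aggregated scores written by [write_aggregated_scores()]
#'
#' @param path TSV path.
#' @return An `aggregated_scores` object.
#' @export
read_aggregated_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  meta_path <- paste0(path, ".json")
  src <- 1L
  meta <- list()
  if (file.exists(meta_path)) {
    info <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    src <- info$source_count %||% 1L
    meta <- as.list(info$meta %||% list())
  }
  aggregated_scores(w, source_count = src, meta = meta)
}
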