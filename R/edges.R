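# Edge extraction and Cytoscape-compatible export.

#' Extract the top-n global miRNA-mRNA edges
#'
#' Returns the `n` highest-weight bipartite pairs in descending weight order
#' with consecutive global ranks. Weight ties are broken lexicographically by
#' (miRNA id, mRNA id) so repeated runs order identically; a tie crossing the
#' cutoff additionally raises a warning, since which tied pair is retained is
#' then a naming artifact.
#'
#' @param a An `aggregated_scores` object.
#' @param n Number of edges, at most the total pair count.
#' @return An `edge_list`: a data frame with columns `mirna`, `mrna`,
#'   `weight`, `rank`.
#' @export
top_n_edges <- function(a, n) {
  stopifnot(inherits(a, "aggregated_scores"))
  total <- length(a$weights)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (n > total) {
    stop(sprintf("n = %d exceeds the number of pairs (%d)", n, total),
         call. = FALSE)
  }
  df <- data.frame(
    mirna = rep(rownames(a$weights), times = ncol(a$weights)),
    mrna = rep(colnames(a$weights), each = nrow(a$weights)),
    weight = as.vector(a$weights),
    stringsAsFactors = FALSE)
  ord <- order(-df$weight, df$mirna, df$mrna)
  df <- df[ord, , drop = FALSE]
  if (n < total && df$weight[n] == df$weight[n + 1L]) {
    warning("weight tie crosses the top-", n,
            " cutoff; tied pairs kept in lexicographic id order",
            call. = FALSE)
  }
  out <- df[seq_len(n), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Top-k mRNAs per miRNA
#'
#' For each miRNA, its `k` strongest mRNA partners by aggregate weight,
#' ordered best-first (lexicographic mRNA id on ties). This is the unit the
#' ground-truth overlap evaluation consumes.
#'
#' @param a An `aggregated_scores` object.
#' @param k Targets per miRNA, at most the number of mRNAs.
#' @return Named list: miRNA id -> ordered character vector of `k` mRNA ids.
#' @export
top_k_per_mirna <- function(a, k) {
  stopifnot(inherits(a, "aggregated_scores"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (k > ncol(a$weights)) {
    stop(sprintf("k = %d exceeds the number of mRNAs (%d)", k,
                 ncol(a$weights)), call. = FALSE)
  }
  mr <- colnames(a$weights)
  out <- apply(a$weights, 1, function(w) {
    mr[order(-w, mr)][seq_len(k)]
  }, simplify = FALSE)
  out
}

#' Export an edge list for Cytoscape
#'
#' `"tsv"` writes `mirna<TAB>mrna<TAB>weight<TAB>rank` with a header;
#' `"sif"` writes Cytoscape simple-interaction lines
#' `mirna associates mrna`.
#'
#' @param e An `edge_list` from [top_n_edges()].
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_edges <- function(e, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(e))
  if (nrow(e) == 0L) {
    warning("exporting an empty edge list", call. = FALSE)
  }
  if (format == "tsv") {
    utils::write.table(
      e[, c("mirna", "mrna", "weight", "rank"), drop = FALSE],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(if (nrow(e)) paste(e$mirna, "associates", e$mrna) else
      character(0), path)
  }
  invisible(path)
}

#' Read an edge list written in SIF format
#'
#' @param path SIF file path.
#' @return Data frame with columns `mirna`, `mrna`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(mirna = character(0), mrna = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "[ \t]+")
  data.frame(mirna = vapply(parts, `[[`, character(1), 1L),
             mrna = vapply(parts, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}
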