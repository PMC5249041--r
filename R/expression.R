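# Expression-profile containers and IO.
#
# An expression set holds a features-by-samples numeric matrix together with a
# per-feature kind label ("mirna" or "mrna").  All downstream estimators
# operate on a single integrated, standardized expression set in which the
# miRNA rows come first.

MIRNA <- "mirna"
MRNA <- "mrna"

#' Construct an expression set
#'
#' Bundles a features-by-samples numeric matrix with per-feature kind labels
#' (miRNA or mRNA) and validates the container invariants: unique feature and
#' sample identifiers, fully finite values, and one kind label per row.
#'
#' @param values Numeric matrix, features in rows and samples in columns, with
#'   row and column names set.
#' @param kind Character vector of length `nrow(values)` with entries
#'   `"mirna"` or `"mrna"`.
#' @return An object of class `expr_set` with elements `values` and `kind`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("miR-1", "miR-2", "miR-3"), paste0("S", 1:4)))
#' x <- expr_set(m, rep("mirna", 3))
#' n_features(x)
#' @export
expr_set <- function(values, kind) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  kind <- as.character(kind)
  if (length(kind) != nrow(values)) {
    stop("kind must have one entry per feature row", call. = FALSE)
  }
  if (!all(kind %in% c(MIRNA, MRNA))) {
    stop("kind entries must be 'mirna' or 'mrna'", call. = FALSE)
  }
  names(kind) <- rownames(values)
  structure(list(values = values, kind = kind), class = "expr_set")
}

#' @rdname expr_set
#' @param x An `expr_set`.
#' @export
n_features <- function(x) nrow(x$values)

#' @rdname expr_set
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname expr_set
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expr_set
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_set
#' @export
mirna_ids <- function(x) rownames(x$values)[x$kind == MIRNA]

#' @rdname expr_set
#' @export
mrna_ids <- function(x) rownames(x$values)[x$kind == MRNA]

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("Expression set: %d features (%d miRNA, %d mRNA) x %d samples\n",
              n_features(x), length(mirna_ids(x)), length(mrna_ids(x)),
              n_samples(x)))
  invisible(x)
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects features in rows and samples in columns: the first row holds sample
#' identifiers, the first column feature identifiers, and the body is numeric.
#' Missing values are rejected by default; with `impute = TRUE` each missing
#' cell is replaced by its feature's mean over the observed samples.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param kind Feature kind for every row: `"mirna"` or `"mrna"`.
#' @param impute Replace missing cells by the per-feature mean instead of
#'   failing. Default `FALSE`.
#' @return An [expr_set].
#' @export
read_expression <- function(path, kind = c("mirna", "mrna"), impute = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("malformed expression file (need a header line and at least one ",
         "feature row): ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # Header may or may not carry a leading cell for the feature-id column.
  body_len <- lengths(fields[-1])
  if (length(unique(body_len)) != 1L) {
    bad <- which(body_len != body_len[1])[1] + 1L
    stop(sprintf("malformed expression file: line %d has %d fields, expected %d",
                 bad, body_len[bad - 1L], body_len[1]), call. = FALSE)
  }
  n_col <- body_len[1] - 1L
  samples <- if (length(header) == body_len[1]) header[-1] else header
  if (length(samples) != n_col) {
    stop(sprintf(paste0("malformed expression file: header has %d sample ids ",
                        "but rows have %d value fields"),
                 length(samples), n_col), call. = FALSE)
  }
  feats <- vapply(fields[-1], `[[`, character(1), 1L)
  vals <- matrix(NA_real_, length(feats), n_col,
                 dimnames = list(feats, samples))
  for (i in seq_along(feats)) {
    raw <- fields[[i + 1L]][-1L]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(toupper(raw) %in% c("NA", "NAN", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at line %d (feature '%s', sample '%s')",
                   raw[bad[1]], i + 1L, feats[i], samples[bad[1]]),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  if (anyNA(vals)) {
    if (!impute) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("missing value at feature '%s', sample '%s' ",
                          "(set impute = TRUE to mean-impute)"),
                   feats[bad[1]], samples[bad[2]]), call. = FALSE)
    }
    for (i in which(rowSums(is.na(vals)) > 0)) {
      mu <- mean(vals[i, ], na.rm = TRUE)
      if (!is.finite(mu)) {
        stop("feature '", feats[i], "' has no observed values to impute from",
             call. = FALSE)
      }
      vals[i, is.na(vals[i, ])] <- mu
    }
    md_log(sprintf("imputed %d missing cells by feature means",
                   sum(rowSums(is.na(vals)))))
  }
  expr_set(vals, rep(kind, length(feats)))
}

#' Write an expression set as tab-separated text
#'
#' Inverse of [read_expression()]: feature ids in the first column, sample ids
#' in the header. Values are written with full precision so a read/write/read
#' cycle is lossless for finite decimal inputs.
#'
#' @param x An [expr_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_set"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature", sample_ids(x)), collapse = "\t"), con)
  body <- apply(x$values, 1, function(v)
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(feature_ids(x), body, sep = "\t"), con)
  invisible(path)
}

#' Integrate matched miRNA and mRNA expression sets
#'
#' Row-stacks the two profiles over their shared samples, miRNA features
#' first, with sample columns aligned to a single order (the miRNA set's
#' order restricted to the intersection). Feature identifiers must be
#' disjoint across the two kinds; a collision aborts, since silently renaming
#' features would corrupt later ground-truth matching.
#'
#' @param mirna,mrna [expr_set] objects with an overlapping sample set.
#' @return An integrated [expr_set].
#' @export
integrate_expression <- function(mirna, mrna) {
  stopifnot(inherits(mirna, "expr_set"), inherits(mrna, "expr_set"))
  shared <- intersect(sample_ids(mirna), sample_ids(mrna))
  if (length(shared) == 0L) {
    stop("the miRNA and mRNA profiles share no sample ids", call. = FALSE)
  }
  clash <- intersect(feature_ids(mirna), feature_ids(mrna))
  if (length(clash)) {
    stop("feature ids present in both the miRNA and mRNA profiles: ",
         paste(utils::head(clash, 5), collapse = ", "),
         if (length(clash) > 5) ", ..." else "", call. = FALSE)
  }
  ord <- sample_ids(mirna)[sample_ids(mirna) %in% shared]
  vals <- rbind(mirna$values[, ord, drop = FALSE],
                mrna$values[, ord, drop = FALSE])
  expr_set(vals, c(unname(mirna$kind), unname(mrna$kind)))
}

#' Standardize an expression set feature-wise
#'
#' Z-scores each feature row over samples (mean 0, unit standard deviation
#' with the n - 1 denominator). Constant rows are rejected: their z-score is
#' undefined and a constant feature carries no association signal.
#'
#' @param x An [expr_set].
#' @return The standardized [expr_set]; applying the function twice gives the
#'   same result to within numerical tolerance.
#' @export
standardize_expression <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  mu <- rowMeans(x$values)
  sd <- apply(x$values, 1, stats::sd)
  flat <- which(sd == 0 | !is.finite(sd))
  if (length(flat)) {
    stop("constant feature rows cannot be standardized: ",
         paste(utils::head(feature_ids(x)[flat], 10), collapse = ", "),
         if (length(flat) > 10) ", ..." else "", call. = FALSE)
  }
  expr_set((x$values - mu) / sd, unname(x$kind))
}

#' Read a miRNA-to-target ground-truth table
#'
#' Parses a two-column tab-separated file of `miRNA<TAB>gene` pairs (for
#' example a union of validated-target databases) into a mapping from each
#' miRNA to its set of target genes. Duplicate pairs are collapsed.
#'
#' @param path Path to the pair list.
#' @param header Set `TRUE` if the first line is a column header. Default
#'   `FALSE`.
#' @return An object of class `ground_truth`: a named list mapping miRNA id
#'   to a character vector of target gene ids, with attributes `n_mirnas`,
#'   `n_genes` and `n_pairs`.
#' @export
read_ground_truth <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1]
  if (length(lines) == 0L) {
    warning("empty ground-truth file: ", path, call. = FALSE)
    return(ground_truth(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    stop(sprintf("ground-truth line %d has %d columns, expected 2",
                 bad + as.integer(header), nf[bad]), call. = FALSE)
  }
  mirna <- vapply(fields, `[[`, character(1), 1L)
  gene <- vapply(fields, `[[`, character(1), 2L)
  pairs <- split(gene, mirna)
  ground_truth(lapply(pairs, unique))
}

#' @rdname read_ground_truth
#' @param pairs Named list mapping miRNA id to a character vector of targets.
#' @export
ground_truth <- function(pairs) {
  stopifnot(is.list(pairs))
  pairs <- lapply(pairs, function(g) unique(as.character(g)))
  structure(pairs, class = "ground_truth",
            n_mirnas = length(pairs),
            n_genes = length(unique(unlist(pairs, use.names = FALSE))),
            n_pairs = sum(lengths(pairs)))
}

#' Look up the known targets of a miRNA
#'
#' @param truth A `ground_truth` object.
#' @param mirna A miRNA identifier.
#' @return Character vector of target gene ids; empty for an unknown miRNA.
#' @export
targets_of <- function(truth, mirna) {
  stopifnot(inherits(truth, "ground_truth"))
  g <- truth[[mirna]]
  if (is.null(g)) character(0) else g
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d pairs over %d miRNAs and %d genes\n",
              attr(x, "n_pairs"), attr(x, "n_mirnas"), attr(x, "n_genes")))
  invisible(x)
}

#' Write a ground-truth mapping as a two-column pair list
#'
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  mirna <- rep(names(truth), lengths(truth))
  gene <- unlist(truth, use.names = FALSE)
  writeLines(paste(mirna, gene, sep = "\t"), path)
  invisible(path)
}
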