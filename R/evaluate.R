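# Ground-truth overlap evaluation.
#
# The precision measure follows the validated-target benchmark convention:
# for each miRNA, count how many of its top-k predicted mRNAs appear among
# the miRNA's known targets, and report the per-miRNA counts and their sum.
# With the number of scored pairs fixed across methods, a higher overlap
# count is a higher precision.

#' Overlap of top-k predictions with ground truth
#'
#' @param predictions Named list miRNA id -> ordered mRNA id vector, e.g.
#'   from [top_k_per_mirna()]; every list must have length at most `k`.
#' @param truth A `ground_truth` object.
#' @param k The per-miRNA list length the predictions were cut at.
#' @param match_case_insensitive Case-fold identifiers before matching.
#'   Default `TRUE` (expression platforms and target databases differ in
#'   capitalization).
#' @param strip_arm_suffix Strip `-3p`/`-5p` arm suffixes from miRNA ids
#'   before matching. Default `FALSE`: arm-level resolution is kept unless
#'   the user opts into the looser match, because silent fuzzy matching
#'   inflates precision.
#' @return A `precision_report`: list with `total_overlap`, `per_mirna`
#'   (named integer vector), `k`, `evaluated_mirnas` (miRNAs with at least
#'   one ground-truth target), `unknown_mirnas` (predicted miRNAs absent
#'   from the truth, which contribute zero), and `total_overlap_known`
#'   (the total restricted to evaluated miRNAs; identical to `total_overlap`
#'   since unknown miRNAs contribute zero, reported for explicitness).
#' @export
overlap_precision <- function(predictions, truth, k,
                              match_case_insensitive = TRUE,
                              strip_arm_suffix = FALSE) {
  stopifnot(is.list(predictions), inherits(truth, "ground_truth"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (any(lengths(predictions) > k)) {
    stop("a prediction list is longer than k", call. = FALSE)
  }
  if (attr(truth, "n_pairs") == 0L) {
    warning("empty ground truth: all overlaps are zero", call. = FALSE)
  }
  norm_mirna <- function(ids) {
    if (match_case_insensitive) ids <- tolower(ids)
    if (strip_arm_suffix) ids <- sub("-[35]p$", "", ids)
    ids
  }
  norm_gene <- function(ids) {
    if (match_case_insensitive) toupper(ids) else ids
  }
  truth_map <- stats::setNames(lapply(truth, norm_gene),
                               norm_mirna(names(truth)))
  per <- integer(length(predictions))
  names(per) <- names(predictions)
  known <- logical(length(predictions))
  for (i in seq_along(predictions)) {
    key <- norm_mirna(names(predictions)[i])
    targets <- truth_map[[key]]
    known[i] <- !is.null(targets)
    per[i] <- if (known[i]) {
      sum(norm_gene(predictions[[i]]) %in% targets)
    } else 0L
  }
  structure(list(total_overlap = sum(per),
                 per_mirna = per,
                 k = k,
                 evaluated_mirnas = sum(known),
                 unknown_mirnas = names(predictions)[!known],
                 total_overlap_known = sum(per[known])),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Precision report: %d overlaps at k = %d over %d miRNAs (%d in truth)\n",
              x$total_overlap, x$k, length(x$per_mirna), x$evaluated_mirnas))
  if (length(x$unknown_mirnas)) {
    cat("  miRNAs absent from ground truth:",
        paste(utils::head(x$unknown_mirnas, 5), collapse = ", "),
        if (length(x$unknown_mirnas) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' Method comparison table
#'
#' Tabulates the total ground-truth overlap per method, identifies the best
#' method, and flags whether every ensemble entry beats the worst of its
#' constituent single methods (the "relief of the worst model" property of
#' rank-ensemble aggregation).
#'
#' @param reports Named list (method label -> `precision_report`), all
#'   computed at the same `k`. Ensemble labels are expected to join their
#'   constituent labels with `&` (e.g. `"corpcor&space&mind"`).
#' @return A data frame (`method`, `k`, `total_overlap`, `evaluated_mirnas`,
#'   `is_best`, `relieves_worst`) with attribute `best_method`.
#' @export
compare_methods <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    stop("reports must be a named list of methods", call. = FALSE)
  }
  ks <- vapply(reports, function(r) as.integer(r$k), integer(1))
  if (length(unique(ks)) != 1L) {
    stop("all reports must share the same k (got ",
         paste(unique(ks), collapse = ", "), ")", call. = FALSE)
  }
  totals <- vapply(reports, function(r) r$total_overlap, numeric(1))
  methods <- names(reports)
  relieves <- rep(NA, length(methods))
  for (i in seq_along(methods)) {
    parts <- strsplit(methods[i], "&", fixed = TRUE)[[1]]
    if (length(parts) >= 2L && all(parts %in% methods)) {
      relieves[i] <- totals[i] > min(totals[parts])
    }
  }
  df <- data.frame(method = methods,
                   k = unname(ks),
                   total_overlap = unname(totals),
                   evaluated_mirnas = vapply(reports, function(r)
                     r$evaluated_mirnas, integer(1)),
                   is_best = totals == max(totals),
                   relieves_worst = relieves,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "best_method") <- methods[which.max(totals)]
  df
}

#' Write a method comparison table as TSV
#'
#' @param comparison Output of [compare_methods()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
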