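# Internal helpers shared across the package.

#' @keywords internal
#' @noRd
soft_threshold <- function(z, lambda) {
  sign(z) * pmax(abs(z) - lambda, 0)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user simulations.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
md_log <- function(..., level = "INFO", verbose = getOption("mirdirect.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...)))
  }
  invisible(NULL)
}

#' @keywords internal
#' @noRd
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Symmetry check with an explicit tolerance on the maximum absolute
# discrepancy (stricter and more transparent than isSymmetric()'s relative
# all.equal test).
#' @keywords internal
#' @noRd
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    stop(sprintf("%s is not symmetric (max |m - t(m)| = %.3g > %.3g)",
                 what, dev, tol), call. = FALSE)
  }
  invisible(TRUE)
}
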