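#' DTW configuration
#'
#' Settings of the dynamic-time-warping distance used throughout the
#' package: absolute-difference local cost, symmetric step pattern with the
#' diagonal move weighted `step_weight_diag` (2 by default, the classic
#' symmetric pattern), optional Sakoe-Chiba window, and per-profile z-score
#' pre-scaling (DTW on raw scales is amplitude-dominated; scaled profiles
#' compare shape).
#'
#' @param step_weight_diag weight of the diagonal step (default 2).
#' @param window Sakoe-Chiba half-width in bins, or `NULL` for no window.
#' @param zscore z-score each profile across bins before computing
#'   distances at the matrix level (default `TRUE`).
#' @export
dtw_config <- function(step_weight_diag = 2, window = NULL, zscore = TRUE) {
  structure(list(step_weight_diag = step_weight_diag,
                 window = if (is.null(window)) -1L else as.integer(window),
                 zscore = isTRUE(zscore)),
            class = "dtw_config")
}

#' DTW distance between two profiles
#'
#' Classic dynamic-programming DTW cost under the configured step pattern;
#' symmetric in its arguments, zero iff the profiles are identical.
#' Profiles are used as given (apply any scaling beforehand; the
#' matrix-level helpers honour `config$zscore`).
#'
#' @param a,b finite numeric vectors.
#' @param config [dtw_config()].
#' @export
dtw_distance <- function(a, b, config = dtw_config()) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("profiles must be finite")
  .dtw_cost_cpp(as.numeric(a), as.numeric(b),
                config$step_weight_diag, config$window)
}

#' Pairwise DTW distance matrix between profile rows
#'
#' @param profiles numeric matrix (profiles in rows, bins in columns).
#' @param config [dtw_config()]; with `zscore = TRUE` each row is z-scored
#'   across bins first.
#' @return symmetric matrix of DTW distances with the input row names.
#' @export
dtw_profile_dist <- function(profiles, config = dtw_config()) {
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  x <- if (config$zscore) .row_zscore(profiles) else profiles
  d <- .dtw_pairwise_cpp(x, config$step_weight_diag, config$window)
  dimnames(d) <- list(rownames(profiles), rownames(profiles))
  d
}

## DTW distances between rows of two matrices (e.g. TFs x target genes).
.dtw_cross_dist <- function(x, y, config = dtw_config()) {
  if (config$zscore) {
    x <- .row_zscore(x); y <- .row_zscore(y)
  }
  d <- .dtw_cross_cpp(x, y, config$step_weight_diag, config$window)
  dimnames(d) <- list(rownames(x), rownames(y))
  d
}
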