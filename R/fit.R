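#' Fit a neutrophil maturation trajectory model
#'
#' End-to-end fit on a raw count matrix: quality-control filters, log1p
#' counts-per-10k normalization, pseudotime inference oriented by marker
#' genes, discretization into expression bins, spline association test,
#' and DTW/Ward/KGS partitioning of the selected maturation genes into
#' modules and of the bins into maturation phases.
#'
#' @param counts raw count matrix or [expression_set()] (genes x cells).
#' @param marker_up,marker_down rising (mmp9-like) and falling (lyz-like)
#'   orientation markers.
#' @param qc apply [filter_features()] / [filter_cells()] first
#'   (default `TRUE`).
#' @param min_cells,min_features,max_mito_frac QC thresholds.
#' @param n_bins trajectory bins (default 100).
#' @param knots interior spline knots of the association test (default 6).
#' @param top_n cap on selected maturation genes (default 1500).
#' @param k_max largest cluster count offered to KGS (default 10).
#' @param mode pseudotime mode, see [infer_pseudotime()].
#' @param exclude_regex gene-exclusion regexes, see [association_test()].
#' @return object of class `maturation_fit` with components `pseudotime`,
#'   `binned`, `association`, `modules`, `phases`, `module_phase_means`,
#'   `normalized`, and the call.
#' @seealso [infer_pseudotime()], [association_test()],
#'   [partition_genes()], [partition_phases()]
#' @export
fit_maturation_trajectory <- function(counts,
                                      marker_up = "mmp9.like",
                                      marker_down = "lyz.like",
                                      qc = TRUE, min_cells = 20,
                                      min_features = 500,
                                      max_mito_frac = 0.10,
                                      n_bins = 100, knots = 6,
                                      top_n = 1500, k_max = 10,
                                      mode = "principal_curve",
                                      exclude_regex = c("^rp[sl]", "^mt-",
                                                        "^hb[ba]")) {
  cl <- match.call()
  raw <- counts
  if (qc) {
    raw <- filter_features(raw, min_cells = min_cells)
    raw <- suppressWarnings(filter_cells(raw, min_features = min_features,
                                         max_mito_frac = max_mito_frac))
  }
  norm <- normalize_expression(raw, "log1p_cp10k")
  pt <- infer_pseudotime(norm, mode = mode,
                         orientation_marker_down = marker_down,
                         orientation_marker_up = marker_up)
  binned <- bin_trajectory(norm, pt, n_bins = n_bins)
  assoc <- association_test(norm, pt, knots = knots, counts = raw,
                            exclude_regex = exclude_regex, top_n = top_n)
  genes <- maturation_genes(assoc)
  modules <- partition_genes(binned, genes, k_max = k_max)
  phases <- partition_phases(binned, genes, k_max = k_max, pt = pt)
  mp <- summarize_modules(binned, modules, phases)
  structure(list(call = cl, pseudotime = pt, binned = binned,
                 association = assoc, modules = modules, phases = phases,
                 module_phase_means = mp, normalized = norm),
            class = "maturation_fit")
}

#' @export
print.maturation_fit <- function(x, ...) {
  cat("Neutrophil maturation trajectory fit\n")
  cat(sprintf("  cells: %d  bins: %d\n", nrow(x$pseudotime),
              x$binned$n_bins))
  cat(sprintf("  maturation genes: %d of %d tested\n",
              sum(x$association$selected), nrow(x$association)))
  cat(sprintf("  modules: %d (KGS)  phases: %d (KGS, contiguity %.2f)\n",
              x$modules$k, x$phases$g, x$phases$contiguity))
  invisible(x)
}

#' @export
summary.maturation_fit <- function(object, ...) {
  out <- list(
    n_cells = nrow(object$pseudotime),
    n_tested = nrow(object$association),
    n_selected = sum(object$association$selected),
    module_sizes = table(object$modules$assignment),
    phase_bins = table(object$phases$bin_phase),
    contiguity = object$phases$contiguity,
    kgs_modules = object$modules$kgs$k,
    kgs_phases = object$phases$kgs$k,
    module_phase_means = object$module_phase_means)
  class(out) <- "summary.maturation_fit"
  out
}

#' @export
print.summary.maturation_fit <- function(x, ...) {
  cat("Maturation trajectory summary\n")
  cat(sprintf("  %d cells; %d genes tested, %d selected\n",
              x$n_cells, x$n_tested, x$n_selected))
  cat("  module sizes:\n"); print(x$module_sizes)
  cat("  bins per phase:\n"); print(x$phase_bins)
  cat(sprintf("  phase contiguity: %.2f\n", x$contiguity))
  cat("  mean z-scored expression per module x phase:\n")
  print(round(x$module_phase_means, 2))
  invisible(x)
}

#' Plot module mean profiles along the trajectory
#'
#' Draws the mean z-scored binned profile of each gene module against the
#' bin index, with phase boundaries as vertical lines and low-quality bins
#' marked with a rug.
#'
#' @param x `maturation_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.maturation_fit <- function(x, ...) {
  z <- .row_zscore(x$binned$values[names(x$modules$assignment), ,
                                   drop = FALSE])
  mods <- sort(unique(x$modules$assignment))
  prof <- vapply(mods, function(m)
    colMeans(z[x$modules$assignment == m, , drop = FALSE]),
    numeric(ncol(z)))
  graphics::matplot(seq_len(nrow(prof)), prof, type = "l", lty = 1,
                    lwd = 2, col = seq_along(mods),
                    xlab = "trajectory bin",
                    ylab = "mean z-scored expression", ...)
  ph <- x$phases$bin_phase
  cuts <- which(ph[-1] != ph[-length(ph)]) + 0.5
  graphics::abline(v = cuts, lty = 3, col = "grey40")
  if (any(x$phases$low_quality))
    graphics::rug(which(x$phases$low_quality))
  graphics::legend("topright", legend = mods, col = seq_along(mods),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
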