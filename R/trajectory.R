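#' Infer a maturation pseudotime
#'
#' Orders cells along the first latent component of the normalized
#' expression matrix. Mode `component1` rescales the rank of each cell's
#' first-principal-component score to \[0, 1\] (cluster-free, mirrors using
#' the first embedding coordinate); mode `principal_curve` fits a
#' Hastie-Stuetzle principal curve in the top two components and uses
#' arc-length position. The trajectory is oriented with marker genes: it is
#' flipped so that `orientation_marker_up` increases along pseudotime
#' (Spearman rho > 0) and `orientation_marker_down` decreases; when the two
#' markers disagree the up marker wins and a warning is issued.
#'
#' @param expr normalized matrix or [expression_set()] (genes x cells).
#' @param mode `"component1"` (default) or `"principal_curve"`.
#' @param orientation_marker_down,orientation_marker_up gene ids of a
#'   decreasing (lyz-like) and an increasing (mmp9-like) maturation marker.
#' @return `data.frame(cell_id, pseudotime)` with pseudotime in \[0, 1\];
#'   attribute `orientation_marker_used` records which marker decided the
#'   orientation.
#' @export
infer_pseudotime <- function(expr, mode = c("component1", "principal_curve"),
                             orientation_marker_down = "lyz.like",
                             orientation_marker_up = "mmp9.like") {
  mode <- match.arg(mode)
  m <- .values(expr)
  for (g in c(orientation_marker_down, orientation_marker_up))
    if (!g %in% rownames(m)) stop("orientation marker not found: ", g)
  z <- .row_zscore(m)
  z <- z[rowSums(abs(z)) > 0, , drop = FALSE]
  if (nrow(z) < 2) stop("degenerate expression matrix")
  ndim <- min(2L, nrow(z), ncol(z))
  sv <- svd(t(z), nu = ndim, nv = 0)
  if (sv$d[1] < sqrt(.Machine$double.eps))
    stop("degenerate first component (zero variance)")
  pc <- sv$u %*% diag(sv$d[seq_len(ndim)], ndim)
  lambda <- if (mode == "component1") pc[, 1] else .principal_curve_lambda(pc)
  pt <- (rank(lambda, ties.method = "average") - 1) / (ncol(m) - 1)

  rho_up <- stats::cor(m[orientation_marker_up, ], pt, method = "spearman")
  rho_dn <- stats::cor(m[orientation_marker_down, ], pt, method = "spearman")
  used <- orientation_marker_up
  if (rho_up < 0) pt <- 1 - pt
  ## recheck the down marker after orienting by the up marker
  rho_dn2 <- if (rho_up < 0) -rho_dn else rho_dn
  if (rho_dn2 > 0) {
    warning("orientation markers disagree; keeping the orientation of '",
            orientation_marker_up, "'")
  } else if (rho_up == 0) {
    used <- orientation_marker_down
    if (rho_dn > 0) pt <- 1 - pt
  }
  out <- data.frame(cell_id = colnames(m), pseudotime = pt)
  attr(out, "orientation_marker_used") <- used
  out
}

## Minimal Hastie-Stuetzle principal-curve arc-length in the top
## components: iterate (smooth each coordinate against the current
## ordering, recompute arc-length positions by projection onto the
## polyline). Entirely deterministic (ties in the projection break toward
## the earlier vertex).
.principal_curve_lambda <- function(pc, iter = 15, df = 6) {
  n <- nrow(pc)
  keep <- unique(round(seq(1, n, length.out = min(n, 800L))))
  run <- function(lambda0) {
    lambda <- lambda0
    sse <- Inf
    for (it in seq_len(iter)) {
      ord <- order(lambda)
      lam_s <- seq_along(ord)
      f <- vapply(seq_len(ncol(pc)), function(j)
        stats::smooth.spline(lam_s, pc[ord, j], df = df)$y,
        numeric(n))
      seg <- sqrt(rowSums(diff(f)^2))
      arc <- c(0, cumsum(seg))
      ## project every point to the nearest of a thinned set of curve
      ## vertices (the curve is smooth; thinning changes positions by less
      ## than a bin); ties break toward the earlier vertex
      d2 <- Reduce(`+`, lapply(seq_len(ncol(pc)), function(j)
        outer(pc[, j], f[keep, j], "-")^2))
      nearest <- apply(d2, 1, which.min)
      sse <- sum(d2[cbind(seq_len(n), nearest)])
      lambda_new <- arc[keep][nearest]
      if (isTRUE(all.equal(lambda_new, lambda))) break
      lambda <- lambda_new
    }
    list(lambda = lambda, sse = sse)
  }
  ## deterministic multi-start: the first component's ordering and, to
  ## unroll arched embeddings, the angular ordering around the centroid
  ang <- atan2(pc[, 2] - mean(pc[, 2]), pc[, 1] - mean(pc[, 1]))
  fits <- list(run(rank(pc[, 1], ties.method = "first")),
               run(rank(ang, ties.method = "first")))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]$lambda
}

#' Discretize a trajectory into expression bins
#'
#' Splits \[0, 1\] pseudotime into `n_bins` equal-width bins (bin b covers
#' `[(b-1)/n_bins, b/n_bins)`, last bin closed) and averages the normalized
#' expression of the cells in each bin. Empty bins are filled by linear
#' interpolation from neighbouring bins and flagged; bins with three or
#' fewer cells are flagged as low-quality but kept.
#'
#' @param expr normalized matrix or [expression_set()].
#' @param pt result of [infer_pseudotime()] or a named numeric vector of
#'   pseudotime values in \[0, 1\] covering every cell.
#' @param n_bins number of bins (default 100; must be at least 2).
#' @return object of class `binned_trajectory`: list with `values`
#'   (genes x bins), `bin_counts`, `low_quality` (logical, counts <= 3),
#'   `interpolated` (logical), `n_bins`.
#' @export
bin_trajectory <- function(expr, pt, n_bins = 100) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  m <- .values(expr)
  ptv <- .pt_vector(pt, colnames(m))
  idx <- .bin_index(ptv, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  vals <- matrix(NA_real_, nrow(m), n_bins,
                 dimnames = list(rownames(m), sprintf("bin%03d", 1:n_bins)))
  for (b in which(counts > 0))
    vals[, b] <- rowMeans(m[, idx == b, drop = FALSE])
  interpolated <- counts == 0
  if (any(interpolated)) {
    filled <- which(!interpolated)
    for (g in seq_len(nrow(vals)))
      vals[g, interpolated] <- stats::approx(filled, vals[g, filled],
                                             xout = which(interpolated),
                                             rule = 2)$y
  }
  structure(list(values = vals, bin_counts = counts,
                 low_quality = counts <= 3, interpolated = interpolated,
                 n_bins = n_bins),
            class = "binned_trajectory")
}

## bin b covers [(b-1)/n, b/n), last bin closed; the epsilon guards
## against pseudotime values sitting on a bin edge in floating point
.bin_index <- function(ptv, n_bins) {
  pmin(as.integer(floor(ptv * n_bins + 1e-9)) + 1L, n_bins)
}

.pt_vector <- function(pt, cell_ids) {
  v <- if (is.data.frame(pt)) stats::setNames(pt$pseudotime, pt$cell_id) else pt
  if (is.null(names(v))) {
    if (length(v) != length(cell_ids)) stop("pseudotime length mismatch")
    names(v) <- cell_ids
  }
  if (!all(cell_ids %in% names(v)))
    stop("pseudotime missing for some cells")
  v <- v[cell_ids]
  if (any(v < 0 | v > 1)) stop("pseudotime outside [0, 1]")
  v
}

#' @export
print.binned_trajectory <- function(x, ...) {
  cat(sprintf("binned_trajectory: %d genes x %d bins; %d low-quality bin(s), %d interpolated\n",
              nrow(x$values), x$n_bins, sum(x$low_quality),
              sum(x$interpolated)))
  invisible(x)
}

#' Test genes for association with pseudotime
#'
#' Fits, per gene, a cubic B-spline of normalized expression against
#' pseudotime (`knots` interior knots at pseudotime quantiles) and tests it
#' against the intercept-only model with an F-test; p-values are
#' Benjamini-Hochberg adjusted. Mitochondrial, ribosomal and
#' hemoglobin-related genes (configurable regexes) and genes with fewer
#' than 5 cells having 3 or more reads (when raw counts are supplied) are
#' excluded before testing. Genes with adjusted p below `alpha` are ranked
#' by descending statistic and the top `top_n` flagged as selected.
#'
#' @param expr normalized matrix or [expression_set()].
#' @param pt pseudotime as in [bin_trajectory()].
#' @param knots number of interior spline knots (default 6).
#' @param counts optional raw count matrix for the read-support exclusion.
#' @param exclude_regex case-insensitive regexes of gene ids to exclude
#'   before testing (default ribosomal, mitochondrial, hemoglobin).
#' @param alpha adjusted-p cutoff for selection (default 0.05).
#' @param top_n maximum number of selected genes (default 1500).
#' @return `data.frame(gene, statistic, p, padj, selected)` of class
#'   `association_result`; excluded genes are absent from the table and
#'   listed in attribute `excluded`.
#' @export
association_test <- function(expr, pt, knots = 6, counts = NULL,
                             exclude_regex = c("^rp[sl]", "^mt-", "^hb[ba]"),
                             alpha = 0.05, top_n = 1500) {
  m <- .values(expr)
  ptv <- .pt_vector(pt, colnames(m))
  excl <- rep(FALSE, nrow(m))
  for (rx in exclude_regex)
    excl <- excl | grepl(rx, tolower(rownames(m)))
  if (!is.null(counts)) {
    cm <- .values(counts)[rownames(m), colnames(m), drop = FALSE]
    excl <- excl | rowSums(cm >= 3) < 5
  }
  excluded <- rownames(m)[excl]
  if (length(excluded))
    .nt_log("association_test: excluded %d gene(s) before testing",
            length(excluded))
  m <- m[!excl, , drop = FALSE]

  kq <- stats::quantile(ptv, probs = seq_len(knots) / (knots + 1))
  B <- splines::bs(ptv, knots = kq, degree = 3,
                   Boundary.knots = range(ptv))
  df1 <- ncol(B)
  df2 <- ncol(m) - df1 - 1L
  if (df2 < 1) stop("fewer cells than spline degrees of freedom")
  fit <- stats::lm.fit(cbind(1, B), t(m))
  rss1 <- colSums(as.matrix(fit$residuals)^2)
  rss0 <- colSums(t(m - rowMeans(m))^2)
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  fstat[rss1 == 0] <- Inf
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(m), statistic = fstat, p = p,
                    padj = padj, row.names = NULL)
  res <- res[order(-res$statistic), ]
  row.names(res) <- NULL
  ## selected = the top_n significant genes in statistic order
  sel_idx <- which(res$padj < alpha)
  res$selected <- FALSE
  res$selected[sel_idx[seq_len(min(top_n, length(sel_idx)))]] <- TRUE
  attr(res, "excluded") <- excluded
  class(res) <- c("association_result", "data.frame")
  res
}

#' Genes selected by an association test
#' @param x `association_result`.
#' @return character vector of selected gene ids, in rank order.
#' @export
maturation_genes <- function(x) {
  stopifnot(inherits(x, "association_result"))
  x$gene[x$selected]
}
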