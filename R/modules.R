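#' Kelley-Gardner-Sutcliffe cluster-number selection
#'
#' For each candidate number of clusters k, cuts the dendrogram, computes
#' the average over clusters of size >= 2 of the mean within-cluster
#' pairwise distance (singletons contribute zero spread), min-max rescales
#' these averages over k to \[1, k_max - 1\], and adds k. The chosen k
#' minimizes the penalty; ties are broken toward the smaller k.
#'
#' @param linkage an [stats::hclust] tree (Ward.D2 over the same distances).
#' @param distance_matrix symmetric distance matrix the tree was built on.
#' @param k_max largest k to consider (must not exceed the item count).
#' @return object of class `kgs_curve`: list with `k` (chosen) and `curve`
#'   (`data.frame(k, spread, penalty)`).
#' @export
kgs_select <- function(linkage, distance_matrix, k_max) {
  n <- nrow(distance_matrix)
  if (k_max > n) stop("k_max exceeds item count")
  if (k_max < 2) stop("k_max must be at least 2")
  ks <- 2:k_max
  spread <- vapply(ks, function(k) {
    labels <- stats::cutree(linkage, k)
    per_cluster <- vapply(split(seq_len(n), labels), function(idx) {
      if (length(idx) < 2) return(NA_real_)
      mean(distance_matrix[idx, idx][lower.tri(matrix(0, length(idx),
                                                      length(idx)))])
    }, numeric(1))
    per_cluster <- per_cluster[!is.na(per_cluster)]
    if (!length(per_cluster)) 0 else mean(per_cluster)
  }, numeric(1))
  rng <- range(spread)
  rescaled <- if (diff(rng) == 0) rep(1, length(ks)) else
    1 + (spread - rng[1]) / diff(rng) * (k_max - 2)
  penalty <- rescaled + ks
  chosen <- ks[which.min(penalty)] # which.min takes the first (smallest k)
  structure(list(k = chosen,
                 curve = data.frame(k = ks, spread = spread,
                                    penalty = penalty)),
            class = "kgs_curve")
}

#' @export
print.kgs_curve <- function(x, ...) {
  cat(sprintf("kgs_curve: chosen k = %d (k in %d..%d)\n", x$k,
              min(x$curve$k), max(x$curve$k)))
  invisible(x)
}

## Centered moving average across bins (window w, edges passed through);
## reduces per-bin sampling noise before DTW so that warping acts on the
## profile shape rather than on bin-level fluctuations.
.smooth_rows <- function(m, w) {
  if (w <= 1) return(m)
  t(apply(m, 1, function(x) {
    y <- stats::filter(x, rep(1 / w, w), sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.numeric(y)
  }))
}

## Shared machinery: DTW distances + Ward.D2 + KGS cut over profile rows.
.dtw_ward_kgs <- function(profiles, k_max, config, k = NULL) {
  if (nrow(profiles) < 3) stop("need at least 3 profiles to partition")
  d <- dtw_profile_dist(profiles, config)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  kgs <- kgs_select(hc, d, min(k_max, nrow(profiles) - 1))
  if (is.null(k)) k <- kgs$k
  labels <- stats::cutree(hc, k)
  list(labels = labels, hclust = hc, kgs = kgs, dist = d)
}

#' Partition maturation genes into modules
#'
#' Clusters the binned profiles of the maturation genes with DTW distances,
#' Ward.D2 linkage and a KGS-selected number of clusters. Modules are
#' labelled M1..Mk in order of the pseudotime at which each module's mean
#' z-scored profile peaks (earliest peak = M1), so labels depend only on
#' the partition, not on the input gene order.
#'
#' @param binned [bin_trajectory()] result.
#' @param maturation_genes character vector of gene ids (subset of the
#'   binned rows), e.g. from [maturation_genes()].
#' @param k_max largest cluster count for KGS (default 10).
#' @param k optional fixed number of modules overriding the KGS choice.
#' @param config [dtw_config()].
#' @param smooth_window width (bins) of the moving average applied to the
#'   z-scored profiles before DTW (default 5); reduces bin-level sampling
#'   noise so distances reflect profile shape.
#' @return object of class `module_partition`: list with `assignment`
#'   (named character vector gene -> "M1".."Mk"), `k`, `kgs`, `hclust`.
#' @export
partition_genes <- function(binned, maturation_genes, k_max = 10, k = NULL,
                            config = dtw_config(), smooth_window = 5) {
  stopifnot(inherits(binned, "binned_trajectory"))
  missing <- setdiff(maturation_genes, rownames(binned$values))
  if (length(missing)) stop("genes not in binned trajectory: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  prof <- binned$values[maturation_genes, , drop = FALSE]
  sm <- .smooth_rows(.row_zscore(prof), smooth_window)
  rownames(sm) <- maturation_genes
  res <- .dtw_ward_kgs(sm, k_max, config, k)
  z <- .row_zscore(prof)
  peak <- vapply(split(seq_along(res$labels), res$labels), function(idx)
    which.max(colMeans(z[idx, , drop = FALSE])), numeric(1))
  new_label <- stats::setNames(paste0("M", rank(peak, ties.method = "first")),
                               names(peak))
  assignment <- stats::setNames(new_label[as.character(res$labels)],
                                maturation_genes)
  structure(list(assignment = assignment, k = length(peak),
                 kgs = res$kgs, hclust = res$hclust),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes in %d module(s)\n",
              length(x$assignment), x$k))
  print(table(x$assignment))
  invisible(x)
}

#' Partition trajectory bins (and cells) into maturation phases
#'
#' Clusters the bins — each bin a vector over the maturation genes (gene
#' profiles z-scored across bins and smoothed first) — with the same
#' DTW + Ward.D2 + KGS machinery used for genes. Before transposing, genes
#' are ordered by the peak position of their profile (the seriated-heatmap
#' order), so the gene axis that DTW warps along is a meaningful
#' early-to-late sequence rather than an arbitrary ordering (over an
#' arbitrary ordering unconstrained warping would compare value multisets
#' and lose the phase structure). By default the configuration uses a
#' narrow warping band (width 10): along a gene axis local warping only
#' serves to match genes of similar timing, and an unconstrained band
#' would let distant genes align and erase the phase structure. Phases
#' are labelled P1..Pg by mean
#' pseudotime (bin position). Contiguity along the bin axis is measured,
#' not enforced: the reported `contiguity` is the fraction of bins matching
#' the best contiguous relabelling (ordered segmentation maximizing
#' agreement). When pseudotime is supplied, cells inherit the phase of
#' their bin.
#'
#' @inheritParams partition_genes
#' @param pt optional pseudotime (as in [bin_trajectory()]) to map cells to
#'   phases.
#' @return object of class `phase_partition`: list with `bin_phase`
#'   (character vector over bins), `g` (number of phases), `contiguity`,
#'   `kgs`, `hclust`, optional `cell_phase`, and `low_quality` propagated
#'   from the binned trajectory.
#' @export
partition_phases <- function(binned, maturation_genes, k_max = 10, k = NULL,
                             config = dtw_config(window = 10), pt = NULL,
                             smooth_window = 5) {
  stopifnot(inherits(binned, "binned_trajectory"))
  prof <- binned$values[maturation_genes, , drop = FALSE]
  z <- .smooth_rows(.row_zscore(prof), smooth_window)
  z <- z[order(apply(z, 1, which.max)), , drop = FALSE] # early-to-late axis
  bins <- t(z) # bins in rows, ordered gene axis as the "series"
  cfg <- config
  cfg$zscore <- FALSE # gene axis already scaled; do not rescale bin vectors
  res <- .dtw_ward_kgs(bins, k_max, cfg, k)
  mean_pos <- vapply(split(seq_along(res$labels), res$labels), mean,
                     numeric(1))
  new_label <- stats::setNames(paste0("P", rank(mean_pos,
                                                ties.method = "first")),
                               names(mean_pos))
  bin_phase <- unname(new_label[as.character(res$labels)])
  g <- length(mean_pos)
  contiguity <- .best_contiguous_agreement(bin_phase, g)
  cell_phase <- NULL
  if (!is.null(pt)) {
    v <- if (is.data.frame(pt)) stats::setNames(pt$pseudotime, pt$cell_id)
         else pt
    idx <- .bin_index(v, binned$n_bins)
    cell_phase <- stats::setNames(bin_phase[idx], names(v))
  }
  structure(list(bin_phase = bin_phase, g = g, contiguity = contiguity,
                 kgs = res$kgs, hclust = res$hclust,
                 cell_phase = cell_phase,
                 low_quality = binned$low_quality),
            class = "phase_partition")
}

## Fraction of bins agreeing with the best ordered contiguous segmentation
## into g segments labelled P1..Pg (dynamic program over cut points).
.best_contiguous_agreement <- function(bin_phase, g) {
  n <- length(bin_phase)
  match_mat <- vapply(seq_len(g), function(p) bin_phase == paste0("P", p),
                      logical(n))
  cum <- rbind(0, apply(match_mat, 2, cumsum)) # (n+1) x g
  ## best[j, p]: max matches covering bins 1..j with segments 1..p
  best <- matrix(-Inf, n + 1, g)
  best[, 1] <- cum[, 1]
  for (p in 2:max(2, g)) {
    if (p > g) break
    run_best <- -Inf
    for (j in seq_len(n + 1)) {
      run_best <- max(run_best, best[j, p - 1] - cum[j, p])
      best[j, p] <- run_best + cum[j, p]
    }
  }
  if (g == 1) return(mean(match_mat[, 1]))
  best[n + 1, g] / n
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("phase_partition: %d bins in %d phase(s); contiguity %.2f\n",
              length(x$bin_phase), x$g, x$contiguity))
  print(table(x$bin_phase))
  invisible(x)
}

#' Mean z-scored expression per module and phase
#'
#' @param binned [bin_trajectory()] result.
#' @param gene_partition [partition_genes()] result.
#' @param phase_partition [partition_phases()] result.
#' @return numeric matrix, modules in rows, phases in columns.
#' @export
summarize_modules <- function(binned, gene_partition, phase_partition) {
  genes <- names(gene_partition$assignment)
  z <- .row_zscore(binned$values[genes, , drop = FALSE])
  mods <- sort(unique(gene_partition$assignment))
  phases <- sort(unique(phase_partition$bin_phase))
  out <- matrix(NA_real_, length(mods), length(phases),
                dimnames = list(mods, phases))
  for (m in mods) for (p in phases)
    out[m, p] <- mean(z[gene_partition$assignment == m,
                        phase_partition$bin_phase == p])
  out
}
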