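#' Single-sample gene set enrichment (ssGSEA)
#'
#' Rank-based running-sum enrichment of each signature in each sample.
#' Per sample, genes are ranked by expression (ties get the average rank);
#' walking down the ranking, the running sum steps up by
#' `|rank statistic|^alpha` (normalized over the set genes) at in-set genes
#' and down by `1/(N - |S|)` otherwise, and the score is the sum of the
#' running-sum values over all positions (the running-sum integral, not its
#' maximum). With `normalize = TRUE` all scores are divided by the global
#' score range. Scores depend on the ranks only, so they are invariant
#' under strictly monotone transforms of a sample's expression values.
#'
#' @param bulk_matrix normalized genes x samples matrix (e.g. log-CPM) or
#'   [expression_set()].
#' @param signatures [signature_set()] or named list of gene vectors; each
#'   must intersect the matrix genes.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize divide by the global score range (default `TRUE`).
#' @return samples x signatures score matrix (class `matrix`), with
#'   attributes `alpha` and `normalized`.
#' @export
ssgsea <- function(bulk_matrix, signatures, alpha = 0.25, normalize = TRUE) {
  m <- .values(bulk_matrix)
  N <- nrow(m)
  sets <- lapply(signatures, intersect, y = rownames(m))
  if (any(lengths(sets) == 0))
    stop("signature(s) with empty gene overlap: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  scores <- matrix(NA_real_, ncol(m), length(sets),
                   dimnames = list(colnames(m), names(sets)))
  for (j in seq_len(ncol(m))) {
    stat <- rank(m[, j], ties.method = "average") # highest expression -> N
    ord <- order(stat, decreasing = TRUE)
    w <- abs(stat[ord])^alpha
    for (k in seq_along(sets)) {
      inset <- rownames(m)[ord] %in% sets[[k]]
      up <- w * inset
      up <- up / sum(up)
      down <- (!inset) / (N - sum(inset))
      scores[j, k] <- sum(cumsum(up - down))
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- isTRUE(normalize)
  scores
}

#' Expression-matched per-cell module score
#'
#' Scores each cell as the mean normalized expression of the gene set
#' minus the mean expression of expression-matched control genes: all
#' genes are split into `n_bins` equal-frequency bins of average
#' expression, and each set gene draws `n_ctrl` control genes from its own
#' bin (with replacement when the bin is smaller). Deterministic given
#' `seed`.
#'
#' @param sc_expr normalized single-cell matrix or [expression_set()].
#' @param gene_set character vector of gene ids; genes absent from the
#'   matrix are dropped with a log message.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @param ctrl_genes optional fixed control pool overriding the matched
#'   draw (used e.g. for self-control checks).
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(sc_expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1, ctrl_genes = NULL) {
  m <- .values(sc_expr)
  set <- intersect(gene_set, rownames(m))
  if (length(set) < length(gene_set))
    .nt_log("module_score: %d set gene(s) absent, dropped",
            length(gene_set) - length(set))
  if (!length(set)) stop("no set gene present in the matrix")
  if (is.null(ctrl_genes)) {
    avg <- rowMeans(m)
    br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
    names(bin) <- rownames(m)
    ctrl_genes <- .with_seed(seed, {
      unlist(lapply(set, function(g) {
        pool <- names(bin)[bin == bin[g]]
        sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
      }))
    })
  }
  colMeans(m[set, , drop = FALSE]) -
    colMeans(m[ctrl_genes, , drop = FALSE])
}

#' Hypergeometric over-representation of a gene module
#'
#' Upper one-tailed hypergeometric test of the overlap between a module
#' and each set of a collection, with Benjamini-Hochberg FDR adjustment.
#' Sets disjoint from the background are skipped (logged).
#'
#' @param module_genes character vector (must be a subset of `background`).
#' @param gene_set_collection [signature_set()] or named list.
#' @param background character vector: the tested gene universe.
#' @param fdr_max report sets with FDR below this bound (default 0.1);
#'   the full table is returned with a `reported` flag.
#' @return `data.frame(set, set_size, overlap, overlap_ratio, p, fdr,
#'   reported)` sorted by FDR.
#' @export
hypergeom_enrichment <- function(module_genes, gene_set_collection,
                                 background, fdr_max = 0.1) {
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background")
  rows <- lapply(names(gene_set_collection), function(nm) {
    s <- intersect(gene_set_collection[[nm]], background)
    if (!length(s)) {
      .nt_log("hypergeom_enrichment: set '%s' disjoint from background, skipped", nm)
      return(NULL)
    }
    q <- length(intersect(module_genes, s))
    p <- stats::phyper(q - 1, length(s), length(background) - length(s),
                       length(module_genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = q,
               overlap_ratio = q / length(s), p = p)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no set overlaps the background")
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$fdr, tab$p), ]
  tab$reported <- tab$fdr < fdr_max
  rownames(tab) <- NULL
  tab
}

#' Mixing sensitivity of signature scores
#'
#' Builds pseudo-bulk samples by mixing neutrophil-stage and stromal cells
#' at defined ratios (sampling to a fixed cell total, several replicates),
#' normalizes them (log1p counts-per-million), scores them with [ssgsea()],
#' and reports the median score per (ratio, signature) over replicates.
#'
#' @inheritParams simulate_bulk_mixtures
#' @param signatures [signature_set()] or named list.
#' @param alpha,normalize passed to [ssgsea()].
#' @return list with `medians` (`data.frame(ratio, signature, median_score)`),
#'   `scores` (per-sample matrix) and `design`.
#' @export
mixing_sensitivity <- function(stage_cells, stromal_cells, signatures,
                               ratios = seq(0, 1, 0.1), total = 1000,
                               reps = 20, seed = 1, alpha = 0.25,
                               normalize = TRUE) {
  mix <- simulate_bulk_mixtures(stage_cells, stromal_cells, ratios,
                                total = total, reps = reps, seed = seed)
  cpm <- log1p(sweep(mix$counts, 2, colSums(mix$counts), "/") * 1e6)
  sc <- ssgsea(cpm, signatures, alpha = alpha, normalize = normalize)
  med <- do.call(rbind, lapply(colnames(sc), function(sig) {
    agg <- tapply(sc[mix$design$sample, sig], mix$design$ratio, stats::median)
    data.frame(ratio = as.numeric(names(agg)), signature = sig,
               median_score = as.numeric(agg))
  }))
  list(medians = med, scores = sc, design = mix$design)
}
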