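#' Scaled DTW similarity between transcription factors and target genes
#'
#' Computes the DTW distance `d[tf, gene]` between every TF profile and
#' every target-gene profile on the shared binned axis, then rescales per
#' target gene across TFs: `s = 1 - d / max_tf(d)`. Thus for every gene the
#' most distant TF scores exactly 0 and a TF scores 1 only when its profile
#' matches the gene's exactly. DTW's warping lets a TF that runs a few bins
#' ahead of its targets still score highly.
#'
#' @param tf_profiles matrix of TF profiles (TFs x bins); at least 2 TFs.
#' @param target_profiles matrix of target-gene profiles (genes x bins).
#' @param config [dtw_config()].
#' @return object of class `regulator_scores`: list with `similarity`
#'   (TF x gene matrix in \[0, 1\]) and `distance` (the raw DTW matrix).
#' @export
scaled_dtw_similarity <- function(tf_profiles, target_profiles,
                                  config = dtw_config()) {
  if (nrow(tf_profiles) < 2)
    stop("need at least 2 TFs (per-gene max distance is degenerate)")
  if (ncol(tf_profiles) != ncol(target_profiles))
    stop("TF and target profiles must share the binned axis")
  d <- .dtw_cross_dist(tf_profiles, target_profiles, config)
  dmax <- apply(d, 2, max)
  s <- 1 - sweep(d, 2, dmax, "/")
  if (any(dmax == 0)) {
    .nt_log("scaled_dtw_similarity: %d gene(s) identical to all TFs; similarity set to 1",
            sum(dmax == 0))
    s[, dmax == 0] <- 1
  }
  structure(list(similarity = s, distance = d), class = "regulator_scores")
}

#' Rank transcription factors as candidate module regulators
#'
#' For each TF, compares its similarity distribution across the gene
#' modules with a Kruskal-Wallis test followed by Dunn's pairwise post-hoc
#' test (computed from rank sums with tie correction) with Holm adjustment.
#' A TF is called a candidate regulator of the module in which its median
#' similarity is highest when all Dunn contrasts of that module against the
#' others are significant at `alpha`. TFs are ranked within each module by
#' median similarity.
#'
#' @param scores [scaled_dtw_similarity()] result.
#' @param module_partition [partition_genes()] result (or a named character
#'   vector gene -> module) covering every target gene.
#' @param alpha significance level for the Holm-adjusted Dunn contrasts
#'   (default 0.05).
#' @return list with `table` (one row per TF: best module, per-module
#'   medians, KW statistic and p, specificity call, rank within best
#'   module) and `by_module` (named list of candidate TFs in rank order).
#' @export
rank_regulators <- function(scores, module_partition, alpha = 0.05) {
  stopifnot(inherits(scores, "regulator_scores"))
  assign <- if (inherits(module_partition, "module_partition"))
    module_partition$assignment else module_partition
  s <- scores$similarity
  if (!all(colnames(s) %in% names(assign)))
    stop("every target gene needs a module label")
  mod <- factor(assign[colnames(s)])
  if (any(table(mod) < 2)) stop("module with fewer than 2 genes")
  mods <- levels(mod)

  rows <- lapply(rownames(s), function(tf) {
    x <- s[tf, ]
    med <- tapply(x, mod, stats::median)
    kw <- stats::kruskal.test(x, mod)
    best <- mods[which.max(med)]
    dunn <- .dunn_test(x, mod)
    contrasts <- dunn[dunn$a == best | dunn$b == best, , drop = FALSE]
    specific <- length(mods) > 1 && all(contrasts$p_holm < alpha)
    out <- data.frame(tf = tf, module = best,
                      kw_stat = unname(kw$statistic),
                      kw_p = kw$p.value, specific = specific,
                      median_similarity = unname(med[best]))
    for (m in mods) out[[paste0("median_", m)]] <- unname(med[m])
    out
  })
  tab <- do.call(rbind, rows)
  tab$rank_in_module <- NA_integer_
  by_module <- list()
  for (m in mods) {
    cand <- tab$tf[tab$module == m & tab$specific]
    cand <- cand[order(-tab$median_similarity[match(cand, tab$tf)])]
    by_module[[m]] <- cand
    tab$rank_in_module[match(cand, tab$tf)] <- seq_along(cand)
  }
  list(table = tab, by_module = by_module)
}

## Dunn's post-hoc z statistics from rank sums, with tie correction and
## Holm-adjusted two-sided p-values.
.dunn_test <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(levels(g), 2)
  z <- apply(combs, 2, function(ab) {
    (rbar[ab[1]] - rbar[ab[2]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[ab[1]] + 1 / n[ab[2]]))
  })
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(a = combs[1, ], b = combs[2, ], z = as.numeric(z),
             p = as.numeric(p),
             p_holm = stats::p.adjust(p, method = "holm"))
}

#' Load a transcription-factor list
#'
#' Reads a one-column (or first-column) TSV of TF gene ids, drops
#' duplicates, and intersects with the genes of an expression matrix;
#' missing TFs are logged.
#'
#' @param path TSV/;text file of gene ids (header optional, first column
#'   used).
#' @param genes character vector of available gene ids (e.g.
#'   `rownames(expr$values)`).
#' @return character vector of TF ids present in `genes`.
#' @export
load_tf_list <- function(path, genes) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(vapply(strsplit(lines, "\t"), `[`, "", 1))
  lines <- unique(lines[nzchar(lines)])
  if (!length(lines)) stop("empty TF list")
  keep <- intersect(lines, genes)
  if (length(keep) < length(lines))
    warning(length(lines) - length(keep), " TF(s) not in expression matrix")
  if (!length(keep)) stop("no TF from the list is present in the matrix")
  keep
}
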