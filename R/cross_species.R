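#' Aggregate samples or cells by maturation stage
#'
#' @param expr matrix or [expression_set()] (genes x cells/samples).
#' @param stage_labels character/factor vector, one label per column; no
#'   empty stage allowed.
#' @return genes x stages matrix of per-stage means, columns in the order
#'   of the factor levels (or first appearance).
#' @export
aggregate_stages <- function(expr, stage_labels) {
  m <- .values(expr)
  if (length(stage_labels) != ncol(m))
    stop("one stage label per column required")
  f <- if (is.factor(stage_labels)) droplevels(stage_labels)
       else factor(stage_labels, levels = unique(stage_labels))
  out <- vapply(levels(f), function(s)
    rowMeans(m[, f == s, drop = FALSE]), numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), levels(f))
  out
}

#' Rank-based quantile normalization
#'
#' Classic quantile normalization: rank genes within each column, average
#' the sorted values across columns at each rank position, and map each
#' value back through its column's original ranks (ties get the average
#' rank and are interpolated). Afterwards every column holds the identical
#' multiset of values.
#'
#' @param m numeric matrix without missing values.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (any(is.na(m))) stop("missing values not allowed")
  if (ncol(m) == 1) {
    .nt_log("quantile_normalize: single column, returning input")
    return(m)
  }
  n <- nrow(m)
  means <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(n), means, xout = r, rule = 2)$y
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Cluster maturation stages across datasets
#'
#' Scales each dataset's stage matrix per gene across its own stages,
#' joins common genes, clusters stages with Ward.D2 linkage on the Pearson
#' distance (1 - r over genes), assigns each stage a maturation score —
#' its rank position among its own dataset's stages rescaled to \[0, 1\]
#' (a single-stage dataset scores 0 by convention) — and reorders the
#' dendrogram leaves within the tree constraints by ascending mean score.
#'
#' @param stage_matrices named list of genes x stages matrices (one per
#'   dataset; columns are that dataset's ordered stages).
#' @return list with `hclust`, `dendrogram` (leaf-reordered), `order`
#'   (stage names in leaf order), `scores` (named per-stage maturation
#'   score) and `dataset` (named per-stage dataset id).
#' @export
cluster_stages <- function(stage_matrices) {
  stopifnot(is.list(stage_matrices), !is.null(names(stage_matrices)))
  ## a single-stage dataset cannot be scaled across its stages; its raw
  ## profile is used as-is
  scaled <- lapply(stage_matrices, function(m)
    if (ncol(m) < 2) m else t(scale(t(m))))
  common <- Reduce(intersect, lapply(scaled, rownames))
  joined <- do.call(cbind, lapply(scaled, function(m)
    m[common, , drop = FALSE]))
  const <- apply(joined, 1, function(x) any(!is.finite(x)))
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped before correlation")
    joined <- joined[!const, , drop = FALSE]
  }
  d <- 1 - stats::cor(joined)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  scores <- unlist(lapply(names(stage_matrices), function(ds) {
    k <- ncol(stage_matrices[[ds]])
    if (k == 1) {
      .nt_log("cluster_stages: dataset '%s' has one stage; score 0", ds)
      sc <- 0
    } else sc <- (seq_len(k) - 1) / (k - 1)
    stats::setNames(sc, colnames(stage_matrices[[ds]]))
  }))
  dataset <- unlist(lapply(names(stage_matrices), function(ds)
    stats::setNames(rep(ds, ncol(stage_matrices[[ds]])),
                    colnames(stage_matrices[[ds]]))))
  dend <- stats::reorder(stats::as.dendrogram(hc),
                         wts = scores[hc$labels], agglo.FUN = mean)
  list(hclust = hc, dendrogram = dend, order = labels(dend),
       scores = scores, dataset = dataset)
}

#' Collapse 1-to-many homology by detection rate
#'
#' Renames the genes of a dataset (rows named by `target_gene` ids) to
#' their reference (`source_gene`) ids. A source gene mapping to several
#' targets keeps the target with the highest detection rate; several
#' sources claiming the same target are resolved by keeping the pair with
#' the higher rate (others dropped, logged). Detection-rate ties break
#' lexicographically on the target id (logged). Genes without a mapping
#' pass through unchanged, so the operation never increases the gene count
#' and is idempotent.
#'
#' @param expr matrix or [expression_set()] with `target_gene` row ids.
#' @param map homology table as from [read_homology_map()].
#' @return object of the same kind with reference gene ids.
#' @export
collapse_homology <- function(expr, map) {
  m <- .values(expr)
  map <- map[map$target_gene %in% rownames(m), , drop = FALSE]
  ## resolve 1-to-many: per source keep the best-detected target
  map <- map[order(map$source_gene, -map$detection_rate, map$target_gene), ]
  tie <- duplicated(map[c("source_gene", "detection_rate")]) &
    !duplicated(map["source_gene"])
  if (any(tie[!duplicated(map$source_gene)]))
    .nt_log("collapse_homology: detection-rate tie(s) broken lexicographically")
  best <- map[!duplicated(map$source_gene), , drop = FALSE]
  ## resolve many-to-one collisions on the target side
  best <- best[order(best$target_gene, -best$detection_rate,
                     best$source_gene), ]
  dup_t <- duplicated(best$target_gene)
  if (any(dup_t))
    .nt_log("collapse_homology: dropped %d source gene(s) in many-to-one collisions",
            sum(dup_t))
  best <- best[!dup_t, , drop = FALSE]
  keep_unmapped <- setdiff(rownames(m), map$target_gene)
  out <- m[c(best$target_gene, keep_unmapped), , drop = FALSE]
  rownames(out) <- c(best$source_gene, keep_unmapped)
  if (anyDuplicated(rownames(out))) {
    dup <- duplicated(rownames(out))
    .nt_log("collapse_homology: dropped %d duplicate id(s) after renaming",
            sum(dup))
    out <- out[!dup, , drop = FALSE]
  }
  .rewrap(expr, out)
}

#' Cross-correlation alignment of two binned profiles
#'
#' Computes `r(k) = sum_t (x[t+k] - mean(x)) (y[t] - mean(y)) / (n sx sy)`
#' for lags `k` in `-max_lag..max_lag`, where `y` is the reference profile
#' and `x` the query, and returns the lag maximizing `r` (ties broken
#' toward the smallest |k|, then the negative lag) with its coefficient.
#' A positive lag means the query pattern occurs later than the reference.
#' The peak coefficient is reported as computed (negative peaks are not
#' clipped).
#'
#' @param ref_profile,query_profile equal-length numeric profiles; neither
#'   may have zero variance.
#' @param max_lag largest |lag| searched (default: full range, n - 1).
#' @return list with `lag` (integer) and `coefficient`.
#' @export
cross_correlate <- function(ref_profile, query_profile, max_lag = NULL) {
  y <- as.numeric(ref_profile); x <- as.numeric(query_profile)
  n <- length(y)
  if (length(x) != n) stop("profiles must have equal length")
  if (is.null(max_lag)) max_lag <- n - 1L
  sx <- sqrt(mean((x - mean(x))^2)); sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) stop("zero-variance profile")
  xc <- x - mean(x); yc <- y - mean(y)
  ks <- seq.int(-max_lag, max_lag)
  r <- vapply(ks, function(k) {
    t_idx <- seq_len(n)
    ok <- t_idx + k >= 1 & t_idx + k <= n
    sum(xc[t_idx[ok] + k] * yc[t_idx[ok]]) / (n * sx * sy)
  }, numeric(1))
  ord <- order(-r, abs(ks), ks)
  best <- ord[1]
  list(lag = ks[best], coefficient = r[best])
}

#' Per-gene cross-correlation lag table across datasets
#'
#' For every gene common to the reference and all query datasets, records
#' the best cross-correlation lag and peak coefficient per dataset (on
#' per-gene z-scored binned profiles), the mean lag per gene across
#' datasets, and the mean peak coefficient per (dataset, module). With
#' three or more datasets a Ward.D2 clustering of datasets on their
#' module-coefficient vectors is attached. Constant-profile genes are
#' dropped with a warning.
#'
#' @param ref_binned reference [bin_trajectory()] result (or genes x bins
#'   matrix).
#' @param dataset_binneds named list of query binned trajectories (or
#'   matrices) with reference gene ids (homology already collapsed).
#' @param modules named character vector or [partition_genes()] result
#'   giving each gene's module (genes without a label are reported with
#'   module `NA`).
#' @param max_lag largest |lag| searched (default 99).
#' @return object of class `lag_table`: list with `per_gene`
#'   (`data.frame(gene, dataset, lag, coefficient)`), `mean_lag` (named
#'   vector), `module_coefficient` (dataset x module matrix), optional
#'   `dataset_hclust`.
#' @export
build_lag_table <- function(ref_binned, dataset_binneds, modules = NULL,
                            max_lag = 99) {
  refm <- if (inherits(ref_binned, "binned_trajectory")) ref_binned$values
          else ref_binned
  mats <- lapply(dataset_binneds, function(b)
    if (inherits(b, "binned_trajectory")) b$values else b)
  genes <- Reduce(intersect, c(list(rownames(refm)), lapply(mats, rownames)))
  if (!length(genes)) stop("empty common gene set")
  zref <- .row_zscore(refm[genes, , drop = FALSE])
  zq <- lapply(mats, function(m) .row_zscore(m[genes, , drop = FALSE]))
  const <- rowSums(abs(zref)) == 0
  for (z in zq) const <- const | rowSums(abs(z)) == 0
  if (any(const)) {
    warning(sum(const), " constant gene profile(s) dropped")
    genes <- genes[!const]
  }
  assign <- if (inherits(modules, "module_partition")) modules$assignment
            else modules
  rows <- list()
  for (ds in names(zq)) {
    for (g in genes) {
      cc <- cross_correlate(zref[g, ], zq[[ds]][g, ], max_lag)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, dataset = ds, lag = cc$lag,
                   coefficient = cc$coefficient,
                   module = if (is.null(assign)) NA_character_
                            else unname(assign[g]))
    }
  }
  per_gene <- do.call(rbind, rows)
  mean_lag <- tapply(per_gene$lag, per_gene$gene, mean)
  mod_coef <- NULL
  if (!is.null(assign)) {
    sub <- per_gene[!is.na(per_gene$module), , drop = FALSE]
    if (nrow(sub)) {
      mod_coef <- tapply(sub$coefficient,
                         list(sub$dataset, sub$module), mean)
      mod_coef <- as.matrix(mod_coef)
    }
  }
  ds_hc <- NULL
  if (!is.null(mod_coef) && nrow(mod_coef) >= 3 &&
      !anyNA(mod_coef))
    ds_hc <- stats::hclust(stats::dist(mod_coef), method = "ward.D2")
  structure(list(per_gene = per_gene,
                 mean_lag = mean_lag[genes],
                 module_coefficient = mod_coef,
                 dataset_hclust = ds_hc, max_lag = max_lag),
            class = "lag_table")
}

#' @export
print.lag_table <- function(x, ...) {
  cat(sprintf("lag_table: %d gene(s) x %d dataset(s), max_lag %d\n",
              length(x$mean_lag), length(unique(x$per_gene$dataset)),
              x$max_lag))
  cat(sprintf("  mean |lag|: %.1f bins\n", mean(abs(x$mean_lag))))
  invisible(x)
}

#' Derive pan-species maturation signatures
#'
#' Per module, the pan-species set keeps the genes whose mean
#' cross-correlation lag across datasets is within `lag_threshold` bins in
#' absolute value (inclusive) and that are not on the blacklist of markers
#' of unrelated cell types. Signatures are named `<module>pan` and carry
#' per-gene provenance.
#'
#' @param lag_table [build_lag_table()] result.
#' @param module_partition [partition_genes()] result or named vector
#'   gene -> module.
#' @param blacklist character vector of gene ids to exclude.
#' @param lag_threshold inclusive bound on |mean lag| (default 50 bins).
#' @return [signature_set()] with provenance columns `gene`, `signature`,
#'   `module`, `mean_lag`, `blacklisted`.
#' @export
derive_pan_signature <- function(lag_table, module_partition,
                                 blacklist = character(),
                                 lag_threshold = 50) {
  stopifnot(inherits(lag_table, "lag_table"))
  assign <- if (inherits(module_partition, "module_partition"))
    module_partition$assignment else module_partition
  genes <- intersect(names(lag_table$mean_lag), names(assign))
  prov <- data.frame(gene = genes,
                     module = unname(assign[genes]),
                     mean_lag = unname(lag_table$mean_lag[genes]),
                     blacklisted = genes %in% blacklist)
  prov$included <- abs(prov$mean_lag) <= lag_threshold & !prov$blacklisted
  prov$signature <- ifelse(prov$included, paste0(prov$module, "pan"), NA)
  sets <- split(prov$gene[prov$included],
                paste0(prov$module[prov$included], "pan"))
  empty_mods <- setdiff(paste0(unique(assign[genes]), "pan"), names(sets))
  if (length(empty_mods))
    warning("empty pan signature(s): ", paste(empty_mods, collapse = ", "))
  if (!length(sets)) stop("all pan signatures are empty")
  signature_set(sets, provenance = prov)
}
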