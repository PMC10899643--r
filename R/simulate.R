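## Synthetic-data generators. These define the study conditions every
## recovery test runs under: smooth pseudotime-dependent gene programs in
## three modules over four phases, an increasing (mmp9-like) and a
## decreasing (lyz-like) reporter, transcription factors leading their
## target module, cross-species per-gene temporal shifts with 1-to-many
## orthology, stage-aggregated datasets, and bulk mixtures with stromal
## background. All generators are pure functions of (parameters, seed).

.shape_fun <- function(shape, center, width) {
  switch(shape,
    rise = function(t) stats::plogis((t - center) / width),
    fall = function(t) stats::plogis(-(t - center) / width),
    bump = function(t) exp(-(t - center)^2 / (2 * width^2)),
    ## transient program with a plateau: on from `center` to `center`+0.25
    pulse = function(t) stats::plogis((t - center) / width) *
      stats::plogis(-(t - center - 0.25) / width),
    ## two-step rise: 12% level after `center`, full level 0.25 later —
    ## a late program active through the last two phases at rising level
    rise2 = function(t) 0.12 * stats::plogis((t - center) / width) +
      0.88 * stats::plogis((t - center - 0.25) / width),
    stop("unknown shape: ", shape))
}

#' Default module design for the synthetic trajectory
#'
#' Three gene modules whose mean profiles differ in shape, not merely in
#' timing (dynamic time warping absorbs pure time shifts, so shape is what
#' separates modules): M1 — early program switching off (falling logistic),
#' M2 — transient intermediate program (plateaued pulse), M3 — late program
#' rising in two steps (half level at phase-3 onset, full level at phase-4
#' onset), so the late module is active through the last two phases at a
#' rising level. The implied phase structure is P1 = M1-high, P2 = M2-high,
#' P3 = M3 at half level, P4 = M3 at full level.
#'
#' @return `data.frame` with columns `module`, `shape`, `center`, `width`,
#'   `amplitude`, `n_genes`.
#' @export
default_module_spec <- function() {
  data.frame(
    module    = c("M1", "M2", "M3"),
    shape     = c("fall", "pulse", "rise2"),
    center    = c(0.25, 0.25, 0.50),
    width     = c(0.025, 0.025, 0.025),
    amplitude = c(8, 8, 8),
    n_genes   = c(55, 55, 70)
  )
}

## Phase windows implied by the default design.
.default_phase_breaks <- c(0.25, 0.50, 0.75)

#' Simulate a single-cell maturation trajectory with planted truth
#'
#' Draws cells uniformly along a latent maturation pseudotime in \[0, 1\] and
#' samples negative-binomial counts with mean
#' `depth_factor * (baseline + amplitude * shape(t))` per gene. Two reporter
#' genes are always included: `mmp9.like` (rising) and `lyz.like` (falling),
#' used downstream to orient the trajectory and to derive sorted-gate labels
#' (NO below the 30th percentile of the rising reporter, HI above the 70th,
#' INT between — a qualitative mirror of FACS gating). Optional transcription
#' factors lead their target module's mean profile by a fixed number of bins.
#'
#' @param n_cells number of cells (default 2000).
#' @param n_genes total genes including reporters and nulls (default 300).
#' @param module_spec design table as in [default_module_spec()].
#' @param noise list with `dispersion` (NB size, default 5), `depth_meanlog`
#'   (default 9) and `depth_sdlog` (default 0.3) for the lognormal per-cell
#'   depth factor.
#' @param tf_spec optional `data.frame(tf, module, lead_bins, amplitude)`;
#'   each TF's profile is its target module's mean profile evaluated at
#'   `t + lead_bins / n_bins` (i.e. the TF runs ahead of its targets).
#' @param n_bins bin resolution at which the noiseless truth profiles are
#'   tabulated (default 100).
#' @param reporter_amplitude amplitude of the two reporter genes
#'   (default 14; set 0 for a fully exchangeable null dataset).
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `expr` ([expression_set()] of raw counts with
#'   `sorted_gate` metadata) and `truth` (class `trajectory_truth`: per-cell
#'   true pseudotime, per-gene module/shape table, per-bin true phase,
#'   noiseless genes x bins profile matrix, and the noise settings).
#' @export
simulate_trajectory_dataset <- function(n_cells = 2000, n_genes = 300,
                                        module_spec = default_module_spec(),
                                        noise = list(dispersion = 5,
                                                     depth_meanlog = 9,
                                                     depth_sdlog = 0.3),
                                        tf_spec = NULL, n_bins = 100,
                                        reporter_amplitude = 14,
                                        seed = 1) {
  stopifnot(n_cells >= 2)
  if (any(module_spec$center < 0 | module_spec$center > 1))
    stop("module centers must lie in [0, 1]")
  if (noise$dispersion <= 0) stop("dispersion must be positive")
  n_module <- sum(module_spec$n_genes)
  n_null <- n_genes - n_module - 2L
  if (n_null < 0) stop("n_genes too small for the module design")

  .with_seed(seed, {
    t_cell <- stats::runif(n_cells)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    names(t_cell) <- cell_ids

    ## per-gene table: module rows, reporters, nulls, TFs
    rows <- list()
    for (r in seq_len(nrow(module_spec))) {
      sp <- module_spec[r, ]
      for (k in seq_len(sp$n_genes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("%s.w%d.g%02d", sp$module, r, k),
          module = sp$module, shape = sp$shape,
          center = sp$center + stats::rnorm(1, 0, 0.01),
          width = sp$width * stats::runif(1, 0.9, 1.1),
          amplitude = sp$amplitude * stats::runif(1, 0.7, 1.3),
          is_tf = FALSE, lead_bins = 0)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "mmp9.like", module = "none", shape = "rise",
      center = 0.55, width = 0.10, amplitude = reporter_amplitude,
      is_tf = FALSE,
      lead_bins = 0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "lyz.like", module = "none", shape = "fall",
      center = 0.45, width = 0.10, amplitude = reporter_amplitude,
      is_tf = FALSE,
      lead_bins = 0)
    if (n_null > 0) {
      for (k in seq_len(n_null)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("null.g%03d", k), module = "none", shape = "flat",
          center = NA_real_, width = NA_real_, amplitude = 0,
          is_tf = FALSE, lead_bins = 0)
      }
    }
    gene_tab <- do.call(rbind, rows)

    baseline <- 0.6
    ## mean profile of a module at pseudotime t (average over its waves)
    module_mean_shape <- function(mod) {
      sub <- module_spec[module_spec$module == mod, , drop = FALSE]
      funs <- Map(.shape_fun, sub$shape, sub$center, sub$width)
      function(t) Reduce(`+`, lapply(funs, function(f) f(t))) / nrow(sub)
    }
    if (!is.null(tf_spec)) {
      for (r in seq_len(nrow(tf_spec))) {
        tf <- tf_spec[r, ]
        gene_tab <- rbind(gene_tab, data.frame(
          gene = tf$tf, module = paste0("TF:", tf$module), shape = "tf",
          center = NA_real_, width = NA_real_,
          amplitude = if (is.null(tf$amplitude)) 8 else tf$amplitude,
          is_tf = TRUE, lead_bins = tf$lead_bins))
      }
    }

    ## noiseless relative-expression profile per gene over pseudotime t
    profile_at <- function(g, t) {
      row <- gene_tab[gene_tab$gene == g, ]
      if (row$shape == "flat") return(rep(baseline + 1, length(t)))
      if (row$is_tf) {
        mod <- sub("^TF:", "", row$module)
        f <- module_mean_shape(mod)
        tt <- pmin(pmax(t + row$lead_bins / n_bins, 0), 1)
        return(baseline + row$amplitude * f(tt))
      }
      f <- .shape_fun(row$shape, row$center, row$width)
      baseline + row$amplitude * f(t)
    }

    genes <- gene_tab$gene
    prof_cells <- vapply(genes, function(g) profile_at(g, t_cell),
                         numeric(n_cells))     # cells x genes
    depth <- stats::rlnorm(n_cells, noise$depth_meanlog, noise$depth_sdlog)
    depth_factor <- depth / exp(noise$depth_meanlog)
    mu <- t(prof_cells) * rep(depth_factor, each = length(genes))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = noise$dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, cell_ids))

    ## sorted-gate labels from the rising reporter
    rep_counts <- counts["mmp9.like", ]
    qs <- stats::quantile(rep_counts, c(0.3, 0.7))
    gate <- ifelse(rep_counts < qs[1], "NO",
                   ifelse(rep_counts > qs[2], "HI", "INT"))

    bin_centers <- (seq_len(n_bins) - 0.5) / n_bins
    profiles <- vapply(genes, function(g) profile_at(g, bin_centers),
                       numeric(n_bins))
    profiles <- t(profiles)                    # genes x bins
    phase_of_bin <- cut(bin_centers,
                        breaks = c(0, .default_phase_breaks, 1),
                        labels = paste0("P", 1:4), include.lowest = TRUE)

    meta <- data.frame(sorted_gate = gate, species = "synthetic",
                       dataset = "reference", row.names = cell_ids)
    truth <- structure(list(
      pseudotime = t_cell, gene_table = gene_tab,
      phase_breaks = .default_phase_breaks,
      bin_phase = as.character(phase_of_bin),
      profiles = profiles, n_bins = n_bins, baseline = baseline,
      noise = noise, module_spec = module_spec, seed = seed),
      class = "trajectory_truth")
    list(expr = expression_set(counts, meta), truth = truth)
  })
}

#' Simulate related species datasets with planted per-gene lags
#'
#' Each simulated dataset reproduces the reference design but evaluates each
#' gene's profile at `t - lag / n_bins` (clamped to \[0, 1\], i.e. edge-padded
#' rather than wrapped), so a positive lag makes the gene's pattern occur
#' later than in the reference. Genes are renamed to species-specific ids and
#' a homology table (source = reference id, target = species id, detection
#' rate = observed detection fraction) is emitted. Optional 1-to-many cases
#' add a weak paralog copy with a lower detection rate.
#'
#' @param truth `trajectory_truth` from [simulate_trajectory_dataset()].
#' @param lag_spec named list (one element per dataset) of integer lag
#'   vectors named by reference gene id; genes absent from a vector get lag 0.
#' @param n_cells cells per simulated dataset (default 1500).
#' @param paralog_genes reference gene ids that receive an extra low-rate
#'   paralog copy in every dataset (default none).
#' @param seed integer seed.
#' @return named list per dataset: `expr` (counts), `homology`
#'   (`data.frame(source_gene, target_gene, detection_rate)`), `lags`
#'   (named integer vector, reference ids), `pseudotime` (true, per cell).
#' @export
simulate_species_family <- function(truth, lag_spec, n_cells = 1500,
                                    paralog_genes = character(), seed = 1) {
  stopifnot(inherits(truth, "trajectory_truth"))
  n_bins <- truth$n_bins
  gt <- truth$gene_table[!truth$gene_table$is_tf, , drop = FALSE]
  out <- list()
  for (i in seq_along(lag_spec)) {
    ds <- names(lag_spec)[i]
    lags <- stats::setNames(rep(0L, nrow(gt)), gt$gene)
    given <- lag_spec[[i]]
    if (any(abs(given) >= n_bins)) stop("|lag| must be < n_bins")
    lags[names(given)] <- as.integer(given)
    sim <- .with_seed(seed + i, {
      t_cell <- stats::runif(n_cells)
      cell_ids <- sprintf("%s.cell%04d", ds, seq_len(n_cells))
      mu_of <- function(row, tt) {
        if (row$shape == "flat") return(rep(truth$baseline + 1, length(tt)))
        f <- .shape_fun(row$shape, row$center, row$width)
        truth$baseline + row$amplitude * f(tt)
      }
      depth <- stats::rlnorm(n_cells, truth$noise$depth_meanlog,
                             truth$noise$depth_sdlog)
      dfac <- depth / exp(truth$noise$depth_meanlog)
      build_counts <- function(rows, ids, lag_by_source) {
        mu <- vapply(seq_len(nrow(rows)), function(r) {
          tt <- pmin(pmax(t_cell - lag_by_source[r] / n_bins, 0), 1)
          mu_of(rows[r, ], tt) * dfac
        }, numeric(n_cells))
        m <- matrix(stats::rnbinom(length(mu), mu = t(mu),
                                   size = truth$noise$dispersion),
                    nrow = nrow(rows), dimnames = list(ids, cell_ids))
        m
      }
      main_ids <- paste0(ds, ":", gt$gene)
      counts <- build_counts(gt, main_ids, lags[gt$gene])
      hom <- data.frame(source_gene = gt$gene, target_gene = main_ids,
                        detection_rate = rowMeans(counts > 0))
      if (length(paralog_genes)) {
        pg <- gt[match(paralog_genes, gt$gene), , drop = FALSE]
        pg$amplitude <- pg$amplitude * 0.15
        par_ids <- paste0(ds, ":", pg$gene, ".b")
        pc <- build_counts(pg, par_ids, lags[pg$gene])
        ## thin the paralog so its detection rate is clearly lower
        pc[] <- pc * (stats::runif(length(pc)) < 0.3)
        counts <- rbind(counts, pc)
        hom <- rbind(hom, data.frame(source_gene = pg$gene,
                                     target_gene = par_ids,
                                     detection_rate = rowMeans(pc > 0)))
      }
      meta <- data.frame(species = rep(ds, n_cells),
                         dataset = rep(ds, n_cells), row.names = cell_ids)
      list(expr = expression_set(counts, meta), homology = hom,
           lags = lags, pseudotime = stats::setNames(t_cell, cell_ids))
    })
    out[[ds]] <- sim
  }
  out
}

#' Simulate stage-aggregated datasets
#'
#' Emulates published datasets available only as a handful of ordered
#' maturation stages: each stage profile is the mean of the noiseless
#' log1p reference profile over its pseudotime window plus Gaussian noise.
#'
#' @param truth `trajectory_truth`.
#' @param stage_grid named list per dataset; each element a numeric vector of
#'   stage centers in \[0, 1\] (optionally named with stage labels).
#' @param halfwidth half-width of each stage's pseudotime window (default
#'   0.5 * minimal gap between that dataset's centers). Windows of the same
#'   dataset must not overlap.
#' @param noise_sd sd of the additive Gaussian noise (default 0.1).
#' @param seed integer seed.
#' @return named list of genes x stages matrices with ordered stage labels
#'   as column names.
#' @export
simulate_stage_datasets <- function(truth, stage_grid, halfwidth = NULL,
                                    noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "trajectory_truth"))
  prof <- log1p(truth$profiles)
  centers_of_bins <- (seq_len(truth$n_bins) - 0.5) / truth$n_bins
  .with_seed(seed, {
    lapply(stats::setNames(names(stage_grid), names(stage_grid)),
           function(ds) {
      cen <- sort(stage_grid[[ds]])
      hw <- halfwidth
      if (is.null(hw))
        hw <- if (length(cen) > 1) min(diff(cen)) / 2 else 0.25
      if (length(cen) > 1 && any(diff(cen) < 2 * hw - 1e-12))
        stop("overlapping stage windows in dataset ", ds)
      labs <- names(stage_grid[[ds]])
      if (is.null(labs)) labs <- sprintf("%s.S%d", ds, seq_along(cen))
      m <- vapply(cen, function(ct) {
        inwin <- abs(centers_of_bins - ct) <= hw
        rowMeans(prof[, inwin, drop = FALSE])
      }, numeric(nrow(prof)))
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
      dimnames(m) <- list(rownames(prof), labs)
      m
    })
  })
}

#' Simulate a stromal background cell pool
#'
#' Cells unrelated to the maturation trajectory: maturation-program genes sit
#' at baseline while a deterministic subset of the null genes acts as stromal
#' markers. Shares the gene universe with the reference dataset so bulk
#' mixtures can be formed.
#'
#' @param truth `trajectory_truth`.
#' @param n_cells pool size (default 1000).
#' @param n_marker number of null genes promoted to stromal markers
#'   (default 30).
#' @param marker_amplitude their mean expression above baseline (default 8).
#' @param seed integer seed.
#' @return [expression_set()] of raw counts.
#' @export
simulate_stromal_pool <- function(truth, n_cells = 1000, n_marker = 30,
                                  marker_amplitude = 8, seed = 1) {
  stopifnot(inherits(truth, "trajectory_truth"))
  gt <- truth$gene_table
  nulls <- gt$gene[gt$shape == "flat"]
  if (length(nulls) < n_marker)
    stop("not enough null genes to act as stromal markers")
  markers <- nulls[seq_len(n_marker)]
  .with_seed(seed, {
    cell_ids <- sprintf("stromal%04d", seq_len(n_cells))
    base_mu <- stats::setNames(rep(truth$baseline, nrow(gt)), gt$gene)
    base_mu[gt$shape == "flat"] <- truth$baseline + 1
    base_mu[markers] <- truth$baseline + marker_amplitude
    depth <- stats::rlnorm(n_cells, truth$noise$depth_meanlog,
                           truth$noise$depth_sdlog)
    dfac <- depth / exp(truth$noise$depth_meanlog)
    mu <- outer(base_mu, dfac)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = truth$noise$dispersion),
                     nrow = nrow(gt), dimnames = list(gt$gene, cell_ids))
    meta <- data.frame(species = rep("synthetic", n_cells),
                       dataset = "stromal", cell_type = "stromal",
                       row.names = cell_ids)
    expression_set(counts, meta)
  })
}

#' Simulate pseudo-bulk mixtures of maturation-stage and stromal cells
#'
#' For every mixing ratio and replicate, draws cells to a fixed total
#' (sampling with replacement, logged, when a pool is smaller than the
#' requested draw) and sums their counts into one pseudo-bulk column.
#'
#' @param stage_cells counts matrix or [expression_set()] of neutrophil cells.
#' @param stromal_cells counts for the stromal pool (same gene universe).
#' @param ratios neutrophil fractions, subset of `seq(0, 1, 0.1)`.
#' @param total cells per pseudo-bulk (default 1000).
#' @param reps replicates per ratio (default 20).
#' @param seed integer seed.
#' @return list with `counts` (genes x (ratio * rep) matrix) and `design`
#'   (`data.frame(sample, ratio, rep)`).
#' @export
simulate_bulk_mixtures <- function(stage_cells, stromal_cells, ratios,
                                   total = 1000, reps = 20, seed = 1) {
  neu <- .values(stage_cells)
  str <- .values(stromal_cells)
  stopifnot(identical(rownames(neu), rownames(str)))
  if (!all(ratios >= 0 & ratios <= 1)) stop("ratios must lie in [0, 1]")
  .with_seed(seed, {
    cols <- list(); design <- list()
    for (r in ratios) {
      n_neu <- round(r * total); n_str <- total - n_neu
      for (rep_i in seq_len(reps)) {
        draw <- function(pool, k) {
          if (k == 0) return(numeric(nrow(pool)))
          if (ncol(pool) < k)
            .nt_log("pool (%d cells) smaller than draw (%d): sampling with replacement",
                    ncol(pool), k)
          idx <- sample.int(ncol(pool), k, replace = ncol(pool) < k)
          rowSums(pool[, idx, drop = FALSE])
        }
        nm <- sprintf("r%03d.rep%02d", round(100 * r), rep_i)
        cols[[nm]] <- draw(neu, n_neu) + draw(str, n_str)
        design[[nm]] <- data.frame(sample = nm, ratio = r, rep = rep_i)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- rownames(neu)
    list(counts = counts, design = do.call(rbind, design))
  })
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat(sprintf("trajectory_truth: %d cells, %d genes (%d in modules), %d bins\n",
              length(x$pseudotime), nrow(x$gene_table),
              sum(x$gene_table$module %in% c("M1", "M2", "M3")), x$n_bins))
  cat("  phases:", paste(unique(x$bin_phase), collapse = " "),
      " breaks:", paste(x$phase_breaks, collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Emits the counts as MTX triplet + id files, cell metadata, and the truth
#' tables (per-cell pseudotime, per-gene module table, per-bin phase) as TSV,
#' so recovery analyses can read truth from disk rather than shared state.
#'
#' @param sim result of [simulate_trajectory_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "counts.mtx"))
  utils::write.table(
    data.frame(cell_id = names(sim$truth$pseudotime),
               pseudotime = sim$truth$pseudotime),
    file.path(dir, "truth_pseudotime.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_table,
                     file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(bin = seq_len(sim$truth$n_bins), phase = sim$truth$bin_phase),
    file.path(dir, "truth_phases.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
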