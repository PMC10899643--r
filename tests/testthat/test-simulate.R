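test_that("trajectory generator is a pure function of its seed", {
  a <- simulate_trajectory_dataset(n_cells = 150, seed = 42)
  b <- simulate_trajectory_dataset(n_cells = 150, seed = 42)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$pseudotime, b$truth$pseudotime)
  c <- simulate_trajectory_dataset(n_cells = 150, seed = 43)
  expect_false(identical(a$expr$values, c$expr$values))
  ## generators leave the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_trajectory_dataset(n_cells = 50, seed = 9))
  expect_identical(runif(1), before)
})

test_that("planted truth respects its declared structure", {
  sim <- cached_sim(seed = 1)
  tr <- sim$truth
  expect_true(all(tr$pseudotime >= 0 & tr$pseudotime <= 1))
  ## phases are contiguous along the bins
  expect_identical(length(rle(tr$bin_phase)$values), 4L)
  expect_equal(dim(tr$profiles), c(nrow(tr$gene_table), tr$n_bins))
  ## module gene counts follow the design
  expect_equal(unname(table(tr$gene_table$module)[c("M1", "M2", "M3")]),
               default_module_spec()$n_genes, ignore_attr = TRUE)
  ## gates split on the rising reporter: NO cells have lower reporter counts
  rep_counts <- sim$expr$values["mmp9.like", ]
  gate <- sim$expr$meta$sorted_gate
  expect_lt(max(rep_counts[gate == "NO"]), min(rep_counts[gate == "HI"]))
  expect_equal(mean(gate == "NO"), 0.3, tolerance = 0.05)
})

test_that("invalid generator settings error", {
  bad <- default_module_spec()
  bad$center[1] <- 1.4
  expect_error(simulate_trajectory_dataset(module_spec = bad, seed = 1),
               "centers")
  expect_error(simulate_trajectory_dataset(
    noise = list(dispersion = -1, depth_meanlog = 9, depth_sdlog = 0.3),
    seed = 1), "dispersion")
  expect_error(simulate_trajectory_dataset(n_genes = 10, seed = 1),
               "n_genes")
})

test_that("a rising reporter correlates with true pseudotime at study noise", {
  ## Monte-Carlo: the mmp9-like logistic reporter at dispersion 5
  rhos <- vapply(1:5, function(s) {
    sim <- simulate_trajectory_dataset(n_cells = 600, seed = 100 + s)
    cor(sim$expr$values["mmp9.like", ], sim$truth$pseudotime,
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.5))
})

test_that("null design yields no planted association", {
  spec0 <- default_module_spec()
  spec0$amplitude <- 0
  ## with zero amplitudes (reporters included) every cell is exchangeable
  ## up to depth, which normalization removes
  sim <- simulate_trajectory_dataset(n_cells = 400, n_genes = 200,
                                     module_spec = spec0,
                                     reporter_amplitude = 0, seed = 3)
  ## tested against an ordering independent of the noise (the latent
  ## pseudotime); an ordering re-inferred from the same null data would
  ## be circular and anti-conservative by construction
  suppressMessages(suppressWarnings({
    norm <- normalize_expression(sim$expr)
    res <- association_test(norm, sim$truth$pseudotime)
  }))
  expect_lt(mean(res$padj < 0.05), 0.05)
})

test_that("species family plants recoverable lags and homology", {
  ## transient (bump) genes carry the planted shifts: their
  ## cross-correlation peak is sharp and localizable
  sim <- simulate_trajectory_dataset(module_spec = lag_study_design(),
                                     n_cells = 400, seed = 1)
  gt <- sim$truth$gene_table
  genes <- gt$gene[gt$shape == "bump"][c(1, 21, 41, 42, 43)]
  lags <- setNames(rep(10L, 5), genes)
  fam <- simulate_species_family(sim$truth, list(mouse = lags),
                                 n_cells = 800, seed = 2)
  m <- fam$mouse
  expect_true(all(startsWith(rownames(m$expr$values), "mouse:")))
  expect_identical(unname(m$lags[genes]), rep(10L, 5))
  expect_true(all(m$lags[setdiff(names(m$lags), genes)] == 0))
  ## homology detection rates are observed detection fractions
  expect_true(all(m$homology$detection_rate >= 0 &
                    m$homology$detection_rate <= 1))
  ## recover the planted lag via binned true-pseudotime profiles
  ref_b <- bin_trajectory(log1p(sim$expr$values), sim$truth$pseudotime)
  qry <- log1p(m$expr$values)
  rownames(qry) <- sub("^mouse:", "", rownames(qry))
  qry_b <- bin_trajectory(qry, m$pseudotime)
  for (g in genes[1:3]) {
    cc <- cross_correlate(scale(ref_b$values[g, ])[, 1],
                          scale(qry_b$values[g, ])[, 1], max_lag = 40)
    expect_lte(abs(cc$lag - 10), 2)
  }
  ## zero lags reproduce a lag-free family
  fam0 <- simulate_species_family(sim$truth, list(ds = integer()),
                                  n_cells = 300, seed = 4)
  expect_true(all(fam0$ds$lags == 0))
  expect_error(simulate_species_family(sim$truth,
                                       list(ds = setNames(150L, genes[1]))),
               "n_bins")
})

test_that("paralog planting yields lower-detection 1-to-many cases", {
  sim <- cached_sim(seed = 1, n_cells = 400)
  gt1 <- sim$truth$gene_table
  pg <- gt1$gene[gt1$module == "M1"][1:4]
  fam <- simulate_species_family(sim$truth, list(ds = integer()),
                                 n_cells = 400, paralog_genes = pg, seed = 7)
  hom <- fam$ds$homology
  for (g in pg) {
    rates <- hom$detection_rate[hom$source_gene == g]
    expect_identical(length(rates), 2L)
    expect_gt(max(rates), min(rates))
  }
  ## collapse keeps the well-detected copy
  out <- suppressMessages(collapse_homology(fam$ds$expr, hom))
  expect_identical(sum(rownames(out$values) %in% pg), 4L)
})

test_that("stage datasets honour their grids", {
  sim <- cached_sim(seed = 1, n_cells = 400)
  grid <- list(dsA = c(0.1, 0.5, 0.9))
  ## zero noise, identical grids -> identical matrices
  a <- simulate_stage_datasets(sim$truth, grid, noise_sd = 0, seed = 1)
  b <- simulate_stage_datasets(sim$truth, grid, noise_sd = 0, seed = 99)
  expect_identical(a$dsA, b$dsA)
  expect_identical(colnames(a$dsA), c("dsA.S1", "dsA.S2", "dsA.S3"))
  expect_error(simulate_stage_datasets(sim$truth,
                                       list(dsA = c(0.4, 0.45)),
                                       halfwidth = 0.1, seed = 1),
               "overlapping")
})

test_that("simulations round-trip through disk with their truth", {
  sim <- simulate_trajectory_dataset(n_cells = 80, seed = 5)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_expression(file.path(dir, "counts.mtx"), "mtx_triplet",
                          meta_file = file.path(dir, "meta.tsv"))
  expect_equal(back$values, sim$expr$values)
  expect_identical(back$meta$sorted_gate, sim$expr$meta$sorted_gate)
  tt <- read.delim(file.path(dir, "truth_pseudotime.tsv"))
  expect_equal(setNames(tt$pseudotime, tt$cell_id), sim$truth$pseudotime)
  ph <- read.delim(file.path(dir, "truth_phases.tsv"))
  expect_identical(ph$phase, sim$truth$bin_phase)
})
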