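# Shared recovery-study machinery used by both the module/phase and the
# cross-species tests (and mirrored by scripts/acceptance.R).

# One full module/phase recovery run on a fresh synthetic dataset: returns
# the KGS-selected counts, the module ARI against the planted truth, and
# the bin-level phase accuracy against the planted windows.
run_module_phase_recovery <- function(seed) {
  sim <- simulate_trajectory_dataset(seed = seed)
  norm <- normalize_expression(sim$expr)
  pt <- infer_pseudotime(norm, mode = "principal_curve")
  b <- bin_trajectory(norm, pt)
  a <- suppressMessages(association_test(norm, pt, counts = sim$expr,
                                         top_n = sum(default_module_spec()$n_genes)))
  sel <- maturation_genes(a)
  truthmod <- with(sim$truth$gene_table, setNames(module, gene))
  pg <- partition_genes(b, sel)
  pp <- partition_phases(b, sel, pt = pt)
  common <- intersect(sel, names(truthmod)[truthmod %in% c("M1", "M2", "M3")])
  list(k = pg$k, g = pp$g,
       ari = ari(pg$assignment[common], truthmod[common]),
       phase_acc = mean(pp$bin_phase == sim$truth$bin_phase),
       contiguity = pp$contiguity)
}

# Design of the cross-species lag study: the standard maturation programs
# (which carry the trajectory) plus transient bump-profile genes at spread
# centers that carry the planted temporal shifts; bumps give the
# cross-correlation a sharp, localizable peak.
lag_study_design <- function() {
  rbind(default_module_spec(),
        data.frame(module = c("M1", "M2", "M3"), shape = "bump",
                   center = c(0.30, 0.50, 0.70), width = 0.06,
                   amplitude = 12, n_genes = 20))
}

# One lag-recovery run: plants uniform shifts in -20..20 bins on the bump
# genes of one simulated species dataset and returns the fraction
# recovered within +-2 bins. Both datasets are discretized on the
# generator's latent pseudotime so the alignment question is isolated
# from ordering error (ordering recovery is assessed separately).
run_lag_recovery <- function(seed) {
  sim <- simulate_trajectory_dataset(module_spec = lag_study_design(),
                                     seed = seed)
  gt <- sim$truth$gene_table
  bumpg <- gt$gene[gt$shape == "bump"]
  lags <- .with_seed_local(seed * 7 + 1, {
    stats::setNames(sample(-20:20, length(bumpg), replace = TRUE), bumpg)
  })
  fam <- simulate_species_family(sim$truth, list(query = lags),
                                 n_cells = 2000, seed = seed * 7 + 2)
  refb <- bin_trajectory(normalize_expression(sim$expr),
                         sim$truth$pseudotime)
  qn <- normalize_expression(fam$query$expr)
  qv <- qn$values
  rownames(qv) <- sub("^query:", "", rownames(qv))
  qb <- bin_trajectory(qv, fam$query$pseudotime)
  lt <- build_lag_table(refb$values[bumpg, ],
                        list(query = qb$values[bumpg, ]),
                        stats::setNames(gt$module, gt$gene)[bumpg],
                        max_lag = 40)
  rec <- stats::setNames(lt$per_gene$lag, lt$per_gene$gene)
  list(within2 = mean(abs(rec[bumpg] - lags[bumpg]) <= 2),
       planted = lags, recovered = rec)
}

.with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# One regulator-recovery run: two TFs leading their module by 5 bins plus
# flat decoys; returns whether each leading TF tops its module's ranking.
run_regulator_recovery <- function(seed) {
  tf_spec <- data.frame(tf = c("tf.m1", "tf.m2", "tf.m3"),
                        module = c("M1", "M2", "M3"),
                        lead_bins = 5, amplitude = 8)
  sim <- simulate_trajectory_dataset(n_cells = 1200, seed = seed,
                                     tf_spec = tf_spec)
  norm <- normalize_expression(sim$expr)
  b <- bin_trajectory(norm, sim$truth$pseudotime)
  truthmod <- with(sim$truth$gene_table, setNames(module, gene))
  planted <- names(truthmod)[truthmod %in% c("M1", "M2", "M3")]
  decoys <- names(truthmod)[startsWith(names(truthmod), "null")][1:3]
  tf_rows <- c("tf.m1", "tf.m2", "tf.m3", decoys)
  sc <- suppressMessages(
    scaled_dtw_similarity(b$values[tf_rows, ], b$values[planted, ]))
  rk <- rank_regulators(sc, truthmod[planted])
  vapply(c(M1 = "M1", M2 = "M2", M3 = "M3"), function(m)
    length(rk$by_module[[m]]) > 0 &&
      rk$by_module[[m]][1] == paste0("tf.", tolower(m)), logical(1))
}
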