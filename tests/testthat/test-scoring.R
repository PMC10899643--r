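test_that("ssGSEA placement oracle: top-rank placement maximizes the score", {
  ## N = 6 genes, |S| = 2: enumerate all 15 placements in one sample
  genes <- paste0("g", 1:6)
  expr <- matrix(6:1, 6, 1, dimnames = list(genes, "s1")) # g1 ranked top
  placements <- combn(genes, 2)
  scores <- apply(placements, 2, function(set)
    ssgsea(expr, list(S = set), normalize = FALSE)[1, 1])
  top <- which(apply(placements, 2, function(p)
    setequal(p, c("g1", "g2"))))
  bottom <- which(apply(placements, 2, function(p)
    setequal(p, c("g5", "g6"))))
  expect_equal(which.max(scores), top)
  expect_gt(scores[top], 0)
  expect_lt(scores[bottom], 0)
  expect_equal(which.min(scores), bottom)
})

test_that("ssGSEA is rank-based: invariant under strictly monotone transforms", {
  set.seed(8)
  m <- matrix(rexp(80 * 5), 80,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:5)))
  sig <- list(A = paste0("g", 1:10), B = paste0("g", 31:50))
  base <- ssgsea(m, sig)
  expect_equal(ssgsea(log1p(m), sig), base)
  expect_equal(ssgsea(m^3, sig), base)
  expect_equal(ssgsea(exp(m), sig), base)
  ## identical samples get identical scores
  mm <- cbind(a = m[, 1], b = m[, 1])
  sc <- ssgsea(mm, sig)
  expect_equal(sc["a", ], sc["b", ])
  ## empty overlap errors
  expect_error(ssgsea(m, list(none = "absent")), "empty gene overlap")
})

test_that("module score is zero under self-control and recovers planted shifts", {
  set.seed(12)
  ## background genes span a wide range of mean expression so the
  ## expression-matched bins of the set genes hold plenty of controls
  gene_means <- runif(200, 3, 8)
  m <- matrix(rnorm(200 * 50, gene_means), 200,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:50)))
  set <- paste0("g", 1:20)
  ## control pool forced equal to the set: exact zero
  s0 <- module_score(m, set, ctrl_genes = set)
  expect_equal(unname(s0), rep(0, 50))
  ## determinism given seed
  expect_identical(module_score(m, set, seed = 7),
                   module_score(m, set, seed = 7))
  ## a +1 shift of the set genes in half the cells is recovered as a
  ## score contrast between shifted and unshifted cells (a shift in every
  ## cell would be absorbed into the expression-matched control bins)
  shifted <- colnames(m)[1:25]
  deltas <- vapply(1:10, function(s) {
    mm <- m
    mm[set, shifted] <- mm[set, shifted] + 1
    sc <- module_score(mm, set, seed = s)
    mean(sc[shifted]) - mean(sc[setdiff(colnames(m), shifted)])
  }, numeric(1))
  ## attenuation below +1 comes from set genes landing in their own
  ## control bins (the matched draw does not exclude them)
  expect_gt(mean(deltas), 0.7)
  expect_lt(mean(deltas), 1.1)
  ## absent set genes are dropped with a message, all absent errors
  expect_message(module_score(m, c(set, "nope"), seed = 1), "absent")
  expect_error(module_score(m, "nope"), "no set gene")
})

test_that("module score is centred under an exchangeable null", {
  set.seed(77)
  m <- matrix(rnorm(300 * 30, 5), 300,
              dimnames = list(paste0("g", 1:300), paste0("c", 1:30)))
  means <- vapply(1:50, function(s) {
    set <- sample(rownames(m), 15)
    mean(module_score(m, set, seed = s))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-3)
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  bg <- paste0("g", 1:10)
  mod <- bg[1:5]
  ## set identical to the module: p = 1 / C(10, 5)
  tab <- hypergeom_enrichment(mod, list(exact = mod), bg)
  expect_equal(tab$p[1], 1 / choose(10, 5))
  ## empty overlap with a large set: p close to 1
  tab2 <- hypergeom_enrichment(mod, list(other = bg[6:10]), bg)
  expect_equal(tab2$p[1], 1)
  ## exhaustive enumeration oracle for all backgrounds of size <= 12
  set.seed(5)
  for (N in c(8, 10, 12)) {
    bgN <- paste0("b", seq_len(N))
    for (rep in 1:10) {
      mod_n <- sample(2:(N - 2), 1)
      set_n <- sample(2:(N - 2), 1)
      modN <- sample(bgN, mod_n)
      setN <- sample(bgN, set_n)
      q <- length(intersect(modN, setN))
      tabN <- hypergeom_enrichment(modN, list(s = setN), bgN)
      expect_equal(tabN$p[1], enum_hyper_tail(q, set_n, N, mod_n),
                   tolerance = 1e-12)
    }
  }
  ## module must be inside the background; disjoint sets are skipped
  expect_error(hypergeom_enrichment(c("x"), list(s = bg), bg), "subset")
  expect_error(
    suppressMessages(hypergeom_enrichment(mod, list(s = "zz"), bg)),
    "no set overlaps")
})

test_that("bulk mixtures hit the requested totals and edge ratios", {
  sim <- cached_sim(seed = 1, n_cells = 400)
  stromal <- simulate_stromal_pool(sim$truth, n_cells = 200, seed = 2)
  neu <- sim$expr$values
  mix <- simulate_bulk_mixtures(neu, stromal$values, ratios = c(0, 1),
                                total = 50, reps = 2, seed = 3)
  expect_identical(ncol(mix$counts), 4L)
  ## ratio 0 is pure stromal: stromal markers present, deterministic given seed
  mix2 <- simulate_bulk_mixtures(neu, stromal$values, ratios = c(0, 1),
                                 total = 50, reps = 2, seed = 3)
  expect_identical(mix$counts, mix2$counts)
  ## a pool smaller than the draw logs and samples with replacement
  expect_message(
    simulate_bulk_mixtures(neu[, 1:10], stromal$values, ratios = 1,
                           total = 50, reps = 1, seed = 1),
    "with replacement")
})

test_that("mixing sensitivity is monotone for the matched late signature", {
  sim <- cached_sim(seed = 1)
  truthmod <- true_modules(sim$truth)
  m3 <- names(truthmod)[truthmod == "M3"]
  mature <- sim$expr$values[, sim$truth$pseudotime > 0.75]
  stromal <- simulate_stromal_pool(sim$truth, n_cells = 600, seed = 5)
  res <- suppressMessages(
    mixing_sensitivity(mature, stromal$values, list(M3pan = m3),
                       ratios = seq(0, 1, 0.25), total = 1000, reps = 20,
                       seed = 11))
  med <- res$medians[order(res$medians$ratio), ]
  expect_true(all(diff(med$median_score) >= 0))
  expect_gt(med$median_score[nrow(med)], med$median_score[1])
  ## same seed, same medians
  res2 <- suppressMessages(
    mixing_sensitivity(mature, stromal$values, list(M3pan = m3),
                       ratios = c(0, 0.5), total = 500, reps = 5, seed = 4))
  res3 <- suppressMessages(
    mixing_sensitivity(mature, stromal$values, list(M3pan = m3),
                       ratios = c(0, 0.5), total = 500, reps = 5, seed = 4))
  expect_identical(res2$medians, res3$medians)
})
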