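test_that("stage aggregation equals a group-by mean", {
  set.seed(9)
  m <- matrix(rnorm(20 * 12, 5), 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:12)))
  lab <- rep(c("S1", "S2", "S3"), each = 4)
  agg <- aggregate_stages(m, lab)
  for (s in unique(lab))
    expect_equal(agg[, s], rowMeans(m[, lab == s]))
  ## one sample per stage is the identity
  one <- aggregate_stages(m[, 1:3], c("a", "b", "c"))
  expect_equal(unname(one), unname(m[, 1:3]))
  expect_error(aggregate_stages(m, lab[-1]), "one stage label")
})

test_that("quantile normalization matches the worked example and its defining property", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))
  ## identical columns unchanged
  mm <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(mm), mm)
  ## defining property: identical sorted values in every column (exact)
  set.seed(14)
  r <- matrix(rnorm(200), 40, 5)
  qr <- quantile_normalize(r)
  ref <- sort(qr[, 1])
  for (j in 2:5) expect_equal(sort(qr[, j]), ref)
  ## independent oracle: limma's implementation agrees on tie-free input
  skip_if_not_installed("limma")
  expect_equal(unname(qr), unname(limma::normalizeQuantiles(r)))
  ## single column: identity (logged)
  expect_equal(suppressMessages(quantile_normalize(r[, 1, drop = FALSE])),
               r[, 1, drop = FALSE])
})

test_that("cross-correlation recovers planted shifts with the stated conventions", {
  x <- dnorm(seq(-3, 3, length.out = 100))
  z <- as.numeric(scale(x))
  ## identical profiles: lag 0, coefficient 1
  cc <- cross_correlate(z, z)
  expect_identical(cc$lag, 0L)
  expect_equal(cc$coefficient, 1)
  ## query delayed by +10 bins -> positive lag
  bump_at <- function(c0) dnorm(seq_len(100), mean = c0, sd = 8)
  ref <- bump_at(45); qry <- bump_at(55)
  cc2 <- cross_correlate(scale(ref)[, 1], scale(qry)[, 1], max_lag = 99)
  expect_identical(cc2$lag, 10L)
  ## antisymmetry of clean shifts
  cc3 <- cross_correlate(scale(qry)[, 1], scale(ref)[, 1], max_lag = 99)
  expect_identical(cc3$lag, -10L)
  ## brute-force argmax oracle over all lags
  brute <- function(yref, xq, L) {
    n <- length(yref)
    xc <- xq - mean(xq); yc <- yref - mean(yref)
    sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
    r <- sapply(-L:L, function(k) {
      idx <- seq_len(n); ok <- idx + k >= 1 & idx + k <= n
      sum(xc[idx[ok] + k] * yc[idx[ok]]) / (n * sx * sy)
    })
    (-L:L)[which.max(r)]
  }
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(60); b <- rnorm(60)
    expect_identical(cross_correlate(a, b, 30)$lag,
                     as.integer(brute(a, b, 30)))
  }
  ## anti-correlated profiles report a negative peak, not clipped
  cc4 <- cross_correlate(z, -z, max_lag = 0)
  expect_lt(cc4$coefficient, 0)
  expect_error(cross_correlate(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("homology collapse keeps the best-detected homolog and is idempotent", {
  m <- matrix(1:12, 3, dimnames = list(c("ds:a", "ds:b1", "ds:b2"),
                                       paste0("c", 1:4)))
  map <- data.frame(source_gene = c("a", "b", "b"),
                    target_gene = c("ds:a", "ds:b1", "ds:b2"),
                    detection_rate = c(1, 0.2, 0.9))
  out <- suppressMessages(collapse_homology(m, map))
  expect_setequal(rownames(out), c("a", "b"))
  expect_equal(unname(out["b", ]), unname(m["ds:b2", ]))
  ## 1-to-1 is a pure rename; reapplication changes nothing
  again <- suppressMessages(collapse_homology(out, map))
  expect_equal(again, out)
  expect_lte(nrow(out), nrow(m))
})

test_that("planted one-to-many cases resolve to the planted truth", {
  set.seed(31)
  n <- 100
  src <- sprintf("z%03d", 1:n)
  tg <- paste0("m:", src)
  m <- matrix(rpois(n * 5, 4), n, dimnames = list(tg, paste0("c", 1:5)))
  map <- data.frame(source_gene = src, target_gene = tg,
                    detection_rate = runif(n, 0.5, 1))
  ## ten 1-to-2 cases: add a paralog with lower detection rate
  extra <- sprintf("m:par%02d", 1:10)
  m <- rbind(m, matrix(rpois(10 * 5, 1), 10,
                       dimnames = list(extra, paste0("c", 1:5))))
  map <- rbind(map, data.frame(source_gene = src[1:10], target_gene = extra,
                               detection_rate = 0.1))
  out <- suppressMessages(collapse_homology(m, map))
  expect_identical(nrow(out), 100L)
  for (i in 1:10)
    expect_equal(unname(out[src[i], ]), unname(m[tg[i], ]))
})

test_that("lag tables record planted lags, mean lags and module coefficients", {
  bump_at <- function(c0) dnorm(seq_len(100), mean = c0, sd = 8)
  genes <- paste0("g", 1:6)
  ref <- t(vapply(c(30, 40, 50, 55, 60, 65), bump_at, numeric(100)))
  rownames(ref) <- genes
  shift_mat <- function(lags) {
    m <- t(vapply(seq_along(lags), function(i) {
      idx <- pmin(pmax(seq_len(100) - lags[i], 1), 100)
      ref[i, idx]
    }, numeric(100)))
    rownames(m) <- genes
    m
  }
  mods <- setNames(rep(c("M1", "M3"), each = 3), genes)
  ## identical datasets: all lags 0, module coefficient 1
  lt0 <- build_lag_table(ref, list(d1 = ref, d2 = ref), mods)
  expect_true(all(lt0$per_gene$lag == 0))
  expect_equal(unname(lt0$module_coefficient), matrix(1, 2, 2),
               tolerance = 1e-10)
  ## planted +10 and +20 in two datasets: mean +15 per gene
  lt <- build_lag_table(ref, list(d1 = shift_mat(rep(10, 6)),
                                  d2 = shift_mat(rep(20, 6))), mods)
  expect_true(all(abs(lt$mean_lag - 15) <= 2))
  ## single-gene module mean equals that gene's coefficient
  mods1 <- setNames(c("M1", rep("M2", 5)), genes)
  lt1 <- build_lag_table(ref, list(d1 = ref), mods1)
  expect_equal(lt1$module_coefficient["d1", "M1"],
               lt1$per_gene$coefficient[lt1$per_gene$gene == "g1"])
  expect_error(build_lag_table(ref, list(d1 = ref[0, , drop = FALSE])),
               "empty common gene set")
})

test_that("pan signature applies the inclusive lag threshold and blacklist", {
  genes <- sprintf("g%03d", 1:135)
  mods <- setNames(rep(c("M1", "M2", "M3"), each = 45), genes)
  mean_lag <- numeric(135); names(mean_lag) <- genes
  conserved <- blacklisted <- shifted <- character()
  for (m in c(0, 45, 90)) {
    idx <- m + 1:45
    mean_lag[idx[1:30]] <- sample(-50:50, 30, replace = TRUE) # conserved
    mean_lag[idx[31:40]] <- c(rep(51, 5), rep(-60, 5))        # shifted
    mean_lag[idx[41:45]] <- 0                                 # blacklisted
    conserved <- c(conserved, genes[idx[1:30]])
    shifted <- c(shifted, genes[idx[31:40]])
    blacklisted <- c(blacklisted, genes[idx[41:45]])
  }
  lt <- structure(list(mean_lag = mean_lag,
                       per_gene = data.frame(), max_lag = 99),
                  class = "lag_table")
  sig <- derive_pan_signature(lt, mods, blacklist = blacklisted)
  expect_setequal(names(sig), c("M1pan", "M2pan", "M3pan"))
  expect_true(all(lengths(sig) == 30))
  expect_setequal(unlist(sig, use.names = FALSE), conserved)
  ## boundary: |lag| = 50 exactly is included, 51 excluded
  lt2 <- structure(list(mean_lag = c(a = 50, b = -50, c = 51),
                        max_lag = 99), class = "lag_table")
  sig2 <- derive_pan_signature(lt2, c(a = "M1", b = "M1", c = "M1"))
  expect_setequal(sig2[["M1pan"]], c("a", "b"))
})

test_that("stage clustering groups matched stages and scores 0 to 1", {
  sim <- cached_sim(seed = 1)
  hit <- 0
  for (s in 1:10) {
    st <- simulate_stage_datasets(sim$truth,
                                  list(dsA = c(0.12, 0.45, 0.85),
                                       dsB = c(0.12, 0.45, 0.85)),
                                  noise_sd = 0.05, seed = s)
    cl <- cluster_stages(st)
    ## matched stages should be mutual nearest leaves: check merge heights
    d <- cophenetic(cl$hclust)
    dm <- as.matrix(d)
    ok <- all(vapply(1:3, function(i) {
      a <- colnames(st$dsA)[i]; b <- colnames(st$dsB)[i]
      which.min(dm[a, setdiff(colnames(dm), a)]) ==
        match(b, setdiff(colnames(dm), a))
    }, logical(1)))
    hit <- hit + ok
    expect_equal(unname(cl$scores[colnames(st$dsA)]), c(0, 0.5, 1))
  }
  expect_gte(hit, 9)
  ## single-stage dataset scores 0 by convention
  st1 <- simulate_stage_datasets(cached_sim(1)$truth,
                                 list(dsA = c(0.2, 0.8), solo = 0.5),
                                 noise_sd = 0.05, seed = 1)
  cl1 <- suppressMessages(cluster_stages(st1))
  expect_equal(unname(cl1$scores[colnames(st1$solo)]), 0)
})
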