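# Binned-profile factory: module programs plus TFs leading them, with
# Gaussian bin noise — the regulator questions live entirely on the binned
# axis, so tests build profiles directly.
make_regulator_profiles <- function(lead = 5, noise = 0.15, seed = 1,
                                    n_per_module = 20) {
  set.seed(seed)
  bins <- (1:100 - 0.5) / 100
  shapes <- list(M1 = function(t) plogis(-(t - 0.25) / 0.03),
                 M2 = function(t) plogis((t - 0.25) / 0.03) *
                   plogis(-(t - 0.5) / 0.03),
                 M3 = function(t) plogis((t - 0.6) / 0.03))
  targets <- do.call(rbind, lapply(names(shapes), function(m) {
    t(vapply(seq_len(n_per_module), function(i)
      shapes[[m]](bins) + rnorm(100, 0, noise), numeric(100)))
  }))
  rownames(targets) <- paste0(rep(names(shapes), each = n_per_module),
                              ".g", seq_len(n_per_module))
  modules <- setNames(rep(names(shapes), each = n_per_module),
                      rownames(targets))
  tfs <- t(vapply(names(shapes), function(m)
    shapes[[m]](pmin(bins + lead / 100, 1)) + rnorm(100, 0, noise),
    numeric(100)))
  rownames(tfs) <- paste0("tf.", names(shapes))
  list(targets = targets, tfs = tfs, modules = modules)
}
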