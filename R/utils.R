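## Internal helpers shared across the package.

.nt_log <- function(fmt, ...) {
  message("[neutrotime] ", sprintf(fmt, ...))
}

#' Row-wise z-score of a numeric matrix
#'
#' Centers and scales each row to mean 0, sd 1. Rows with zero variance are
#' returned as all-zero rather than NaN so that constant profiles stay usable
#' downstream (their distance to anything is then driven by the other profile).
#'
#' @param x numeric matrix (features in rows).
#' @return matrix of the same shape and dimnames.
#' @keywords internal
.row_zscore <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  s[s == 0] <- Inf # constant row -> zeros
  out <- (x - mu) / s
  dimnames(out) <- dimnames(x)
  out
}

## Run `expr` with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards so generators are pure functions of (args, seed).
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Extract the genes x cells value matrix from either a bare matrix or an
## expression_set; used by every operation that accepts both.
.values <- function(x) {
  if (inherits(x, "expression_set")) x$values else x
}

## Rebuild an object of the same kind as `orig` around new values, keeping
## metadata rows aligned to the retained cells.
.rewrap <- function(orig, values) {
  if (!inherits(orig, "expression_set")) return(values)
  meta <- orig$meta
  if (!is.null(meta)) meta <- meta[colnames(values), , drop = FALSE]
  expression_set(values, meta)
}
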