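#' Expression set container
#'
#' A light container for a genes x cells (or genes x samples) expression
#' matrix plus per-cell metadata. Values are stored dense, genes in rows;
#' all file readers and generators in the package return this class, and
#' every operation also accepts a bare matrix.
#'
#' @param values numeric matrix, genes in rows, cells in columns; finite,
#'   non-negative for counts; unique row and column names required.
#' @param meta optional `data.frame` of per-cell metadata (columns such as
#'   `species`, `dataset`, `sorted_gate`, `stage_label`, `cell_type`), one
#'   row per cell, row names equal to the cell ids.
#' @return an object of class `expression_set`: a list with elements
#'   `values` and `meta`.
#' @export
expression_set <- function(values, meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell ids")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (any(values < 0))
    stop("negative expression values")
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != ncol(values))
      stop("metadata rows must align 1:1 with cells")
    rownames(meta) <- colnames(values)
  }
  structure(list(values = values, meta = meta), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$meta))
    cat("  metadata columns:", paste(colnames(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports two formats: `mtx_triplet` — a MatrixMarket coordinate file with
#' 1-based indices plus separate one-column TSV files of gene and cell ids —
#' and `dense_tsv` — a tab-separated table with gene ids in the first column
#' and a header row of cell ids. Indices are converted to R's in-memory
#' representation on read; the dense layout has genes as rows.
#'
#' @param path path to the `.mtx` file or the dense TSV.
#' @param format one of `"mtx_triplet"`, `"dense_tsv"`.
#' @param gene_file,cell_file id files for the triplet format; default to
#'   `genes.tsv` / `cells.tsv` next to `path`.
#' @param meta_file optional TSV of per-cell metadata with a `cell_id` column.
#' @return [expression_set()]
#' @export
read_expression <- function(path, format = c("mtx_triplet", "dense_tsv"),
                            gene_file = NULL, cell_file = NULL,
                            meta_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx_triplet") {
    if (is.null(gene_file)) gene_file <- file.path(dirname(path), "genes.tsv")
    if (is.null(cell_file)) cell_file <- file.path(dirname(path), "cells.tsv")
    for (f in c(gene_file, cell_file))
      if (!file.exists(f)) stop("file not found: ", f)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("id counts do not match matrix dimensions")
    if (any(m < 0)) stop("negative count in matrix")
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
  }
  meta <- NULL
  if (!is.null(meta_file)) {
    meta <- utils::read.delim(meta_file, header = TRUE, check.names = FALSE)
    if (!"cell_id" %in% colnames(meta)) stop("meta file needs a cell_id column")
    rownames(meta) <- meta$cell_id
    meta <- meta[colnames(m), setdiff(colnames(meta), "cell_id"), drop = FALSE]
  }
  expression_set(m, meta)
}

#' Write an expression matrix as MTX triplet plus id files
#'
#' Inverse of [read_expression()] for the `mtx_triplet` format.
#'
#' @param expr matrix or [expression_set()].
#' @param path output `.mtx` path; `genes.tsv`/`cells.tsv` are written next
#'   to it, and `meta.tsv` when metadata is present.
#' @export
write_expression <- function(expr, path) {
  m <- .values(expr)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                          "CsparseMatrix"), "generalMatrix"),
                  path)
  writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
  writeLines(colnames(m), file.path(dirname(path), "cells.tsv"))
  if (inherits(expr, "expression_set") && !is.null(expr$meta)) {
    meta <- cbind(cell_id = colnames(m), expr$meta)
    utils::write.table(meta, file.path(dirname(path), "meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter features by detection
#'
#' Keeps genes detected (nonzero) in at least `min_cells` cells, the standard
#' first quality-control step on raw counts.
#'
#' @param expr raw count matrix or [expression_set()].
#' @param min_cells minimum number of cells with a nonzero count (default 20).
#' @return filtered object of the same kind, with attributes `n_total` and
#'   `n_retained`.
#' @export
filter_features <- function(expr, min_cells = 20) {
  m <- .values(expr)
  if (any(!is.finite(m)) || any(m < 0)) stop("filter_features expects counts")
  keep <- rowSums(m > 0) >= min_cells
  .nt_log("filter_features: retained %d of %d features (min_cells = %d)",
          sum(keep), nrow(m), min_cells)
  out <- .rewrap(expr, m[keep, , drop = FALSE])
  attr(out, "n_total") <- nrow(m)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Filter cells by detected features and mitochondrial fraction
#'
#' Retains cells with at least `min_features` detected genes and a
#' mitochondrial read proportion strictly below `max_mito_frac`.
#' Mitochondrial genes are recognized by a configurable, case-insensitive
#' id-prefix list (zebrafish and mammalian naming differ).
#'
#' @param expr raw count matrix or [expression_set()].
#' @param min_features minimum detected genes per cell (inclusive; default 500).
#' @param max_mito_frac maximum mitochondrial proportion (exclusive; default 0.10).
#' @param mito_prefix character vector of gene-id prefixes (default `"mt-"`).
#' @return filtered object of the same kind.
#' @export
filter_cells <- function(expr, min_features = 500, max_mito_frac = 0.10,
                         mito_prefix = "mt-") {
  m <- .values(expr)
  if (any(!is.finite(m)) || any(m < 0)) stop("filter_cells expects counts")
  n_feat <- colSums(m > 0)
  pat <- paste0("^(", paste(tolower(mito_prefix), collapse = "|"), ")")
  mito <- grepl(pat, tolower(rownames(m)))
  if (!any(mito) && max_mito_frac < 1) {
    warning("no gene matched the mitochondrial prefix; ",
            "mitochondrial fraction treated as 0")
    frac <- rep(0, ncol(m))
  } else {
    tot <- colSums(m)
    frac <- ifelse(tot > 0, colSums(m[mito, , drop = FALSE]) / tot, 0)
  }
  keep <- n_feat >= min_features & frac < max_mito_frac
  .nt_log("filter_cells: retained %d of %d cells", sum(keep), ncol(m))
  .rewrap(expr, m[, keep, drop = FALSE])
}

#' Normalize expression
#'
#' `log1p_cp10k`: per-cell depth scaling to 10,000 total counts followed by
#' log1p — the package's deterministic normalization used ahead of binning
#' and z-scoring. `none` returns the input unchanged.
#'
#' @param expr raw count matrix or [expression_set()].
#' @param method `"log1p_cp10k"` or `"none"`.
#' @export
normalize_expression <- function(expr, method = c("log1p_cp10k", "none")) {
  method <- match.arg(method)
  if (method == "none") return(expr)
  m <- .values(expr)
  tot <- colSums(m)
  if (any(tot == 0)) stop("all-zero cell; filter cells first")
  out <- log1p(sweep(m, 2, tot, "/") * 1e4)
  .rewrap(expr, out)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated gene ids. Duplicate
#' genes within a line are removed with a warning.
#'
#' @param path GMT file.
#' @return a `signature_set`: named list of unique gene-id vectors, with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line with fewer than 3 fields: line ",
                     which(bad)[1])
  sets <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    if (anyDuplicated(g)) {
      warning("duplicate gene(s) in set '", p[1], "' removed")
      g <- unique(g)
    }
    g
  })
  names(sets) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate signature names")
  signature_set(sets,
                description = vapply(parts, `[`, "", 2))
}

#' Construct a signature set
#'
#' @param sets named list of character vectors (no empty list allowed;
#'   genes within a list must be unique after construction).
#' @param description per-set description strings.
#' @param provenance optional `data.frame` of per-gene provenance
#'   (columns such as `gene`, `signature`, `module`, `mean_lag`,
#'   `blacklisted`).
#' @export
signature_set <- function(sets, description = NULL, provenance = NULL) {
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("signature sets must be a non-empty named list")
  if (any(lengths(sets) == 0)) stop("empty gene list in signature set")
  sets <- lapply(sets, unique)
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, class = "signature_set",
            description = stats::setNames(description, names(sets)),
            provenance = provenance)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set with %d set(s):\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Write a signature set to GMT
#'
#' @param sig a `signature_set` (or plain named list of gene vectors).
#' @param path output path.
#' @export
write_gmt <- function(sig, path) {
  desc <- attr(sig, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sig)), names(sig))
  lines <- vapply(names(sig), function(nm) {
    d <- desc[[nm]]
    if (!nzchar(d)) d <- "na"
    paste(c(nm, d, sig[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a homology table
#'
#' TSV with columns `source_gene`, `target_gene`, `detection_rate`; a source
#' gene may map to several targets and vice versa (1-to-many orthology).
#'
#' @param path TSV path.
#' @return `data.frame` with the three columns, detection rates validated
#'   to lie in \[0, 1\].
#' @export
read_homology_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  need <- c("source_gene", "target_gene", "detection_rate")
  if (!all(need %in% colnames(tab)))
    stop("homology table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$detection_rate < 0 | tab$detection_rate > 1))
    stop("detection_rate outside [0, 1]")
  tab[need]
}
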