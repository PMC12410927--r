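#' Expression matrix container
#'
#' Builds the package's canonical expression container: a numeric N x G matrix
#' with cells as rows and genes as columns, plus a flag recording whether the
#' values are on the model scale (gene-wise min-max normalized log expression).
#'
#' @param values numeric matrix, cells as rows, genes as columns. Must be
#'   non-negative with no missing values.
#' @param cell_ids,gene_ids character vectors of row/column names; taken from
#'   `dimnames(values)` when omitted.
#' @param normalized logical; `TRUE` only for matrices on the model's \[0,1\]
#'   observation scale (the output of [normalize_expression()] or of the
#'   forward simulator).
#' @return An object of class `mixtraj_expr` with fields `values`, `cell_ids`,
#'   `gene_ids`, `normalized`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values), normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  n <- nrow(values); g <- ncol(values)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(g))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length does not match rows")
  if (length(gene_ids) != g) stop("gene_ids length does not match columns")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf("missing or non-finite expression value at (cell '%s', gene '%s')",
                 cell_ids[ij[1]], gene_ids[ij[2]]))
  }
  neg <- which(values < 0)
  if (length(neg)) {
    ij <- arrayInd(neg[1], dim(values))
    stop(sprintf("negative expression value %.6g at (cell '%s', gene '%s')",
                 values[neg[1]], cell_ids[ij[1]], gene_ids[ij[2]]))
  }
  if (anyDuplicated(gene_ids))
    stop(sprintf("duplicate gene id '%s': marker genes must be unambiguous",
                 gene_ids[anyDuplicated(gene_ids)]))
  if (anyDuplicated(cell_ids)) {
    warning("duplicate cell ids; suffixing to make them unique")
    cell_ids <- make.unique(cell_ids)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 normalized = isTRUE(normalized)),
            class = "mixtraj_expr")
}

#' @export
print.mixtraj_expr <- function(x, ...) {
  cat(sprintf("<mixtraj_expr> %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized [0,1] scale" else "raw"))
  invisible(x)
}

#' @export
dim.mixtraj_expr <- function(x) dim(x$values)

#' Read an expression matrix
#'
#' Reads cells-by-genes expression from CSV/TSV (header row of gene names,
#' first column of cell names), MatrixMarket (`.mtx` with `.rows`/`.cols`
#' sidecar name files), or h5ad (`X` with `obs`/`var` indices; requires a
#' `python` with the `anndata` module on the PATH).
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`, `"h5ad"`; guessed from the
#'   file extension when omitted.
#' @param transpose set `TRUE` for files stored genes-as-rows.
#' @return A [expression_matrix()] with `normalized = FALSE`.
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx", "h5ad"),
                            transpose = FALSE) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx", h5ad = "h5ad",
                     stop(sprintf("cannot guess format from extension '.%s'; pass `format`", ext)))
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read expression file '%s': no such file", path))
  m <- switch(format,
    csv = .read_delim_expr(path, ","),
    tsv = .read_delim_expr(path, "\t"),
    mtx = .read_mtx_expr(path),
    h5ad = .read_h5ad_expr(path))
  if (transpose) m <- t(m)
  expression_matrix(m, normalized = FALSE)
}

.read_delim_expr <- function(path, sep) {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop(sprintf("'%s' does not look like a cells x genes table", path))
  cells <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cells
  m
}

.read_mtx_expr <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  side <- function(suffix) {
    for (cand in c(paste0(stem, suffix), paste0(path, suffix)))
      if (file.exists(cand)) return(readLines(cand))
    stop(sprintf("MTX sidecar '%s%s' not found next to '%s'", stem, suffix, path))
  }
  rn <- side(".rows"); cn <- side(".cols")
  m <- as.matrix(Matrix::readMM(path))
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("MTX dimensions do not match .rows/.cols sidecars")
  dimnames(m) <- list(rn, cn)
  m
}

.read_h5ad_expr <- function(path) {
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out), add = TRUE)
  code <- paste(
    "import sys, anndata, pandas as pd",
    "import scipy.sparse as sp",
    "a = anndata.read_h5ad(sys.argv[1])",
    "X = a.X.toarray() if sp.issparse(a.X) else a.X",
    "pd.DataFrame(X, index=a.obs_names, columns=a.var_names).to_csv(sys.argv[2])",
    sep = "; ")
  status <- suppressWarnings(system2("python", c("-c", shQuote(code), shQuote(path), shQuote(out)),
                                     stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(out))
    stop(sprintf("failed to read h5ad file '%s' (python/anndata unavailable or file unreadable)", path))
  .read_delim_expr(out, ",")
}

#' Write an expression matrix to CSV
#'
#' @param m a `mixtraj_expr`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "mixtraj_expr"))
  df <- data.frame(cell_id = m$cell_ids, m$values, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Gene-wise min-max normalization of log expression
#'
#' Maps each gene column `v` to `(log1p(v) - min) / (max - min)`, the
#' model's \[0,1\] observation scale. `log1p` keeps exact zeros at zero so
#' they remain candidate dropout events. Constant genes have zero range and
#' are set to all-zeros with a warning: they carry no dynamic information.
#'
#' @param m an unnormalized `mixtraj_expr`.
#' @return A new `mixtraj_expr` with `normalized = TRUE`; `m` is unmodified.
#' @export
normalize_expression <- function(m) {
  stopifnot(inherits(m, "mixtraj_expr"))
  if (m$normalized) stop("matrix is already normalized")
  v <- log1p(m$values)
  rng <- apply(v, 2, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat)) {
    warning(sprintf("constant gene column(s) set to zero after normalization: %s",
                    paste(m$gene_ids[flat], collapse = ", ")))
    span[flat] <- 1
  }
  v <- sweep(sweep(v, 2, rng[1, ], "-"), 2, span, "/")
  v[, flat] <- 0
  expression_matrix(v, m$cell_ids, m$gene_ids, normalized = TRUE)
}
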