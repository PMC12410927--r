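#' Marker panel: branch topology plus the gene/branch marker map
#'
#' A marker panel declares the K terminal branches of the differentiation
#' topology and, for every marker gene, the branch(es) along which that gene
#' shows switch-like activation. On all other branches the gene is modelled
#' as a transient pulse. Genes present in the expression matrix but absent
#' from the marker map are treated as transient on every branch.
#'
#' @param branch_names character vector of K branch names, in topology order.
#' @param marker_map named list: gene id -> character vector of branch names
#'   (or integer vector of branch indices) the gene marks.
#' @param expr optional `mixtraj_expr` used to validate that every marker
#'   gene is present in the matrix.
#' @return An object of class `mixtraj_panel` with fields `K`,
#'   `branch_names`, and `marker_map` (gene -> sorted integer branch indices).
#' @export
marker_panel <- function(branch_names, marker_map, expr = NULL) {
  branch_names <- as.character(branch_names)
  K <- length(branch_names)
  if (K < 1) stop("a marker panel needs at least one branch (K >= 1)")
  if (anyDuplicated(branch_names)) stop("duplicate branch names")
  if (length(marker_map) == 0) stop("marker_map is empty: every branch needs markers")
  if (is.null(names(marker_map)) || any(names(marker_map) == ""))
    stop("marker_map must be a named list (gene id -> branches)")
  map <- lapply(marker_map, function(b) {
    if (is.character(b)) {
      idx <- match(b, branch_names)
      if (anyNA(idx)) stop(sprintf("unknown branch name '%s' in marker map", b[which(is.na(idx))[1]]))
    } else {
      idx <- as.integer(b)
      if (any(idx < 1 | idx > K)) stop("branch index out of range in marker map")
    }
    sort(unique(idx))
  })
  if (!is.null(expr)) {
    stopifnot(inherits(expr, "mixtraj_expr"))
    missing <- setdiff(names(map), expr$gene_ids)
    if (length(missing))
      stop(sprintf("marker gene(s) absent from the expression matrix: %s",
                   paste(missing, collapse = ", ")))
  }
  per_branch <- vapply(seq_len(K), function(k) sum(vapply(map, function(b) k %in% b, logical(1))), integer(1))
  if (any(per_branch == 0))
    stop(sprintf("branch '%s' has no marker genes", branch_names[which(per_branch == 0)[1]]))
  if (any(per_branch < 4))
    warning(sprintf("branch(es) with fewer than 4 marker genes (%s); at least four per lineage is recommended for robust inference",
                    paste(branch_names[per_branch < 4], collapse = ", ")))
  structure(list(K = K, branch_names = branch_names, marker_map = map),
            class = "mixtraj_panel")
}

#' @export
print.mixtraj_panel <- function(x, ...) {
  cat(sprintf("<mixtraj_panel> K=%d branches: %s\n", x$K, paste(x$branch_names, collapse = ", ")))
  for (k in seq_len(x$K)) {
    g <- names(x$marker_map)[vapply(x$marker_map, function(b) k %in% b, logical(1))]
    cat(sprintf("  %s: %s\n", x$branch_names[k], paste(g, collapse = ", ")))
  }
  invisible(x)
}

#' Parse a marker panel from YAML or JSON
#'
#' The file must contain a `branches` key (ordered list of branch names) and
#' a `markers` mapping from gene id to a branch name or list of branch names.
#'
#' @param path YAML or JSON file.
#' @param m a `mixtraj_expr` against which marker genes are validated.
#' @return A [marker_panel()].
#' @export
parse_marker_panel <- function(path, m = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read marker panel '%s': no such file", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$branches) || is.null(spec$markers))
    stop("marker panel file needs `branches` and `markers` keys")
  branches <- unlist(spec$branches, use.names = FALSE)
  map <- lapply(spec$markers, function(b) unlist(b, use.names = FALSE))
  marker_panel(branches, map, expr = m)
}

#' Build the marker matrix (genes x branches) for a gene set
#'
#' Internal helper aligning a panel to the gene order of an expression
#' matrix; entry (j, k) is 1 when gene j is switch-like on branch k.
#' @noRd
.marker_matrix <- function(panel, gene_ids) {
  M <- matrix(0L, length(gene_ids), panel$K, dimnames = list(gene_ids, panel$branch_names))
  for (g in names(panel$marker_map)) {
    if (!g %in% gene_ids)
      stop(sprintf("marker gene '%s' absent from the expression matrix", g))
    M[g, panel$marker_map[[g]]] <- 1L
  }
  M
}

#' Simplify a panel to a subset of branches
#'
#' Emulates topology-prior ablation: branches outside `keep_branches` are
#' removed and their markers fall out of the marker map, so those genes are
#' treated as transient on every remaining branch while staying in the
#' expression matrix.
#'
#' @param panel a `mixtraj_panel`.
#' @param keep_branches integer indices or branch names to retain (non-empty).
#' @return A `mixtraj_panel` with `K = length(keep_branches)`.
#' @export
ablate_topology <- function(panel, keep_branches) {
  stopifnot(inherits(panel, "mixtraj_panel"))
  if (length(keep_branches) == 0) stop("keep_branches must be a non-empty subset of branches")
  if (is.character(keep_branches)) {
    keep <- match(keep_branches, panel$branch_names)
    if (anyNA(keep)) stop("unknown branch name in keep_branches")
  } else {
    keep <- as.integer(keep_branches)
    if (any(keep < 1 | keep > panel$K)) stop("branch index out of range in keep_branches")
  }
  keep <- sort(unique(keep))
  map <- lapply(panel$marker_map, function(b) match(intersect(b, keep), keep))
  map <- map[vapply(map, length, integer(1)) > 0]
  marker_panel(panel$branch_names[keep], map)
}

#' Construct a K-branch test panel with regular gene names
#'
#' Convenience constructor used by the simulator and the command line:
#' branch k receives `markers_per_branch` switch-like markers named
#' `b<k>_m<r>`.
#'
#' @param K number of branches.
#' @param markers_per_branch markers per branch (default 4).
#' @param branch_names optional names; defaults to `branch1..branchK`.
#' @return A [marker_panel()].
#' @export
default_panel <- function(K, markers_per_branch = 4, branch_names = NULL) {
  if (is.null(branch_names)) branch_names <- sprintf("branch%d", seq_len(K))
  map <- list()
  for (k in seq_len(K))
    for (r in seq_len(markers_per_branch))
      map[[sprintf("b%d_m%d", k, r)]] <- k
  if (markers_per_branch >= 4) marker_panel(branch_names, map)
  else suppressWarnings(marker_panel(branch_names, map))
}
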