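#' Load an undirected protein-protein interaction network
#'
#' Reads a 2- or 3-column tab-separated edge list (`gene_a`, `gene_b`, and an
#' optional weight). The graph is undirected and simple: duplicate and
#' reversed edges are merged, self-edges are dropped, and any weight column is
#' binarized (the propagation operator is defined on 0/1 adjacencies only).
#'
#' @param path Edge-list TSV.
#' @param drop_isolated Remove degree-0 nodes after cleaning (default TRUE,
#'   mirroring the usual "remove nodes with no interactions" step).
#' @return A `ppi_network`: list with `gene_order` (lexicographically sorted
#'   node IDs), `adjacency` (sparse symmetric binary `dgCMatrix` with zero
#'   diagonal) and `degrees` (named integer row sums).
#' @export
load_ppi <- function(path, drop_isolated = TRUE) {
  if (!file.exists(path)) stop_validation("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_validation("edge list is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop_parse("malformed edge row at line ", bad[1L],
               ": expected at least 2 tab-separated columns")
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop_parse("edge row with a blank gene ID at line ",
               which(!nzchar(a) | !nzchar(b))[1L])
  has_w <- vapply(fields, length, 1L) >= 3L
  if (any(has_w)) message("edge weights present; binarized on load")

  keep <- a != b                        # drop self-edges; diag is added later
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) stop_validation("edge list has no non-self edges")
  genes <- sort(unique(c(a, b)))
  i <- match(a, genes); j <- match(b, genes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(length(genes), length(genes)),
                              dimnames = list(genes, genes))
  adj@x[] <- 1                          # merge duplicates/reversals to 0/1
  deg <- Matrix::rowSums(adj)
  if (drop_isolated && any(deg == 0)) {
    keep <- deg > 0
    adj <- adj[keep, keep, drop = FALSE]
    genes <- genes[keep]
    deg <- deg[keep]
  }
  structure(list(gene_order = genes,
                 adjacency = methods::as(adj, "generalMatrix"),
                 degrees = stats::setNames(as.integer(deg), genes)),
            class = "ppi_network")
}

#' Construct a `ppi_network` from an in-memory adjacency matrix
#'
#' Mostly used by the synthetic-fixture generator and in tests.
#'
#' @param adjacency Symmetric binary matrix (dense or sparse) with zero
#'   diagonal; dimnames give gene IDs (generated if absent).
#' @return A `ppi_network`.
#' @export
ppi_from_adjacency <- function(adjacency) {
  adj <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                 "dMatrix"), "generalMatrix")
  if (nrow(adj) != ncol(adj)) stop_validation("adjacency must be square")
  if (!is_binary_matrix(adj)) stop_validation("adjacency must be binary")
  if (!Matrix::isSymmetric(adj)) stop_validation("adjacency must be symmetric")
  if (any(Matrix::diag(adj) != 0)) stop_validation("adjacency diagonal must be zero")
  genes <- rownames(adj) %||% sprintf("g%04d", seq_len(nrow(adj)))
  dimnames(adj) <- list(genes, genes)
  structure(list(gene_order = genes, adjacency = adj,
                 degrees = stats::setNames(as.integer(Matrix::rowSums(adj)), genes)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$gene_order), "genes,",
      sum(x$degrees) / 2, "undirected edges\n")
  invisible(x)
}

#' Self-loop-augmented adjacency
#'
#' Returns the adjacency with added self-connections, A + I, used by every
#' graph-convolution layer so each node retains its own features during
#' propagation.
#'
#' @param network A `ppi_network`.
#' @return Sparse binary matrix A + I.
#' @export
add_self_loops <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  a <- network$adjacency
  a + Matrix::Diagonal(nrow(a), 1)
}

#' Boolean OR feature propagation
#'
#' The propagation product for strictly binary inputs: entry (i, j) of the
#' result is 1 iff gene i has at least one neighbour (under `A`, which
#' normally includes self-loops) carrying feature j — i.e. the logical OR
#' over the neighbourhood, replacing the additive accumulation of an
#' ordinary matrix product. Equivalently `sign(A %*% H)`; implemented with
#' sparse boolean arithmetic so no dense N x N intermediate is formed.
#'
#' @param A Binary N x N matrix (adjacency, typically with self-loops).
#' @param H Binary N x M feature matrix.
#' @return Sparse binary N x M `dgCMatrix`.
#' @export
or_propagate <- function(A, H) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  H <- Matrix::Matrix(H, sparse = TRUE)
  if (ncol(A) != nrow(H)) stop_validation("inner dimensions disagree")
  if (!is_binary_matrix(A) || !is_binary_matrix(H))
    stop_validation("or_propagate is defined for 0/1 matrices only")
  res <- methods::as(A, "nMatrix") %&% methods::as(H, "nMatrix")
  out <- methods::as(methods::as(res, "dMatrix"), "generalMatrix")
  dimnames(out) <- list(rownames(A), colnames(H))
  out
}

#' Write a network's adjacency as Matrix Market plus a node-order sidecar
#'
#' @param network A `ppi_network`.
#' @param prefix Output path prefix; writes `<prefix>.mtx` and
#'   `<prefix>.genes.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_ppi <- function(network, prefix) {
  stopifnot(inherits(network, "ppi_network"))
  paths <- paste0(prefix, c(".mtx", ".genes.tsv"))
  Matrix::writeMM(network$adjacency, paths[[1L]])
  writeLines(network$gene_order, paths[[2L]])
  invisible(paths)
}
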