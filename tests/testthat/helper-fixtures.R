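# Shared fixture builders: everything is generated in code at test time.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small deterministic annotation TSV covering all three namespaces.
demo_annotation_lines <- function() {
  c("g1\tMF\tGO:0001", "g1\tMF\tGO:0001", "g1\tBP\tGO:0009",
    "g2\tMF\tGO:0002", "g2\tCC\tGO:0005", "g2\tCC\tGO:0006",
    "g3\tBP\tGO:0009", "g3\tBP\tGO:0010", "g3\tMF\tGO:0001",
    "g4\tCC\tGO:0005")
}

# Minimal GAF 2.x content: 17 columns, aspect in column 9.
demo_gaf_lines <- function() {
  gaf_row <- function(gene, go, aspect) {
    cols <- rep("", 17)
    cols[1] <- "DB"; cols[2] <- gene; cols[3] <- gene
    cols[5] <- go; cols[7] <- "IEA"; cols[9] <- aspect
    cols[12] <- "protein"; cols[13] <- "taxon:9606"; cols[14] <- "20200101"
    cols[15] <- "DB"
    paste(cols, collapse = "\t")
  }
  c("!gaf-version: 2.2",
    "! comment line",
    gaf_row("geneA", "GO:0000001", "F"),
    gaf_row("geneA", "GO:0000002", "P"),
    gaf_row("geneB", "GO:0000001", "F"),
    gaf_row("geneB", "GO:0000003", "C"),
    gaf_row("geneC", "GO:0000004", "P"))
}

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a + t(a)
}

# Random edge-list lines from an adjacency (one direction each).
edges_from_adjacency <- function(a, genes) {
  idx <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  paste(genes[idx[, 1]], genes[idx[, 2]], sep = "\t")
}

# Tiny trained-model ingredients: a path graph with one-hot-ish features.
tiny_problem <- function(n = 6, m = 5, seed = 1) {
  withr_seed <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  genes <- sprintf("n%02d", seq_len(n))
  dimnames(a) <- list(genes, genes)
  X <- Matrix::Matrix(matrix(as.numeric(runif(n * m) < 0.4), n, m),
                      sparse = TRUE)
  rownames(X) <- genes
  assign(".Random.seed", withr_seed, envir = globalenv())
  list(network = ppi_from_adjacency(a), X = X, genes = genes)
}

# Central finite differences of f over a flat parameter vector.
numeric_gradient <- function(f, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, 0)
}

# Flatten / unflatten model params for finite differencing.
flatten_params <- function(params) {
  c(unlist(params$W), unlist(params$b), as.numeric(params$Wy),
    as.numeric(params$Wc))
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 1L
  for (k in seq_along(template$W)) {
    n <- length(template$W[[k]])
    out$W[[k]] <- matrix(theta[pos:(pos + n - 1)], nrow(template$W[[k]]))
    pos <- pos + n
  }
  for (k in seq_along(template$b)) {
    n <- length(template$b[[k]])
    out$b[[k]] <- theta[pos:(pos + n - 1)]
    pos <- pos + n
  }
  n <- length(template$Wy)
  out$Wy <- matrix(theta[pos:(pos + n - 1)], nrow(template$Wy))
  pos <- pos + n
  n <- length(template$Wc)
  out$Wc <- matrix(theta[pos:(pos + n - 1)], nrow(template$Wc))
  out
}

flatten_grads <- function(g) {
  c(unlist(g$W), unlist(g$b), as.numeric(g$Wy), as.numeric(g$Wc))
}

# Generate a full small fixture on disk and load every piece.
load_fixture <- function(config = fixture_config()) {
  dir <- tempfile("fixture")
  fx <- generate_fixture(config, dir)
  network <- load_ppi(fx$paths[["edges"]])
  ann <- read_annotations(fx$paths[["annotations"]])
  features <- suppressMessages(build_feature_matrices(ann, network$gene_order))
  coords <- read_gene_coords(fx$paths[["coordinates"]])
  disease <- intersect(read_gmt(fx$paths[["gmt"]])$disease1,
                       network$gene_order)
  list(fx = fx, network = network, features = features, coords = coords,
       disease = disease, dir = dir)
}
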