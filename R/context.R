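#' Sample context triples for the unsupervised loss
#'
#' Draws `(i, c, gamma)` triples encoding two kinds of node context. With
#' probability `negative_ratio` a triple is a negative pair: `i` and `c`
#' drawn uniformly (distinct), `gamma = -1`. Otherwise it is a positive pair
#' (`gamma = +1`), which with probability `label_context_ratio` is
#' label-based — `i` and `c` are distinct labeled nodes sharing a class —
#' and otherwise walk-based: a uniform-start random walk of `walk_length`
#' steps is taken on the (un-augmented) adjacency, and one ordered pair of
#' distinct nodes at walk distance at most `window` is chosen uniformly.
#' Walks stop early at dead ends; walks yielding no eligible pair are
#' redrawn. If label context is requested but no class has two labeled
#' members, sampling falls back to graph context (with a message).
#'
#' Uses the current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param network A `ppi_network`.
#' @param labels Optional named vector (names = gene IDs) of class labels
#'   for the labeled subset.
#' @param config A `model_config` (supplies walk and ratio parameters).
#' @param n Number of triples to draw.
#' @return Data frame with integer columns `i`, `c` (node indices into
#'   `network$gene_order`) and `gamma` (+1/-1).
#' @export
sample_context <- function(network, labels = NULL, config, n) {
  stopifnot(inherits(network, "ppi_network"))
  N <- length(network$gene_order)
  if (N < 2L) stop_validation("need at least 2 nodes to sample context")
  adj <- adjacency_list(network)

  lab_groups <- list()
  if (!is.null(labels) && length(labels)) {
    idx <- match(names(labels), network$gene_order)
    ok <- !is.na(idx)
    groups <- split(idx[ok], as.character(labels)[ok])
    lab_groups <- Filter(function(g) length(g) >= 2L, groups)
  }
  warned <- FALSE

  i <- integer(n); cc <- integer(n); gamma <- integer(n)
  for (t in seq_len(n)) {
    if (runif(1) < config$negative_ratio) {
      a <- sample.int(N, 1L)
      b <- sample.int(N - 1L, 1L)
      if (b >= a) b <- b + 1L
      i[t] <- a; cc[t] <- b; gamma[t] <- -1L
      next
    }
    use_label <- runif(1) < config$label_context_ratio
    if (use_label && length(lab_groups) == 0L) {
      if (!warned && !is.null(labels)) {
        message("no class with two labeled nodes; falling back to graph context")
        warned <- TRUE
      }
      use_label <- FALSE
    }
    if (use_label) {
      grp <- lab_groups[[sample.int(length(lab_groups), 1L)]]
      pair <- grp[sample.int(length(grp), 2L)]
      i[t] <- pair[[1L]]; cc[t] <- pair[[2L]]; gamma[t] <- 1L
    } else {
      pair <- NULL
      while (is.null(pair)) {
        walk <- random_walk(adj, sample.int(N, 1L), config$walk_length)
        pair <- pick_walk_pair(walk, config$window)
      }
      i[t] <- pair[[1L]]; cc[t] <- pair[[2L]]; gamma[t] <- 1L
    }
  }
  data.frame(i = i, c = cc, gamma = gamma)
}

# Neighbour lists of the raw adjacency (no self-loops), cached per call site.
adjacency_list <- function(network) {
  a <- methods::as(network$adjacency, "TsparseMatrix")
  lapply(split(a@j + 1L, factor(a@i + 1L, levels = seq_len(nrow(a)))),
         as.integer)
}

# Uniform random walk of `steps` steps; returns the visited node sequence
# (length <= steps + 1; shorter if a dead end is reached).
random_walk <- function(adj, start, steps) {
  walk <- integer(steps + 1L)
  walk[1L] <- start
  cur <- start
  for (s in seq_len(steps)) {
    nb <- adj[[cur]]
    if (length(nb) == 0L) return(walk[seq_len(s)])
    cur <- nb[[sample.int(length(nb), 1L)]]
    walk[s + 1L] <- cur
  }
  walk
}

# Uniformly choose one ordered pair (w_j, w_k) with 0 < |j - k| <= window
# and w_j != w_k; NULL if the walk has no eligible pair.
pick_walk_pair <- function(walk, window) {
  L <- length(walk)
  if (L < 2L) return(NULL)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(L)) {
    lo <- max(1L, j - window); hi <- min(L, j + window)
    ks <- setdiff(seq.int(lo, hi), j)
    ks <- ks[walk[ks] != walk[j]]
    from <- c(from, rep.int(j, length(ks))); to <- c(to, ks)
  }
  if (length(from) == 0L) return(NULL)
  pick <- sample.int(length(from), 1L)
  c(walk[from[pick]], walk[to[pick]])
}
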