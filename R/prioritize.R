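#' Read gene coordinates from a BED-like TSV
#'
#' Columns: chrom, start, end, gene (0-based half-open intervals).
#'
#' @param path File path.
#' @return Data frame with `gene`, `chrom`, `start`, `end`, `midpoint`.
#' @export
read_gene_coords <- function(path) {
  if (!file.exists(path)) stop_validation("coordinates file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop_parse("coordinates file needs 4 columns (chrom, start, end, gene)")
  names(df)[1:4] <- c("chrom", "start", "end", "gene")
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop_parse("start/end columns must be numeric")
  if (any(df$end <= df$start))
    stop_validation("interval with end <= start at row ",
                    which(df$end <= df$start)[1L])
  if (anyDuplicated(df$gene))
    stop_validation("duplicate gene in coordinates: ",
                    df$gene[duplicated(df$gene)][1L])
  df$midpoint <- (df$start + df$end) / 2
  df[, c("gene", "chrom", "start", "end", "midpoint")]
}

#' Build an artificial linkage interval around a target gene
#'
#' The candidate set is the target plus the 99 genes genomically nearest to
#' it (midpoint distance on the same chromosome first; genes on other
#' chromosomes, ordered by absolute midpoint difference, are used only when
#' the chromosome has too few eligible genes). Genes in the disease seed set
#' are never candidates; distance ties break lexicographically by gene ID.
#'
#' @param target Target gene ID (the left-out disease gene).
#' @param coords Coordinates data frame from [read_gene_coords()].
#' @param seed_set Remaining disease genes (excluded from the 99).
#' @param universe Gene IDs eligible as candidates (e.g. the network nodes).
#' @param size Interval size (default 100: target + 99 neighbours).
#' @param disease_id Label stored on the interval.
#' @return A `linkage_interval`: list with `target_gene`, `candidates`
#'   (length `size`, target first, then by increasing distance) and
#'   `disease_id`.
#' @export
build_linkage_interval <- function(target, coords, seed_set, universe,
                                   size = 100, disease_id = "disease") {
  tc <- coords[coords$gene == target, ]
  if (nrow(tc) == 0L)
    stop_validation("target gene ", target, " has no coordinates")
  pool <- coords[coords$gene %in% setdiff(universe, c(seed_set, target)), ]
  if (nrow(pool) < size - 1L)
    stop_validation("only ", nrow(pool), " eligible genes; need ", size - 1L)
  same <- pool$chrom == tc$chrom
  dist <- abs(pool$midpoint - tc$midpoint)
  ord <- order(!same, dist, pool$gene)   # same chromosome first, then distance
  chosen <- pool$gene[ord][seq_len(size - 1L)]
  structure(list(target_gene = target,
                 candidates = c(target, chosen),
                 disease_id = disease_id),
            class = "linkage_interval")
}

#' Score interval candidates under the three namespace models
#'
#' For each GO namespace, the candidate's positive-class probability from
#' the graph forward pass. Candidates absent from the network are scored
#' feed-forward with an all-zero feature row (logged).
#'
#' @param models Named list of three `gcn_model` objects (`MF`, `CC`, `BP`).
#' @param features Named list of the three `feature_matrix` objects.
#' @param network The `ppi_network`.
#' @param interval A `linkage_interval`.
#' @param positive_class Label of the disease class (default `"disease"`).
#' @return Numeric matrix, candidates x namespaces.
#' @export
score_candidates <- function(models, features, network, interval,
                             positive_class = "disease") {
  stopifnot(inherits(interval, "linkage_interval"))
  cands <- interval$candidates
  out <- matrix(NA_real_, length(cands), length(models),
                dimnames = list(cands, names(models)))
  absent <- setdiff(cands, network$gene_order)
  if (length(absent))
    message(length(absent), " candidate(s) not in the network; ",
            "scored with all-zero features")
  for (ns in names(models)) {
    probs <- predict.gcn_model(models[[ns]], features[[ns]], network)
    pc <- match(positive_class, models[[ns]]$classes)
    if (is.na(pc)) stop_validation("model lacks class ", positive_class)
    present <- intersect(cands, rownames(probs))
    out[present, ns] <- probs[present, pc]
    for (g in absent)
      out[g, ns] <- predict_proba(numeric(models[[ns]]$params$input_width),
                                  models[[ns]]$params, models[[ns]]$config)[pc]
  }
  out
}

#' Rank interval candidates from per-namespace scores
#'
#' The final score is the arithmetic mean of the namespace scores
#' (`aggregate = "score_mean"`, the default) or the mean of the
#' per-namespace descending-score ranks (`"rank_mean"`). Candidates are
#' ordered best-first; ties break lexicographically by gene ID.
#'
#' @param namespace_scores Candidates x namespaces score matrix (rownames =
#'   candidate IDs, aligned with the interval).
#' @param interval A `linkage_interval`.
#' @param aggregate `"score_mean"` or `"rank_mean"`.
#' @return A `rank_list`: list with `interval`, `ranking` (candidates
#'   best-first), `scores` (final scores, named) and `target_rank`.
#' @export
rank_candidates <- function(namespace_scores, interval,
                            aggregate = c("score_mean", "rank_mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(interval, "linkage_interval"))
  s <- namespace_scores[interval$candidates, , drop = FALSE]
  if (any(!is.finite(s))) stop_validation("non-finite candidate score")
  final <- if (aggregate == "score_mean") {
    rowMeans(s)
  } else {
    # lower mean rank is better; negate so "higher is better" holds below
    -rowMeans(apply(-s, 2L, rank, ties.method = "average"))
  }
  ord <- order(-final, interval$candidates)
  ranking <- interval$candidates[ord]
  structure(list(interval = interval,
                 ranking = ranking,
                 scores = stats::setNames(final, interval$candidates),
                 target_rank = match(interval$target_gene, ranking)),
            class = "rank_list")
}

#' @export
print.rank_list <- function(x, ...) {
  cat("rank_list [", x$interval$disease_id, "]: target ",
      x$interval$target_gene, " ranked ", x$target_rank, "/",
      length(x$ranking), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out evaluation over a disease gene set
#'
#' For every disease gene `u`: `u` is removed from the positive labels, the
#' three namespace models are (re)trained on the remaining seed set, `u`'s
#' artificial linkage interval is built, and its candidates are ranked.
#' Training labels are the remaining seed genes (class `"disease"`) plus an
#' equally sized seeded sample of background genes outside both the disease
#' set and `u`'s interval (class `"other"`).
#'
#' `method = "degree"` replaces the model scores with the candidate's node
#' degree (a guilt-by-association-free baseline). `fast = TRUE` trains the
#' three models once per disease with all disease genes labeled positive and
#' reuses them for every interval; it is an optimistic approximation of the
#' full leave-one-out protocol (the target's label participates in training)
#' and is intended for quick smoke runs only.
#'
#' @param disease_genes Character vector of disease genes (length >= 2).
#' @param features Named list of the three `feature_matrix` objects.
#' @param network A `ppi_network`.
#' @param coords Coordinates data frame.
#' @param config A `model_config`; `config$seed` drives negative sampling
#'   and the per-fit training seeds.
#' @param method `"gcn"` or `"degree"`.
#' @param aggregate Passed to [rank_candidates()].
#' @param negatives_per_positive Background labeled genes per seed gene.
#' @param interval_size Candidate-set size (default 100).
#' @param disease_id Label recorded on intervals.
#' @param fast Train once per disease instead of once per left-out gene.
#' @return List of `rank_list`, one per disease gene.
#' @export
loocv_evaluate <- function(disease_genes, features, network, coords,
                           config = model_config(),
                           method = c("gcn", "degree"),
                           aggregate = "score_mean",
                           negatives_per_positive = 1,
                           interval_size = 100,
                           disease_id = "disease",
                           fast = FALSE) {
  method <- match.arg(method)
  disease_genes <- sort(unique(disease_genes))
  if (length(disease_genes) < 2L)
    stop_validation("disease set must contain at least 2 genes")
  universe <- network$gene_order

  fit_models <- function(positives, exclude, stream) {
    neg_pool <- setdiff(universe, c(disease_genes, exclude))
    n_neg <- min(length(neg_pool),
                 ceiling(length(positives) * negatives_per_positive))
    negs <- with_seed(derive_seed(config$seed, "neg", stream),
                      sample(neg_pool, n_neg))
    labels <- stats::setNames(c(rep("disease", length(positives)),
                                rep("other", length(negs))),
                              c(positives, negs))
    lapply(stats::setNames(nm = names(features)), function(ns) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, "fit", stream, ns)
      train_gcn(features[[ns]], network, labels, cfg)
    })
  }

  shared_models <- if (method == "gcn" && fast)
    fit_models(intersect(disease_genes, universe), character(0), "shared")

  out <- vector("list", length(disease_genes))
  names(out) <- disease_genes
  for (u in disease_genes) {
    seed_set <- setdiff(disease_genes, u)
    interval <- build_linkage_interval(u, coords, seed_set, universe,
                                       size = interval_size,
                                       disease_id = disease_id)
    scores <- if (method == "degree") {
      d <- network$degrees[interval$candidates]
      d[is.na(d)] <- 0
      matrix(rep(as.numeric(d), 3), ncol = 3,
             dimnames = list(interval$candidates, c("MF", "CC", "BP")))
    } else {
      models <- if (fast) shared_models else
        fit_models(intersect(seed_set, universe), interval$candidates, u)
      score_candidates(models, features, network, interval)
    }
    out[[u]] <- rank_candidates(scores, interval, aggregate)
  }
  out
}

#' Target ranks of a list of rank lists
#'
#' @param rank_lists List of `rank_list` objects.
#' @return Integer vector of 1-based target ranks.
#' @export
target_ranks <- function(rank_lists) {
  vapply(rank_lists, function(r) as.integer(r$target_rank), 1L)
}

#' Write rank lists as a tidy TSV
#'
#' One row per (left-out gene, candidate): disease, target, candidate,
#' score, rank.
#'
#' @param rank_lists List of `rank_list` objects.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rank_lists <- function(rank_lists, path) {
  rows <- do.call(rbind, lapply(rank_lists, function(r) {
    data.frame(disease = r$interval$disease_id,
               target = r$interval$target_gene,
               candidate = r$ranking,
               score = unname(r$scores[r$ranking]),
               rank = seq_along(r$ranking))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
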