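#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the two information channels the prioritizer
#' exploits: a planted, densely connected disease module inside an
#' Erdos-Renyi background graph (network channel), and a set of enriched GO
#' terms carried preferentially by disease genes (annotation channel).
#' Setting `p_in = p_out` ablates the network signal; setting
#' `p_term_disease = p_term_background` ablates the annotation signal.
#'
#' @param n_genes Number of genes.
#' @param n_disease Number of planted disease-module genes.
#' @param p_in Edge probability inside the disease module.
#' @param p_out Background edge probability.
#' @param n_terms_per_namespace GO terms per namespace.
#' @param n_enriched_terms Enriched terms per namespace.
#' @param p_term_disease Probability a disease gene carries an enriched term.
#' @param p_term_background Annotation probability for every other
#'   (gene, term) pair.
#' @param chrom_count Number of chromosomes genes are laid out on.
#' @param seed Master seed; every file is bit-for-bit reproducible from it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 300, n_disease = 20,
                           p_in = 0.3, p_out = 0.01,
                           n_terms_per_namespace = 60,
                           n_enriched_terms = 10,
                           p_term_disease = 0.6,
                           p_term_background = 0.05,
                           chrom_count = 3, seed = 42) {
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop_validation("need 0 <= p_out <= p_in <= 1")
  if (!(p_term_background >= 0 && p_term_background <= p_term_disease &&
        p_term_disease <= 1))
    stop_validation("need 0 <= p_term_background <= p_term_disease <= 1")
  if (n_disease >= n_genes) stop_validation("n_disease must be < n_genes")
  if (n_enriched_terms > n_terms_per_namespace)
    stop_validation("n_enriched_terms must be <= n_terms_per_namespace")
  if (chrom_count < 1) stop_validation("chrom_count must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_disease = as.integer(n_disease),
                 p_in = p_in, p_out = p_out,
                 n_terms_per_namespace = as.integer(n_terms_per_namespace),
                 n_enriched_terms = as.integer(n_enriched_terms),
                 p_term_disease = p_term_disease,
                 p_term_background = p_term_background,
                 chrom_count = as.integer(chrom_count),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a seeded synthetic benchmark dataset
#'
#' Writes, into `dir`: `annotations.tsv` (gene, namespace, term),
#' `ppi_edges.tsv` (edge list), `coordinates.bed` (chrom, start, end, gene;
#' genes laid out block-wise on `chrom_count` chromosomes at regular 100 kb
#' offsets with 10 kb bodies), `disease.gmt` (the planted disease gene set)
#' and `manifest.json` recording the ground truth (module members, enriched
#' terms, config). Each component draws from its own substream of the
#' master seed, so outputs are byte-identical across runs.
#'
#' @param config A `fixture_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`
#'   (disease genes and per-namespace enriched terms).
#' @export
generate_fixture <- function(config = fixture_config(), dir) {
  stopifnot(inherits(config, "fixture_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- config$n_genes
  genes <- sprintf("g%0*d", nchar(as.character(n)), seq_len(n))

  disease <- sort(with_seed(derive_seed(config$seed, "disease"),
                            sample(genes, config$n_disease)))
  is_dis <- genes %in% disease

  # --- interaction graph: planted partition -------------------------------
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  p <- ifelse(is_dis[pairs[, 1L]] & is_dis[pairs[, 2L]],
              config$p_in, config$p_out)
  keep <- with_seed(derive_seed(config$seed, "graph"),
                    runif(nrow(pairs)) < p)
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges) == 0L) stop_validation("generated graph has no edges")
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  if (any(deg == 0) && (config$p_in == 0 || config$p_out == 0))
    warning(sum(deg == 0), " isolated gene(s) under a degenerate edge config")
  edge_path <- file.path(dir, "ppi_edges.tsv")
  writeLines(paste(genes[edges[, 1L]], genes[edges[, 2L]], sep = "\t"),
             edge_path)

  # --- annotations: enriched terms on disease genes -----------------------
  namespaces <- c("MF", "CC", "BP")
  enriched <- list()
  ann_lines <- character(0)
  for (ns in namespaces) {
    terms <- sprintf("%s:T%03d", ns, seq_len(config$n_terms_per_namespace))
    enr <- sort(with_seed(derive_seed(config$seed, "enriched", ns),
                          sample(terms, config$n_enriched_terms)))
    enriched[[ns]] <- enr
    pmat <- matrix(config$p_term_background, n, length(terms))
    pmat[is_dis, match(enr, terms)] <- config$p_term_disease
    hit <- with_seed(derive_seed(config$seed, "annot", ns),
                     matrix(runif(length(pmat)) < pmat, n))
    idx <- which(hit, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    ann_lines <- c(ann_lines,
                   paste(genes[idx[, 1L]], ns, terms[idx[, 2L]], sep = "\t"))
  }
  ann_path <- file.path(dir, "annotations.tsv")
  writeLines(ann_lines, ann_path)

  # --- coordinates: regular block layout ----------------------------------
  per_chrom <- ceiling(n / config$chrom_count)
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
  pos <- (seq_len(n) - 1L) %% per_chrom
  start <- pos * 100000L
  coord_path <- file.path(dir, "coordinates.bed")
  writeLines(paste(chrom, start, start + 10000L, genes, sep = "\t"),
             coord_path)

  # --- disease set and manifest -------------------------------------------
  gmt_path <- file.path(dir, "disease.gmt")
  writeLines(paste(c("disease1", "synthetic planted disease module", disease),
                   collapse = "\t"), gmt_path)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(config),
                            disease_genes = disease,
                            enriched_terms = enriched),
                       manifest_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(paths = c(annotations = ann_path, edges = edge_path,
                           coordinates = coord_path, gmt = gmt_path,
                           manifest = manifest_path),
                 truth = list(disease_genes = disease,
                              enriched_terms = enriched)))
}

#' Generate a synthetic diseases x methods AUC table
#'
#' Gaussian AUC-like values `50 + effect + noise`, clipped to `[0, 100]`,
#' for exercising the rank/Friedman statistics with a known method ordering.
#'
#' @param n_diseases Number of rows.
#' @param methods Method names (>= 2).
#' @param effect_sizes Per-method mean shift (recycled to `methods`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed.
#' @return Numeric matrix with a `ground_truth_order` attribute (method
#'   names, best first).
#' @export
generate_score_table <- function(n_diseases, methods, effect_sizes = 0,
                                 noise_sd = 1, seed = 1) {
  if (n_diseases < 2L || length(methods) < 2L)
    stop_validation("need >= 2 diseases and >= 2 methods")
  effect_sizes <- rep_len(effect_sizes, length(methods))
  m <- with_seed(derive_seed(seed, "scoretable"), {
    vals <- 50 + matrix(effect_sizes, n_diseases, length(methods),
                        byrow = TRUE) +
      matrix(rnorm(n_diseases * length(methods), sd = noise_sd),
             n_diseases)
    pmin(pmax(vals, 0), 100)
  })
  dimnames(m) <- list(sprintf("disease%02d", seq_len(n_diseases)), methods)
  attr(m, "ground_truth_order") <- methods[order(-effect_sizes)]
  m
}
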