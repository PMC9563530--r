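#' Threshold-rank ROC AUC over a set of rank lists
#'
#' For rank cutoffs `t = 0..max_threshold`, sensitivity is the percentage of
#' lists whose target gene is ranked at or above the cutoff, and the
#' false-positive rate is the mean fraction of the 99 non-target candidates
#' ranked at or above it. The AUC is the trapezoidal area under the
#' (FPR, sensitivity) curve, normalized by the FPR span so that a method
#' ranking every target first scores exactly 100 and uniform-random ranking
#' scores about 50. Returned in percent.
#'
#' The truncated curve (small `max_threshold`) is an operating-range
#' measure: only the full sweep (`max_threshold = interval_size - 1`, the
#' default) has the usual 50%-for-random calibration, which is what the
#' null-behaviour checks use.
#'
#' @param rank_lists List of `rank_list` objects, or an integer vector of
#'   target ranks.
#' @param max_threshold Largest rank cutoff `T` (at most
#'   `interval_size - 1`, the default: the full sweep).
#' @param interval_size Candidate-set size (default 100).
#' @return AUC in percent.
#' @export
threshold_auc <- function(rank_lists, max_threshold = interval_size - 1,
                          interval_size = 100) {
  ranks <- if (is.numeric(rank_lists)) as.integer(rank_lists) else
    target_ranks(rank_lists)
  if (length(ranks) == 0L) stop_validation("no rank lists")
  if (max_threshold < 1 || max_threshold > interval_size - 1L)
    stop_validation("max_threshold must lie in 1..", interval_size - 1L)
  if (any(ranks < 1L | ranks > interval_size))
    stop_validation("target rank outside 1..", interval_size)
  t <- 0:max_threshold
  sens <- vapply(t, function(tt) 100 * mean(ranks <= tt), 0)
  fpr <- vapply(t, function(tt) mean((tt - (ranks <= tt)) / (interval_size - 1L)), 0)
  span <- fpr[length(fpr)] - fpr[1L]
  if (span <= 0) stop_validation("degenerate FPR span")
  sum(diff(fpr) * (head(sens, -1L) + tail(sens, -1L)) / 2) / span
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = 100 * tp / (tp + fp)`, `recall = 100 * tp / (tp + fn)`,
#' `F1 = 2 p r / (p + r)`.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return Named numeric vector `c(precision, recall, f1)`, each in percent.
#' @export
precision_recall_f1 <- function(tp, fp, tn = 0, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("confusion counts must be nonnegative integers")
  if (tp + fp == 0) stop_validation("precision undefined: tp + fp = 0")
  if (tp + fn == 0) stop_validation("recall undefined: tp + fn = 0")
  p <- 100 * tp / (tp + fp)
  r <- 100 * tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

check_score_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop_validation("score table must be numeric")
  if (anyNA(m)) stop_validation("score table has missing cells")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_validation("score table needs >= 2 rows and >= 2 columns")
  m
}

rank_rows <- function(m, higher_is_better) {
  if (higher_is_better) m <- -m
  t(apply(m, 1L, rank))                  # average ranks on ties
}

#' Per-method mean ranks across diseases
#'
#' Within each row (disease), methods are ranked 1 = best; ties receive
#' average ranks. Column means are returned; they always sum to
#' `k (k + 1) / 2`.
#'
#' @param table Numeric diseases x methods matrix (or data frame).
#' @param higher_is_better Rank 1 goes to the highest value (TRUE, default)
#'   or the lowest.
#' @return Named numeric vector of mean ranks.
#' @export
friedman_mean_ranks <- function(table, higher_is_better = TRUE) {
  m <- check_score_table(table)
  colMeans(rank_rows(m, higher_is_better))
}

#' Friedman omnibus chi-square test across methods
#'
#' With within-row rank sums `R_j` over `n` rows and `k` methods, the
#' statistic is `12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)`, divided by the
#' tie-correction factor `1 - sum(t^3 - t) / (n k (k^2 - 1))` when ties are
#' present; `df = k - 1` and the p-value comes from the chi-square upper
#' tail (the usual large-sample approximation).
#'
#' @inheritParams friedman_mean_ranks
#' @return List with `statistic`, `df`, `p_value`, `mean_ranks`.
#' @export
friedman_chi_square <- function(table, higher_is_better = TRUE) {
  m <- check_score_table(table)
  r <- rank_rows(m, higher_is_better)
  n <- nrow(m); k <- ncol(m)
  Rj <- colSums(r)
  chi <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(r, 1L, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  })
  corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (corr <= 0) {
    # all rows fully tied: no evidence of any difference
    chi <- 0
  } else {
    chi <- chi / corr
  }
  list(statistic = chi, df = k - 1L,
       p_value = stats::pchisq(chi, k - 1L, lower.tail = FALSE),
       mean_ranks = colMeans(r))
}

#' Read a diseases x methods AUC table from CSV
#'
#' First column = disease names (row labels), remaining columns = methods.
#' Values are AUC percentages in `[0, 100]`; missing cells are an error.
#'
#' @param path CSV path.
#' @return Numeric matrix with disease rownames and method colnames.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop_validation("score table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_parse("score table needs a label column and >= 2 methods")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!is.numeric(m)) stop_parse("non-numeric cells in score table")
  if (anyNA(m)) stop_validation("score table has missing cells")
  if (any(m < 0 | m > 100)) stop_validation("AUC values must lie in [0, 100]")
  m
}

#' Read disease gene sets from a GMT file
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop_parse("malformed GMT line ", bad[1L], ": need name, description, genes")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}
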