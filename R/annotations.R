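#' Read gene -> GO term annotations
#'
#' Parses gene annotations from either a simple 3-column TSV
#' (`gene`, `namespace`, `term`, with namespace one of `MF`, `CC`, `BP`) or a
#' GAF 2.x association file (tab-separated, `!`-prefixed comment lines
#' skipped; column 2 is the gene identifier, column 5 the GO term, column 9
#' the aspect, mapped `F` -> `MF`, `C` -> `CC`, `P` -> `BP`).
#'
#' Duplicate (gene, term) rows collapse to a single set element. Evidence
#' codes are not filtered and no ancestor propagation is performed: the
#' feature encoding tests raw membership in the directly annotated term sets.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return An object of class `gene_annotations`: a named list of gene
#'   records, each a list with `gene_id`, `mf_terms`, `cc_terms`, `bp_terms`
#'   (character vectors, possibly empty). Gene order follows first
#'   appearance in the file.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gaf") lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(list(), class = "gene_annotations"))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(vapply(fields, length, 1L) < 3L)
    if (length(bad))
      stop_parse("malformed annotation row at line ", bad[1L],
                 ": expected 3 tab-separated columns (gene, namespace, term)")
    gene <- vapply(fields, `[[`, "", 1L)
    ns   <- vapply(fields, `[[`, "", 2L)
    term <- vapply(fields, `[[`, "", 3L)
  } else {
    bad <- which(vapply(fields, length, 1L) < 9L)
    if (length(bad))
      stop_parse("malformed GAF row at line ", bad[1L],
                 ": expected >= 9 tab-separated columns")
    gene <- vapply(fields, `[[`, "", 2L)
    asp  <- vapply(fields, `[[`, "", 9L)
    term <- vapply(fields, `[[`, "", 5L)
    ns <- c(F = "MF", C = "CC", P = "BP")[asp]
    if (anyNA(ns))
      stop_validation("unknown GAF aspect code '", asp[which(is.na(ns))[1L]],
                      "' (expected F, P or C)")
  }
  if (!all(ns %in% c("MF", "CC", "BP")))
    stop_validation("unknown namespace '", setdiff(ns, c("MF", "CC", "BP"))[1L],
                    "' (expected MF, CC or BP)")
  if (any(!nzchar(gene)) || any(!nzchar(term)))
    stop_parse("blank gene or term identifier in annotation file")

  genes <- unique(gene)
  ann <- lapply(genes, function(g) {
    sel <- gene == g
    list(gene_id  = g,
         mf_terms = sort(unique(term[sel & ns == "MF"])),
         cc_terms = sort(unique(term[sel & ns == "CC"])),
         bp_terms = sort(unique(term[sel & ns == "BP"])))
  })
  names(ann) <- genes
  structure(ann, class = "gene_annotations")
}

#' @export
print.gene_annotations <- function(x, ...) {
  cat("gene_annotations:", length(x), "genes\n")
  if (length(x)) {
    n <- vapply(x, function(a)
      length(a$mf_terms) + length(a$cc_terms) + length(a$bp_terms), 1L)
    cat("  terms per gene: median", stats::median(n), "max", max(n), "\n")
  }
  invisible(x)
}

ns_field <- c(MF = "mf_terms", CC = "cc_terms", BP = "bp_terms")

#' Build the ordered term catalog for one GO namespace
#'
#' The catalog is the union of the namespace's term sets over all annotated
#' genes, ordered lexicographically so the column layout of the feature
#' matrices is reproducible.
#'
#' @param annotations A `gene_annotations` object.
#' @param namespace One of `"MF"`, `"CC"`, `"BP"`.
#' @return A `term_catalog`: list with `namespace`, `terms` (sorted unique
#'   character vector) and `padded_length` (initially `length(terms)`).
#' @export
build_term_catalog <- function(annotations, namespace = c("MF", "CC", "BP")) {
  namespace <- match.arg(namespace)
  if (length(annotations) == 0L)
    stop_validation("annotations must be non-empty")
  terms <- sort(unique(unlist(lapply(annotations, `[[`, ns_field[[namespace]]),
                              use.names = FALSE)))
  if (length(terms) == 0L)
    warning("no ", namespace, " terms found; catalog is empty")
  structure(list(namespace = namespace, terms = terms,
                 padded_length = length(terms)),
            class = "term_catalog")
}

#' Build the three binary GO feature matrices
#'
#' One row per gene in `gene_order`, one column per catalog term; entry
#' (i, j) is 1 iff gene i's namespace term set contains catalog term j.
#' All three matrices share the same column count `m`, the size of the
#' largest namespace catalog; shorter catalogs are zero-padded on the right
#' so the indicator semantics of the occupied columns are preserved.
#'
#' Genes in `gene_order` without an annotation record get all-zero rows (the
#' interaction network may contain unannotated genes).
#'
#' @param annotations A `gene_annotations` object.
#' @param gene_order Character vector of gene IDs fixing the row order.
#' @return Named list `list(MF = , CC = , BP = )` of `feature_matrix`
#'   objects. Each holds `namespace`, `gene_order`, `values` (sparse binary
#'   `dgCMatrix`, genes x m) and `catalog`.
#' @export
build_feature_matrices <- function(annotations, gene_order) {
  if (length(gene_order) == 0L) stop_validation("gene_order is empty")
  if (anyDuplicated(gene_order)) stop_validation("gene_order has duplicates")
  catalogs <- lapply(c(MF = "MF", CC = "CC", BP = "BP"), function(ns)
    build_term_catalog(annotations, ns))
  m <- max(vapply(catalogs, function(ct) length(ct$terms), 1L))
  missing <- setdiff(gene_order, names(annotations))
  if (length(missing))
    message(length(missing), " gene(s) without annotation records; ",
            "their feature rows are all-zero")
  out <- lapply(catalogs, function(ct) {
    ct$padded_length <- m
    field <- ns_field[[ct$namespace]]
    ii <- integer(0); jj <- integer(0)
    for (i in seq_along(gene_order)) {
      a <- annotations[[gene_order[[i]]]]
      if (is.null(a)) next
      j <- match(a[[field]], ct$terms)
      j <- j[!is.na(j)]
      ii <- c(ii, rep.int(i, length(j))); jj <- c(jj, j)
    }
    values <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                   dims = c(length(gene_order), m),
                                   dimnames = list(gene_order, NULL))
    structure(list(namespace = ct$namespace, gene_order = gene_order,
                   values = values, catalog = ct),
              class = "feature_matrix")
  })
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix [", x$namespace, "]: ",
      nrow(x$values), " genes x ", ncol(x$values), " columns (",
      length(x$catalog$terms), " terms, ",
      ncol(x$values) - length(x$catalog$terms), " zero-padding)\n", sep = "")
  invisible(x)
}

#' Write a feature matrix as Matrix Market plus sidecar TSVs
#'
#' Writes `<prefix>.mtx` (sparse values), `<prefix>.genes.tsv` (row order)
#' and `<prefix>.terms.tsv` (column order; padding columns have empty term
#' labels).
#'
#' @param fm A `feature_matrix`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  paths <- paste0(prefix, c(".mtx", ".genes.tsv", ".terms.tsv"))
  Matrix::writeMM(fm$values, paths[[1L]])
  writeLines(fm$gene_order, paths[[2L]])
  terms <- c(fm$catalog$terms,
             rep("", ncol(fm$values) - length(fm$catalog$terms)))
  writeLines(terms, paths[[3L]])
  invisible(paths)
}
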