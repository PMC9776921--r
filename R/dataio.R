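# Readers and writers for the plain-text formats the pipeline touches.
#
# Canonical dialect is tab-separated text. Gene identifiers are opaque,
# case-sensitive strings; no probe/symbol mapping is attempted. Missing
# values in expression input are rejected rather than imputed.

# ---- expression matrices ----------------------------------------------------

.validate_expression <- function(mat, context = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    .fail("%s must be a numeric matrix", context)
  genes <- rownames(mat)
  samples <- colnames(mat)
  if (is.null(genes) || is.null(samples))
    .fail("%s must have gene row names and sample column names", context)
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    .fail("duplicate gene identifier(s): %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    .fail("duplicate sample identifier(s): %s", paste(dup_s, collapse = ", "))
  if (nrow(mat) < 2L || ncol(mat) < 4L)
    .fail("%s needs at least 2 genes and 4 samples (got %d x %d)",
          context, nrow(mat), ncol(mat))
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    .fail("non-finite value at gene '%s', sample '%s'",
          genes[bad[1L]], samples[bad[2L]])
  }
  invisible(mat)
}

#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' Expects genes in rows and samples in columns: the first column holds gene
#' identifiers and the first row sample identifiers. Values must parse as
#' finite numbers ("NA" is rejected, not imputed). Row and column order are
#' preserved from the file.
#'
#' @param path path to a TSV file.
#' @return a numeric matrix with gene row names and sample column names.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) .fail("expression file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) .fail("expression file needs a gene column plus samples")
  genes <- df[[1L]]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, colnames(df)[-1L]))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    .fail("non-numeric or missing value at row %d (gene '%s'), column %d ('%s')",
          bad[1L, 1L], genes[bad[1L, 1L]],
          bad[1L, 2L] + 1L, colnames(df)[-1L][bad[1L, 2L]])
  }
  rownames(vals) <- genes
  .validate_expression(vals, sprintf("expression file '%s'", path))
}

#' Write an expression matrix as tab-separated text
#'
#' @param mat numeric matrix, genes in rows, samples in columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  .validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample labels ----------------------------------------------------------

#' Construct a sample-label table
#'
#' Maps each sample to one of two conditions, "A" or "B" (e.g. non-plaque vs
#' plaque tissue, or early vs advanced lesions). Both conditions must carry at
#' least 3 samples.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param conditions character vector of "A"/"B", parallel to `sample_ids`.
#' @param condition_names optional display names, e.g.
#'   `c(A = "early", B = "advanced")`.
#' @return a `sample_labels` data frame with columns `sample_id`, `condition`.
#' @export
sample_labels <- function(sample_ids, conditions,
                          condition_names = c(A = "A", B = "B")) {
  if (length(sample_ids) != length(conditions))
    .fail("sample_ids and conditions must have equal length")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) .fail("duplicate sample identifier(s): %s",
                         paste(dup, collapse = ", "))
  if (!all(conditions %in% c("A", "B")))
    .fail("conditions must be 'A' or 'B'")
  tab <- table(factor(conditions, levels = c("A", "B")))
  if (any(tab < 3L))
    .fail("both conditions need >= 3 samples (got A = %d, B = %d)",
          tab[["A"]], tab[["B"]])
  out <- data.frame(sample_id = as.character(sample_ids),
                    condition = as.character(conditions),
                    stringsAsFactors = FALSE)
  attr(out, "condition_names") <- condition_names
  class(out) <- c("sample_labels", "data.frame")
  out
}

#' Samples belonging to one condition
#'
#' @param labels a [sample_labels()] table.
#' @param condition "A" or "B".
#' @return character vector of sample ids.
#' @export
condition_samples <- function(labels, condition) {
  stopifnot(inherits(labels, "sample_labels"))
  labels$sample_id[labels$condition == condition]
}

#' Read sample labels from two-column tab-separated text
#'
#' Columns: `sample_id`, `condition` (values "A"/"B"), with a header line.
#'
#' @param path path to the labels TSV.
#' @return a `sample_labels` table.
#' @export
read_sample_labels <- function(path) {
  if (!file.exists(path)) .fail("labels file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) .fail("labels file needs columns sample_id, condition")
  sample_labels(df[[1L]], df[[2L]])
}

#' Write sample labels as tab-separated text
#' @param labels a [sample_labels()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sample_labels"))
  utils::write.table(as.data.frame(labels)[c("sample_id", "condition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check that a labels table matches an expression matrix
.check_labels_match <- function(mat, labels) {
  missing_in_mat <- setdiff(labels$sample_id, colnames(mat))
  if (length(missing_in_mat))
    .fail("labeled sample(s) absent from matrix: %s",
          paste(missing_in_mat, collapse = ", "))
  unlabeled <- setdiff(colnames(mat), labels$sample_id)
  if (length(unlabeled))
    .fail("unlabeled sample(s) in matrix: %s",
          paste(unlabeled, collapse = ", "))
  invisible(TRUE)
}

# ---- gene-set catalogs (GMT) ------------------------------------------------

#' Construct a gene-set catalog
#'
#' @param sets named list of character vectors (members); names are set names.
#' @param descriptions optional character vector parallel to `sets`.
#' @param namespace free-text tag, e.g. "GOBP-like" or "KEGG-like".
#' @return a `gene_set_catalog` object.
#' @export
gene_set_catalog <- function(sets, descriptions = NULL, namespace = "custom") {
  if (is.null(names(sets)) && length(sets))
    .fail("gene sets must be named")
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) .fail("duplicate set name(s): %s", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) < 1L)) .fail("every set needs >= 1 member")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = setNames(as.character(descriptions), names(sets)),
                 namespace = namespace),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d sets (%s), sizes %s\n",
              length(x$sets), x$namespace,
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Read a gene-set catalog in GMT format
#'
#' Each line is `name TAB description TAB member TAB member ...`. Duplicate
#' members within a line are collapsed; a line with fewer than 3 fields is a
#' parse error. An empty file yields an empty catalog with a warning.
#'
#' @param path path to a GMT file.
#' @param namespace tag stored on the catalog.
#' @return a [gene_set_catalog()].
#' @export
read_gmt <- function(path, namespace = "custom") {
  if (!file.exists(path)) .fail("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_catalog(setNames(list(), character(0)),
                            namespace = namespace))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .fail("GMT parse error at line %d: fewer than 3 fields", short[1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  descr <- vapply(fields, `[[`, character(1), 2L)
  gene_set_catalog(sets, descr, namespace)
}

#' Write a gene-set catalog in GMT format
#' @param catalog a [gene_set_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, catalog$descriptions[[nm]], catalog$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- PPI edge lists ---------------------------------------------------------

#' Construct an undirected protein-protein interaction graph
#'
#' Reversed duplicate edges are merged and self-loops dropped (with a message
#' giving the count). Edges are stored once with endpoints in sorted order.
#'
#' @param from,to character vectors of endpoint gene ids.
#' @param score optional numeric confidence per edge.
#' @return a `ppi_graph` data frame with columns `from`, `to` (and `score`).
#' @export
ppi_graph <- function(from, to, score = NULL) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) .fail("from/to must have equal length")
  loops <- from == to
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  keep <- !loops
  from <- from[keep]; to <- to[keep]
  if (!is.null(score)) score <- score[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(from = a[first], to = b[first], stringsAsFactors = FALSE)
  if (!is.null(score)) out$score <- as.numeric(score)[first]
  class(out) <- c("ppi_graph", "data.frame")
  out
}

#' Read an undirected edge list from tab-separated text
#'
#' Two or three tab-separated columns (node, node, optional numeric score),
#' no header. See [ppi_graph()] for deduplication rules.
#'
#' @param path path to the edge-list file.
#' @return a [ppi_graph()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) .fail("edge list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(ppi_graph(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    .fail("edge-list parse error at line %d: expected 2-3 fields, got %d",
          bad[1L], nf[bad[1L]])
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  score <- NULL
  if (all(nf == 3L)) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(score))
      .fail("edge-list parse error at line %d: non-numeric score",
            which(is.na(score))[1L])
  }
  ppi_graph(from, to, score)
}

#' Write an undirected edge list as tab-separated text
#' @param graph a [ppi_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "ppi_graph"))
  utils::write.table(as.data.frame(graph), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Node degrees of a PPI graph
#' @param graph a [ppi_graph()].
#' @return named integer vector of degrees (nodes with >= 1 edge).
#' @export
ppi_degree <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!nrow(graph)) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(graph[, c("from", "to")], directed = FALSE)
  d <- igraph::degree(g)
  setNames(as.integer(d), names(d))
}
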