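# Weighted co-expression network core: variance filter, soft-threshold
# selection, unsigned adjacency, topological overlap, hierarchical module
# detection with eigengene merging, module eigengenes and kME module
# membership.

#' Keep the most variable genes
#'
#' Retains the `ceiling(keep_fraction * G)` genes of highest sample
#' variance, with ties at the cut broken in favour of the lexicographically
#' smaller gene id. Row order of surviving genes is preserved.
#'
#' @param expr genes x samples matrix.
#' @param keep_fraction fraction of genes to keep, in (0, 1].
#' @return the filtered expression matrix.
#' @export
variance_filter <- function(expr, keep_fraction = 0.75) {
  .validate_expression(expr)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    .fail("keep_fraction must lie in (0, 1]")
  G <- nrow(expr)
  n_keep <- ceiling(keep_fraction * G)
  if (n_keep < 2L) .fail("fewer than 2 genes would survive the filter")
  v <- apply(expr, 1L, var)
  ord <- order(-v, rownames(expr))
  keep <- sort(ord[seq_len(n_keep)])
  expr[keep, , drop = FALSE]
}

#' Unsigned weighted adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta (Pearson), with the diagonal set to 0 for
#' downstream topological-overlap and connectivity computations.
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold exponent (>= 1).
#' @return symmetric genes x genes matrix with values in `[0, 1]`, zero
#'   diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 6) {
  .validate_expression(expr)
  if (!is.numeric(beta) || beta < 1) .fail("beta must be >= 1")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0))
    .fail("constant gene(s) have undefined correlation: %s",
          paste(head(rownames(expr)[sds == 0], 5L), collapse = ", "))
  a <- abs(cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj and k_i = sum_u a_iu; TOM_ii = 1. The topological
#' overlap credits shared neighbours, robustifying the raw adjacency.
#'
#' @param adj symmetric adjacency with zero diagonal, values in `[0, 1]`.
#' @return the TOM similarity matrix (dissimilarity is `1 - TOM`).
#' @export
topological_overlap <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    .fail("adjacency must be a square matrix")
  if (max(abs(adj - t(adj))) > 1e-12) .fail("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1)) .fail("adjacency values must lie in [0, 1]")
  if (any(diag(adj) != 0)) .fail("adjacency diagonal must be 0")
  l <- adj %*% adj
  k <- colSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Pick the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the adjacency, computes the
#' connectivity k_i = sum_j a_ij, and fits log10 frequency against log10
#' mean connectivity over equal-width connectivity bins (the standard
#' scale-free fit index). The signed fit index is -sign(slope) * R^2; the
#' smallest power reaching `r2_target` is returned, otherwise the argmax
#' with a warning.
#'
#' @param expr genes x samples matrix (>= 50 genes).
#' @param candidate_powers integer powers to scan.
#' @param r2_target signed R^2 considered sufficient (default 0.8).
#' @param n_bins number of equal-count connectivity bins.
#' @return the chosen power, with the per-power fit table in attribute
#'   `"fit"`.
#' @export
pick_soft_power <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                            r2_target = 0.8, n_bins = 10) {
  .validate_expression(expr)
  if (nrow(expr) < 50L) .fail("need >= 50 genes to assess scale-free fit")
  r2 <- vapply(candidate_powers, function(b) {
    k <- colSums(adjacency_matrix(expr, b))
    .scale_free_r2(k, n_bins)
  }, numeric(1))
  fit <- data.frame(power = candidate_powers, signed_r2 = r2)
  ok <- which(r2 >= r2_target)
  choice <- if (length(ok)) candidate_powers[ok[1L]] else {
    warning(sprintf("no candidate power reaches signed R^2 >= %.2f; using %d",
                    r2_target, candidate_powers[which.max(r2)]))
    candidate_powers[which.max(r2)]
  }
  structure(choice, fit = fit)
}

.scale_free_r2 <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  bin <- cut(k, n_bins, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(kmean) & freq > 0
  if (sum(keep) < 3L) return(0)
  fitlm <- lm(log10(freq[keep]) ~ log10(kmean[keep]))
  -sign(coef(fitlm)[2L]) * summary(fitlm)$r.squared
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity; initial
#' modules come from a static cut of the tree at `cut_height` (on the
#' dissimilarity scale), clusters smaller than `min_module_size` are
#' relabelled 0 (background), and modules whose eigengene dissimilarity
#' (1 - correlation of eigengenes) falls below `merge_cut` are merged
#' iteratively. Final labels are renumbered by decreasing module size.
#'
#' @param expr genes x samples matrix (rows must match the dissimilarity).
#' @param dissim symmetric gene x gene dissimilarity, usually `1 - TOM`.
#' @param min_module_size smallest retained module (default 30).
#' @param merge_cut eigengene-dissimilarity merge threshold (default 0.25).
#' @param cut_height static tree-cut height (default 0.99).
#' @return a `module_partition`: `labels` (named integers, 0 = background),
#'   `dendrogram` (hclust), `module_sizes`.
#' @export
detect_modules <- function(expr, dissim, min_module_size = 30,
                           merge_cut = 0.25, cut_height = 0.99) {
  .validate_expression(expr)
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim))
    .fail("dissimilarity must be a square matrix")
  if (nrow(dissim) != nrow(expr))
    .fail("dissimilarity and expression disagree on gene count")
  if (merge_cut <= 0 || merge_cut >= 1) .fail("merge_cut must lie in (0, 1)")
  tree <- hclust(as.dist(dissim), method = "average")
  labs <- if (max(tree$height) <= cut_height) {
    warning("all genes merge below the cut height; single module returned")
    setNames(rep(1L, nrow(expr)), rownames(expr))
  } else setNames(cutree(tree, h = cut_height), rownames(expr))
  sizes <- table(labs)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  labs[labs %in% small] <- 0L
  if (all(labs == 0L)) {
    warning("no cluster reaches min_module_size; all genes unassigned")
    part <- list(labels = labs, dendrogram = tree,
                 module_sizes = integer(0))
    class(part) <- "module_partition"
    return(part)
  }
  labs <- .renumber_labels(labs)
  labs <- .merge_close_modules(expr, labs, merge_cut)
  labs <- .renumber_labels(labs)
  part <- list(labels = labs, dendrogram = tree,
               module_sizes = as.integer(table(labs[labs > 0L])))
  class(part) <- "module_partition"
  part
}

# renumber module labels 1..M by decreasing size (ties: older label first)
.renumber_labels <- function(labs) {
  mods <- sort(unique(labs[labs > 0L]))
  if (!length(mods)) return(labs)
  sizes <- vapply(mods, function(m) sum(labs == m), integer(1))
  new_order <- mods[order(-sizes, mods)]
  out <- labs
  for (i in seq_along(new_order)) out[labs == new_order[i]] <- i
  out
}

# iteratively merge module pairs with eigengene dissimilarity < merge_cut
.merge_close_modules <- function(expr, labs, merge_cut) {
  repeat {
    mods <- sort(unique(labs[labs > 0L]))
    if (length(mods) < 2L) return(labs)
    part <- structure(list(labels = labs), class = "module_partition")
    me <- module_eigengenes(expr, part)$eigengenes
    d <- 1 - cor(me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (d[idx[1L], idx[2L]] >= merge_cut) return(labs)
    keep <- min(mods[idx]); drop <- max(mods[idx])
    labs[labs == drop] <- keep
  }
}

#' @export
print.module_partition <- function(x, ...) {
  n0 <- sum(x$labels == 0L)
  cat(sprintf("module_partition: %d modules over %d genes (%d unassigned)\n",
              length(x$module_sizes), length(x$labels), n0))
  if (length(x$module_sizes))
    cat("  sizes:", paste(x$module_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Module eigengenes
#'
#' Per module, genes are standardised (zero mean, unit variance across
#' samples) and the eigengene is the first right singular vector of the
#' module submatrix — the first principal component of the module's
#' expression, one value per sample, unit norm. Its sign is oriented so the
#' mean correlation with the member genes is non-negative.
#'
#' @param expr genes x samples matrix.
#' @param partition a [detect_modules()] result (labels over `expr` rows).
#' @return an `eigengene_matrix`: `eigengenes` (samples x modules, columns
#'   `ME1`, `ME2`, ...) and `var_explained` per module.
#' @export
module_eigengenes <- function(expr, partition) {
  stopifnot(inherits(partition, "module_partition"))
  labs <- partition$labels
  mods <- sort(unique(labs[labs > 0L]))
  if (!length(mods)) .fail("partition has no modules")
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labs)[labs == mods[i]]
    if (length(genes) < 2L)
      .fail("module %d has fewer than 2 genes", mods[i])
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1L, sd)
    if (any(sds == 0))
      .fail("zero-variance gene in module %d: %s", mods[i],
            names(sds)[sds == 0][1L])
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    if (mean(cor(v, t(X))) < 0) v <- -v
    me[, i] <- v
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve),
            class = "eigengene_matrix")
}

#' Module-membership (kME) table
#'
#' Pearson correlation of every gene with every module eigengene. A gene is
#' a hub when the absolute correlation with its own module's eigengene
#' exceeds `hub_threshold`.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes a [module_eigengenes()] result.
#' @param partition the matching [detect_modules()] partition.
#' @param hub_threshold |kME| hub cutoff (default 0.85).
#' @return a `kme_table`: `kme` (genes x modules matrix), `own_module`,
#'   `own_kme`, logical `hub`, and the threshold.
#' @export
kme <- function(expr, eigengenes, partition, hub_threshold = 0.85) {
  stopifnot(inherits(eigengenes, "eigengene_matrix"),
            inherits(partition, "module_partition"))
  me <- eigengenes$eigengenes
  if (!identical(rownames(me), colnames(expr)))
    .fail("eigengenes and expression disagree on samples")
  km <- cor(t(expr), me)
  labs <- partition$labels[rownames(expr)]
  own <- rep(NA_real_, nrow(expr))
  has <- !is.na(labs) & labs > 0L
  col_of <- match(paste0("ME", labs[has]), colnames(me))
  own[has] <- km[cbind(which(has), col_of)]
  structure(list(kme = km,
                 own_module = setNames(labs, rownames(expr)),
                 own_kme = setNames(own, rownames(expr)),
                 hub = setNames(!is.na(own) & abs(own) > hub_threshold,
                                rownames(expr)),
                 hub_threshold = hub_threshold),
            class = "kme_table")
}

#' Fit a weighted co-expression network end to end
#'
#' Convenience wrapper: variance filter, soft power (fixed or "auto" via
#' [pick_soft_power()]), adjacency, TOM, module detection, eigengenes and
#' kME.
#'
#' @param expr genes x samples matrix.
#' @param beta soft power (integer) or "auto".
#' @param keep_fraction variance-filter fraction.
#' @param min_module_size,merge_cut,cut_height see [detect_modules()].
#' @param hub_threshold see [kme()].
#' @return a `coexpression_network` with the filtered matrix, power used,
#'   `partition`, `eigengenes` and `kme`.
#' @export
fit_coexpression_network <- function(expr, beta = 6, keep_fraction = 0.75,
                                     min_module_size = 30, merge_cut = 0.25,
                                     cut_height = 0.99, hub_threshold = 0.85) {
  filtered <- variance_filter(expr, keep_fraction)
  if (identical(beta, "auto")) beta <- as.integer(pick_soft_power(filtered))
  adj <- adjacency_matrix(filtered, beta)
  tom <- topological_overlap(adj)
  partition <- detect_modules(filtered, 1 - tom,
                              min_module_size = min_module_size,
                              merge_cut = merge_cut, cut_height = cut_height)
  if (length(partition$module_sizes)) {
    eig <- module_eigengenes(filtered, partition)
    km <- kme(filtered, eig, partition, hub_threshold)
  } else {
    eig <- NULL; km <- NULL
  }
  structure(list(expr = filtered, beta = beta, partition = partition,
                 eigengenes = eig, kme = km),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes x %d samples, beta = %d\n",
              nrow(x$expr), ncol(x$expr), x$beta))
  print(x$partition)
  invisible(x)
}
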