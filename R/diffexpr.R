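# Two-group differential expression, BH adjustment, top-K pattern selection
# and the cross-cohort common-gene intersection.
#
# The default test is Welch's two-sample t on the provided (log2) scale —
# appropriate for continuous microarray-style intensities. The log2 fold
# change is mean(B) - mean(A).

#' Two-group differential expression test (Welch's t)
#'
#' Per gene: Welch two-sample t statistic, Welch-Satterthwaite degrees of
#' freedom and two-sided p, plus the log2 fold change mean(B) - mean(A).
#' Genes with zero variance in both groups and equal means get statistic 0
#' and p = 1. P-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param expr genes x samples numeric matrix (log2 scale).
#' @param labels a [sample_labels()] table covering every sample.
#' @return a `de_result` data frame with one row per input gene, in input
#'   order: `gene_id`, `log2fc`, `statistic`, `p_value`, `adj_p`.
#' @export
two_group_test <- function(expr, labels) {
  .validate_expression(expr)
  stopifnot(inherits(labels, "sample_labels"))
  .check_labels_match(expr, labels)
  sA <- condition_samples(labels, "A")
  sB <- condition_samples(labels, "B")
  nA <- length(sA); nB <- length(sB)
  if (nA < 3L || nB < 3L)
    .fail("both groups need >= 3 samples (got A = %d, B = %d)", nA, nB)
  XA <- expr[, sA, drop = FALSE]
  XB <- expr[, sB, drop = FALSE]
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  vA <- rowSums((XA - mA)^2) / (nA - 1)
  vB <- rowSums((XB - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  diff <- mB - mA
  stat <- ifelse(se2 > 0, diff / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * pt(-abs(stat), df), 1)
  degenerate <- se2 == 0 & diff != 0
  stat[degenerate] <- sign(diff[degenerate]) * Inf
  p[degenerate] <- 0
  out <- data.frame(gene_id = rownames(expr), log2fc = diff,
                    statistic = stat, p_value = p,
                    adj_p = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: adjusted
#' values are monotone non-decreasing in sorted order, capped at 1, and
#' returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) .fail("p must be numeric")
  if (any(!is.finite(p) | p < 0 | p > 1))
    .fail("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select the top-k significant genes in one direction
#'
#' Keeps genes with sign-consistent log2 fold change (up: > 0, down: < 0)
#' and adjusted p below `alpha`, ranked by adjusted p ascending with ties
#' broken by |log2FC| descending then gene id, truncated at `k`. May return
#' fewer than `k` genes; an empty result warns.
#'
#' @param de a [two_group_test()] result.
#' @param k maximum number of genes (default 500).
#' @param direction "up" or "down".
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of gene ids in rank order.
#' @export
select_top_k <- function(de, k = 500, direction = c("up", "down"),
                         alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  direction <- match.arg(direction)
  if (!.is_count(k) || k < 1) .fail("k must be a positive integer")
  keep <- de$adj_p < alpha &
    (if (direction == "up") de$log2fc > 0 else de$log2fc < 0)
  sub <- de[keep, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no ", direction, "-regulated gene passes adjusted p < ", alpha)
    return(character(0))
  }
  ord <- order(sub$adj_p, -abs(sub$log2fc), sub$gene_id)
  head(sub$gene_id[ord], k)
}

#' Genes meeting the DEG definition
#'
#' Adjusted p below `alpha` and fold change above `fc_threshold`
#' (|log2FC| > log2(fc_threshold)).
#'
#' @param de a [two_group_test()] result.
#' @param alpha adjusted-p threshold.
#' @param fc_threshold fold-change threshold on the linear scale (default 2).
#' @return character vector of gene ids.
#' @export
deg_genes <- function(de, alpha = 0.05, fc_threshold = 2) {
  stopifnot(inherits(de, "de_result"))
  de$gene_id[de$adj_p < alpha & abs(de$log2fc) > log2(fc_threshold)]
}

#' Cross-cohort common-pattern genes
#'
#' Intersects the per-cohort top-k up and down lists: the genes consistently
#' regulated in the same direction across both cohorts.
#'
#' @param listsA,listsB lists with components `up` and `down` (outputs of
#'   [select_top_k()] on the two cohorts).
#' @return a `common_gene_lists` object with sorted `common_up`,
#'   `common_down` and a `provenance` list of input sizes.
#' @export
common_pattern_genes <- function(listsA, listsB) {
  for (l in list(listsA, listsB))
    if (!all(c("up", "down") %in% names(l)))
      .fail("inputs must be lists with components 'up' and 'down'")
  common_up <- sort(intersect(listsA$up, listsB$up))
  common_down <- sort(intersect(listsA$down, listsB$down))
  both <- intersect(common_up, common_down)
  if (length(both))
    .fail("gene(s) in both common_up and common_down: %s",
          paste(both, collapse = ", "))
  if (!length(common_up) && !length(common_down))
    warning("no common genes between the two cohorts")
  structure(list(common_up = common_up, common_down = common_down,
                 provenance = list(sizes_A = lengths(listsA[c("up", "down")]),
                                   sizes_B = lengths(listsB[c("up", "down")]))),
            class = "common_gene_lists")
}

#' @export
print.common_gene_lists <- function(x, ...) {
  cat(sprintf("common_gene_lists: %d common up, %d common down\n",
              length(x$common_up), length(x$common_down)))
  cat(sprintf("  from per-cohort lists A(up %d, down %d) B(up %d, down %d)\n",
              x$provenance$sizes_A[["up"]], x$provenance$sizes_A[["down"]],
              x$provenance$sizes_B[["up"]], x$provenance$sizes_B[["down"]]))
  invisible(x)
}
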