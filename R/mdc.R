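# Modular differential connectivity (MDC) and its permutation test.
#
# For a module with member genes g1..gk, the connectivity in one condition
# is the mean absolute Pearson correlation over all unordered gene pairs,
# computed on that condition's samples only. MDC = rbarA / rbarB; MDC > 1
# means tighter co-regulation in condition A. Significance comes from a
# label-shuffling permutation null on |log2 MDC|.

# mean |cor| over unordered pairs; drops constant genes, NA if < 2 usable
.mean_abs_cor <- function(X) {
  n <- ncol(X)
  sds <- sqrt(rowSums((X - rowMeans(X))^2) / (n - 1))
  keep <- sds > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 2L)
    return(list(value = NA_real_, n_dropped = n_dropped))
  r <- cor(t(X[keep, , drop = FALSE]))
  list(value = mean(abs(r[upper.tri(r)])), n_dropped = n_dropped)
}

#' Mean absolute pairwise correlation of a module in one condition
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param partition a [detect_modules()] partition over the rows of `expr`.
#' @param module module label (>= 1).
#' @param condition "A" or "B".
#' @return the mean over all unordered member pairs of the absolute Pearson
#'   correlation on that condition's samples. Genes constant within the
#'   condition are excluded with a message; if fewer than two usable genes
#'   remain, an error is raised.
#' @export
module_connectivity <- function(expr, labels, partition, module, condition) {
  stopifnot(inherits(labels, "sample_labels"),
            inherits(partition, "module_partition"))
  .check_labels_match(expr, labels)
  genes <- names(partition$labels)[partition$labels == module]
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 3L)
    .fail("module %s has fewer than 3 genes in the matrix", module)
  samples <- condition_samples(labels, condition)
  if (length(samples) < 4L)
    .fail("condition %s has fewer than 4 samples", condition)
  res <- .mean_abs_cor(expr[genes, samples, drop = FALSE])
  if (res$n_dropped > 0L)
    message(res$n_dropped, " constant gene(s) excluded from module ", module)
  if (is.na(res$value))
    .fail("all gene pairs excluded in module %s, condition %s",
          module, condition)
  res$value
}

# per-module log-ratio machinery shared by the statistic and the test
.mdc_core <- function(expr, module_genes, condA, condB) {
  vapply(module_genes, function(genes) {
    rA <- .mean_abs_cor(expr[genes, condA, drop = FALSE])$value
    rB <- .mean_abs_cor(expr[genes, condB, drop = FALSE])$value
    c(rA, rB)
  }, numeric(2))
}

#' Modular differential connectivity statistic
#'
#' Per module: rbarA, rbarB, MDC = rbarA / rbarB and log2 MDC. Modules with
#' fewer than 3 genes are reported with NA values and a reason.
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param partition a [detect_modules()] partition.
#' @return an `mdc_result` data frame: `module`, `n_genes`, `r_bar_a`,
#'   `r_bar_b`, `mdc`, `log2_mdc` (and `reason` for skipped modules).
#' @export
mdc_statistic <- function(expr, labels, partition) {
  stopifnot(inherits(labels, "sample_labels"),
            inherits(partition, "module_partition"))
  .check_labels_match(expr, labels)
  condA <- condition_samples(labels, "A")
  condB <- condition_samples(labels, "B")
  if (length(condA) < 4L || length(condB) < 4L)
    .fail("both conditions need >= 4 samples")
  labs <- partition$labels
  mods <- sort(unique(labs[labs > 0L]))
  module_genes <- lapply(mods, function(m)
    intersect(names(labs)[labs == m], rownames(expr)))
  names(module_genes) <- mods
  usable <- lengths(module_genes) >= 3L
  out <- data.frame(module = mods,
                    n_genes = lengths(module_genes),
                    r_bar_a = NA_real_, r_bar_b = NA_real_,
                    mdc = NA_real_, log2_mdc = NA_real_,
                    reason = ifelse(usable, "", "fewer than 3 genes"),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(usable)) {
    rr <- .mdc_core(expr, module_genes[usable], condA, condB)
    out$r_bar_a[usable] <- rr[1L, ]
    out$r_bar_b[usable] <- rr[2L, ]
    bad <- usable & (is.na(out$r_bar_b) | out$r_bar_b == 0)
    if (any(bad))
      .fail("undefined MDC ratio (rbarB = 0) in module %s",
            paste(out$module[bad], collapse = ", "))
    out$mdc[usable] <- out$r_bar_a[usable] / out$r_bar_b[usable]
    out$log2_mdc[usable] <- log2(out$mdc[usable])
  }
  class(out) <- c("mdc_result", "data.frame")
  out
}

#' MDC permutation test
#'
#' Shuffles the sample condition labels (group sizes preserved) `n_perm`
#' times, recomputing every module's MDC under each shuffle; the same
#' permutation sequence is applied to all modules, preserving cross-module
#' dependence. The two-sided empirical p is pseudocounted:
#' p = (1 + #\{|log2 MDC_perm| >= |log2 MDC_obs|\}) / (1 + n_perm).
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param partition a [detect_modules()] partition.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return an `mdc_result` data frame with added `p_value` and
#'   `significant`; attributes `n_perm` and `seed`.
#' @export
mdc_permutation_test <- function(expr, labels, partition, n_perm = 1000,
                                 seed = NULL, alpha = 0.05) {
  if (!.is_count(n_perm) || n_perm < 100) .fail("n_perm must be >= 100")
  obs <- mdc_statistic(expr, labels, partition)
  usable <- !is.na(obs$log2_mdc)
  labs <- partition$labels
  module_genes <- lapply(obs$module[usable], function(m)
    intersect(names(labs)[labs == m], rownames(expr)))
  cond <- labels$condition[match(colnames(expr), labels$sample_id)]
  if (!is.null(seed)) set.seed(seed)
  exceed <- integer(sum(usable))
  n_valid <- integer(sum(usable))
  obs_abs <- abs(obs$log2_mdc[usable])
  for (b in seq_len(n_perm)) {
    perm <- sample(cond)
    pa <- colnames(expr)[perm == "A"]
    pb <- colnames(expr)[perm == "B"]
    rr <- .mdc_core(expr, module_genes, pa, pb)
    lperm <- abs(log2(rr[1L, ] / rr[2L, ]))
    ok <- is.finite(lperm)
    exceed[ok] <- exceed[ok] + (lperm[ok] >= obs_abs[ok])
    n_valid <- n_valid + ok
  }
  obs$p_value <- NA_real_
  obs$p_value[usable] <- (1 + exceed) / (1 + n_valid)
  obs$significant <- !is.na(obs$p_value) & obs$p_value < alpha
  attr(obs, "n_perm") <- n_perm
  attr(obs, "seed") <- seed
  obs
}

#' @export
print.mdc_result <- function(x, digits = 3, ...) {
  cat(sprintf("mdc_result: %d modules%s\n", nrow(x),
              if (!is.null(x$p_value))
                sprintf(", %d significant (permutation p < 0.05)",
                        sum(x$significant, na.rm = TRUE))
              else ""))
  df <- as.data.frame(x)
  df$reason <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}
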