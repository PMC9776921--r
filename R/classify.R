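# Logistic classification of sample condition from key-gene expression:
# ridge-penalised maximum likelihood (stable under separation), stratified
# 3-fold cross-validated ROC/AUC, and a random-gene baseline.

#' Fit a ridge-penalised logistic regression
#'
#' Features are standardised internally; the fit is penalised maximum
#' likelihood via iteratively reweighted least squares with a small L2
#' ridge on the (standardised) coefficients, which keeps the fit
#' well-defined under complete separation. The intercept is unpenalised.
#'
#' @param x samples x features numeric matrix.
#' @param y binary response (0/1, logical, or a 2-level factor whose second
#'   level codes 1).
#' @param lambda ridge penalty on standardised coefficients (default 1e-3).
#' @param max_iter,tol IRLS iteration controls.
#' @return a `ridge_logistic` object with `coefficients` (on the
#'   standardised scale), `center`, `scale`.
#' @export
fit_logistic <- function(x, y, lambda = 1e-3, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  y <- .as_binary(y)
  if (nrow(x) != length(y)) .fail("x rows and y length differ")
  if (length(unique(y)) < 2L) .fail("response has a single class")
  if (min(table(y)) < 2L) .fail("each class needs >= 2 samples")
  center <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  b <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - drop(pen %*% b)
    H <- crossprod(X, X * w) + pen
    delta <- solve(H, g)
    b <- b + delta
    if (max(abs(g)) < tol) break
  }
  structure(list(coefficients = setNames(drop(b), colnames(X)),
                 center = center, scale = scl, lambda = lambda),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newx,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  xs <- sweep(sweep(newx, 2L, object$center), 2L, object$scale, "/")
  eta <- drop(cbind(1, xs) %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

.as_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) .fail("factor response must have 2 levels")
    return(as.integer(y == levels(y)[2L]))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) .fail("response must be binary")
  as.integer(y)
}

#' Area under the ROC curve
#'
#' Concordance form with half credit for ties:
#' AUC = (#concordant + 0.5 #tied) / (#pos * #neg) — identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (see [fit_logistic()] for accepted codings).
#' @return the AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(scores) != length(y)) .fail("scores and labels differ in length")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) .fail("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# empirical ROC curve points, (0,0) to (1,1), grouped over tied scores
.roc_points <- function(scores, y) {
  ord <- order(-scores)
  y <- y[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  data.frame(fpr = c(0, cumsum(fp) / sum(1 - y)),
             tpr = c(0, cumsum(tp) / sum(y)), row.names = NULL)
}

#' Cross-validated ROC of a gene-signature logistic model
#'
#' Stratified k-fold cross-validation: within each class the samples are
#' shuffled (seeded) and dealt round-robin into folds, so every fold
#' retains both classes. Per fold, a ridge-logistic model is fitted on the
#' training samples and scored on the held-out samples; per-fold AUC and
#' the fold average are reported. Condition "B" codes the positive class.
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param genes signature gene ids (rows of `expr`).
#' @param k_folds number of folds (default 3).
#' @param seed integer seed for the fold assignment.
#' @param lambda ridge penalty passed to [fit_logistic()].
#' @return a `roc_result`: `fold_auc`, `mean_auc`, `folds` (named
#'   assignment), `curves` (per-fold ROC points), `seed`.
#' @export
cross_validated_roc <- function(expr, labels, genes, k_folds = 3,
                                seed = NULL, lambda = 1e-3) {
  stopifnot(inherits(labels, "sample_labels"))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    .fail("signature gene(s) absent from matrix: %s",
          paste(head(missing, 5L), collapse = ", "))
  .check_labels_match(expr, labels)
  y <- setNames(as.integer(labels$condition == "B"), labels$sample_id)
  if (min(table(y)) < k_folds)
    .fail("class too small for %d stratified folds; use a smaller k", k_folds)
  if (!is.null(seed)) set.seed(seed)
  folds <- setNames(integer(length(y)), names(y))
  for (cls in c(0L, 1L)) {
    ids <- sample(names(y)[y == cls])
    folds[ids] <- rep_len(seq_len(k_folds), length(ids))
  }
  feat <- t(expr[genes, names(y), drop = FALSE])
  fold_auc <- numeric(k_folds)
  curves <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test <- names(y)[folds == f]
    train <- setdiff(names(y), test)
    fit <- fit_logistic(feat[train, , drop = FALSE], y[train], lambda)
    scores <- predict(fit, feat[test, , drop = FALSE])
    fold_auc[f] <- auc(scores, y[test])
    curves[[f]] <- .roc_points(scores, y[test])
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 folds = folds, curves = curves, genes = genes, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d-fold CV on %d genes; fold AUC %s; average %.3f\n",
              length(x$fold_auc), length(x$genes),
              paste(sprintf("%.3f", x$fold_auc), collapse = ", "),
              x$mean_auc))
  invisible(x)
}

#' Random-gene baseline for a gene-signature classifier
#'
#' Repeats [cross_validated_roc()] on `n_draws` uniformly drawn gene sets
#' of the same size, optionally excluding genes (e.g. the key genes) from
#' the pool, and returns the draws' average AUCs.
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param n_genes signature size per draw (default 8).
#' @param n_draws number of random draws.
#' @param seed integer seed.
#' @param exclude gene ids removed from the sampling pool.
#' @param k_folds folds per draw (default 3).
#' @param lambda ridge penalty.
#' @return numeric vector of average AUCs, one per draw; the drawn sets are
#'   in attribute `"gene_sets"`.
#' @export
random_gene_baseline <- function(expr, labels, n_genes = 8, n_draws = 20,
                                 seed = NULL, exclude = NULL, k_folds = 3,
                                 lambda = 1e-3) {
  pool <- setdiff(rownames(expr), exclude)
  if (length(pool) < n_genes)
    .fail("gene pool (%d) smaller than n_genes = %d", length(pool), n_genes)
  if (!is.null(seed)) set.seed(seed)
  sets <- replicate(n_draws, sample(pool, n_genes), simplify = FALSE)
  fold_seeds <- sample.int(.Machine$integer.max, n_draws)
  aucs <- vapply(seq_len(n_draws), function(i) {
    cross_validated_roc(expr, labels, sets[[i]], k_folds,
                        seed = fold_seeds[i], lambda = lambda)$mean_auc
  }, numeric(1))
  attr(aucs, "gene_sets") <- sets
  aucs
}
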