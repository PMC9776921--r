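# Rank-based running-sum enrichment (GSEA-style) with a gene-set permutation
# null, hypergeometric over-representation with BH correction, and per-gene
# pathway-membership counting.

#' Rank genes by a two-group association metric
#'
#' Signal-to-noise is (muA - muB) / (sdA + sdB), each group standard
#' deviation floored at `sd_floor_frac * |mu|` (the usual microarray
#' convention); a constant gene gets metric 0. Genes are returned in
#' descending metric order with a deterministic gene-id tie-break.
#'
#' @param expr genes x samples matrix.
#' @param labels a [sample_labels()] table.
#' @param metric "signal_to_noise" or "t_statistic".
#' @param sd_floor_frac standard-deviation floor as a fraction of |mean|.
#' @return a `ranked_list` data frame: `gene_id`, `metric`, descending.
#' @export
rank_genes <- function(expr, labels,
                       metric = c("signal_to_noise", "t_statistic"),
                       sd_floor_frac = 0.2) {
  .validate_expression(expr)
  stopifnot(inherits(labels, "sample_labels"))
  .check_labels_match(expr, labels)
  metric <- match.arg(metric)
  sA <- condition_samples(labels, "A")
  sB <- condition_samples(labels, "B")
  if (length(sA) < 3L || length(sB) < 3L)
    .fail("both groups need >= 3 samples")
  XA <- expr[, sA, drop = FALSE]; XB <- expr[, sB, drop = FALSE]
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  if (metric == "signal_to_noise") {
    dA <- pmax(apply(XA, 1L, sd), sd_floor_frac * abs(mA))
    dB <- pmax(apply(XB, 1L, sd), sd_floor_frac * abs(mB))
    denom <- dA + dB
    m <- ifelse(denom > 0, (mA - mB) / denom, 0)
  } else {
    de <- two_group_test(expr, labels)
    m <- -de$statistic  # orient so condition A enrichment is positive
    m[!is.finite(m)] <- sign(m[!is.finite(m)]) * .Machine$double.xmax
  }
  ord <- order(-m, rownames(expr))
  out <- data.frame(gene_id = rownames(expr)[ord], metric = m[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# signed extremum given the walk's maximum and minimum; on a magnitude tie
# (within 1e-9 -- ties are structural, e.g. full hit mass vs miss steps)
# the positive extremum is reported
.signed_extremum <- function(walk_max, walk_min) {
  if (walk_max + walk_min >= -1e-9) walk_max else walk_min
}

# ES of a full walk; returns the signed extremum and the running sum
.es_walk <- function(is_hit, metric, weight) {
  N <- length(is_hit)
  nh <- sum(is_hit)
  w <- abs(metric)^weight
  tot <- sum(w[is_hit])
  step <- numeric(N)
  step[is_hit] <- if (tot > 0) w[is_hit] / tot else 1 / nh
  step[!is_hit] <- -1 / (N - nh)
  rs <- cumsum(step)
  list(es = .signed_extremum(max(rs), min(rs)), running_sum = rs)
}

# ES from sorted hit positions only (O(set size)); equals .es_walk because
# the walk's extrema occur at hit positions (maxima) or just before a hit
# (minima)
.es_positions <- function(pos, metric, weight, N) {
  nh <- length(pos)
  miss <- 1 / (N - nh)
  w <- abs(metric[pos])^weight
  tot <- sum(w)
  hitw <- if (tot > 0) cumsum(w) / tot else seq_len(nh) / nh
  at_hit <- hitw - (pos - seq_len(nh)) * miss
  before_hit <- c(0, hitw[-nh]) - (pos - seq_len(nh)) * miss
  .signed_extremum(max(at_hit, 0), min(before_hit, 0))
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranked list: hits increment the running sum by
#' |metric|^weight / sum over hits of |metric|^weight, misses decrement by
#' 1/(N - N_hits). The enrichment score is the signed extremum of the walk;
#' when the positive and negative excursions tie in magnitude the positive
#' one is reported.
#'
#' @param ranked a [rank_genes()] result (or any `ranked_list`).
#' @param gene_set character vector of member gene ids.
#' @param weight metric exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @return list with `es`, the `running_sum` vector and the logical hit
#'   indicator `hits`.
#' @export
gsea_enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  is_hit <- ranked$gene_id %in% gene_set
  if (!any(is_hit)) .fail("no gene-set member present in the ranked list")
  if (all(is_hit)) {
    # never decremented; walk terminates at the full hit mass
    w <- abs(ranked$metric)^weight
    tot <- sum(w)
    rs <- if (tot > 0) cumsum(w) / tot else
      seq_along(w) / length(w)
    return(list(es = 1, running_sum = rs, hits = is_hit))
  }
  walk <- .es_walk(is_hit, ranked$metric, weight)
  list(es = walk$es, running_sum = walk$running_sum, hits = is_hit)
}

#' Gene-set permutation p-value for a GSEA enrichment score
#'
#' The null is the ES of `n_perm` random gene sets of the same size drawn
#' from the ranked universe ("gene set" permutation mode). The empirical p
#' is pseudocounted and two-sided on |ES|:
#' p = (1 + #\{|ES_null| >= |ES_obs|\}) / (1 + n_perm). The normalised ES
#' divides by the mean |ES_null| of null scores sharing the observed sign.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of member gene ids.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight metric exponent.
#' @return a one-row `gsea_result` data frame: `es`, `nes`, `p_value`,
#'   `n_hits`, `n_perm`.
#' @export
gsea_permutation_p <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                               weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!.is_count(n_perm) || n_perm < 100) .fail("n_perm must be >= 100")
  N <- nrow(ranked)
  obs <- gsea_enrichment_score(ranked, gene_set, weight)
  nh <- sum(obs$hits)
  if (nh >= N) .fail("gene set must be smaller than the ranked universe")
  if (!is.null(seed)) set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(b) {
    pos <- sort(sample.int(N, nh))
    .es_positions(pos, ranked$metric, weight, N)
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same)) obs$es / mean(abs(same))
  else obs$es / mean(abs(null_es))
  out <- data.frame(es = obs$es, nes = nes, p_value = p,
                    n_hits = nh, n_perm = n_perm, row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each catalog set S, tests whether the query list overlaps S more than
#' chance given the universe: p = P[X >= k] with X hypergeometric
#' (N = |universe|, K = |S intersect universe|, n = |query|) and
#' k = |query intersect S|. P-values are BH-adjusted across the catalog.
#'
#' @param query character vector of genes (must lie inside `universe`).
#' @param catalog a [gene_set_catalog()].
#' @param universe character vector of background genes.
#' @return an `ora_result` data frame: `set_name`, `set_size`, `overlap`,
#'   `p_value`, `adj_p`.
#' @export
ora_hypergeometric <- function(query, catalog, universe) {
  stopifnot(inherits(catalog, "gene_set_catalog"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(universe)) .fail("universe is empty")
  if (!length(query)) .fail("query is empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    .fail("query gene(s) outside the universe: %s",
          paste(head(outside, 5L), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  K <- vapply(catalog$sets, function(s) length(intersect(s, universe)),
              integer(1))
  k <- vapply(catalog$sets, function(s) length(intersect(s, query)),
              integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_name = names(catalog$sets), set_size = K,
                    overlap = k, p_value = p, adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Per-gene pathway-membership counts
#'
#' For each gene, the number of significant catalog sets (adjusted
#' p <= `alpha` in `ora`) that contain it.
#'
#' @param genes character vector of genes to count for.
#' @param ora an [ora_hypergeometric()] result over `catalog`.
#' @param catalog the [gene_set_catalog()] the ORA was run on.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return named integer vector, one entry per input gene.
#' @export
pathway_membership_counts <- function(genes, ora, catalog, alpha = 0.05) {
  stopifnot(inherits(ora, "ora_result"), inherits(catalog, "gene_set_catalog"))
  genes <- as.character(genes)
  sig <- ora$set_name[ora$adj_p <= alpha]
  counts <- setNames(integer(length(genes)), genes)
  for (nm in sig) {
    hit <- genes %in% catalog$sets[[nm]]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
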