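# Three-criterion key-gene prioritisation: PPI degree on the
# candidate-induced subgraph, pathway-membership counts, and module hubness
# (|kME| above threshold within an enriched module). The key genes are the
# intersection of the three criteria.

#' Rank candidate genes by PPI degree
#'
#' Degree is computed on the subgraph induced by the candidate genes (the
#' interaction network of the common DE genes, not the full interactome).
#' Competition ranking; the top-n cut includes every gene tied at the
#' boundary rank. Candidates absent from the graph get degree 0 and are
#' never part of the top set.
#'
#' @param graph a [ppi_graph()].
#' @param candidates character vector of candidate gene ids.
#' @param top_n size of the top cut (default 20).
#' @return a `degree_rank` data frame: `gene_id`, `degree`, `rank`,
#'   logical `top`; ordered by rank then gene id.
#' @export
ppi_degree_rank <- function(graph, candidates, top_n = 20) {
  stopifnot(inherits(graph, "ppi_graph"))
  candidates <- unique(as.character(candidates))
  sub <- graph[graph$from %in% candidates & graph$to %in% candidates, ,
               drop = FALSE]
  deg <- setNames(integer(length(candidates)), candidates)
  if (nrow(sub)) {
    d <- ppi_degree(ppi_graph(sub$from, sub$to))
    deg[names(d)] <- d
  }
  rank <- .competition_rank(deg)
  top <- deg > 0L & rank <= top_n
  out <- data.frame(gene_id = candidates, degree = as.integer(deg),
                    rank = rank, top = top,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("degree_rank", "data.frame")
  out
}

#' Module over-representation of a candidate gene list
#'
#' Hypergeometric test (via [ora_hypergeometric()]) of candidate membership
#' in each module of a partition, BH-corrected across modules. Modules with
#' adjusted p <= `alpha` are the "enriched modules" used by the key-gene
#' hubness criterion.
#'
#' @param candidates character vector of genes (subset of `universe`).
#' @param partition a [detect_modules()] partition.
#' @param universe background gene ids.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return a `module_enrichment` data frame (`module`, `set_size`,
#'   `overlap`, `p_value`, `adj_p`) with the enriched module labels in
#'   attribute `"enriched_modules"`.
#' @export
module_overrepresentation <- function(candidates, partition, universe,
                                      alpha = 0.05) {
  stopifnot(inherits(partition, "module_partition"))
  labs <- partition$labels
  mods <- sort(unique(labs[labs > 0L]))
  if (!length(mods)) .fail("partition has no modules")
  sets <- lapply(mods, function(m) names(labs)[labs == m])
  names(sets) <- sprintf("module_%d", mods)
  catalog <- gene_set_catalog(sets, namespace = "modules")
  ora <- ora_hypergeometric(intersect(candidates, universe), catalog, universe)
  out <- data.frame(module = mods, set_size = ora$set_size,
                    overlap = ora$overlap, p_value = ora$p_value,
                    adj_p = ora$adj_p, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "enriched_modules") <- mods[out$adj_p <= alpha]
  class(out) <- c("module_enrichment", "data.frame")
  out
}

#' Integrate the three key-gene criteria
#'
#' A candidate is a key gene when it (1) sits in the top-`top_n` of PPI
#' degree, (2) sits in the top-`top_n` of pathway-membership counts, and
#' (3) belongs to an enriched module with |kME| above `kme_threshold` for
#' that module's eigengene. Criteria (1) and (2) use competition ranking
#' with tie inclusion at the cut; genes with zero degree or zero count
#' never qualify. Criterion (3) may be evaluated against several networks
#' (e.g. one per cohort); membership in any of them suffices.
#'
#' @param degree_rank a [ppi_degree_rank()] result over the candidates.
#' @param pathway_counts named integer vector from
#'   [pathway_membership_counts()] over the same candidates.
#' @param kme_table a [kme()] table, or a list of them (one per cohort).
#' @param enriched_modules integer vector of enriched module labels, or a
#'   list parallel to `kme_table`.
#' @param top_n top-cut size for criteria (1) and (2) (default 20).
#' @param kme_threshold |kME| hub threshold (default 0.85).
#' @return a `key_gene_report`: `report` data frame (per-candidate degree,
#'   rank, count, flags) and the sorted `key_genes` passing all three.
#' @export
select_key_genes <- function(degree_rank, pathway_counts, kme_table,
                             enriched_modules, top_n = 20,
                             kme_threshold = 0.85) {
  stopifnot(inherits(degree_rank, "degree_rank"))
  if (inherits(kme_table, "kme_table")) {
    kme_table <- list(kme_table)
    enriched_modules <- list(enriched_modules)
  }
  stopifnot(length(kme_table) == length(enriched_modules))
  candidates <- sort(degree_rank$gene_id)
  if (!setequal(candidates, names(pathway_counts)))
    .fail("degree ranks and pathway counts cover different candidate sets")
  counts <- pathway_counts[candidates]
  count_rank <- .competition_rank(counts)
  count_top <- counts > 0L & count_rank <= top_n
  hub_flag <- setNames(rep(FALSE, length(candidates)), candidates)
  best_kme <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (i in seq_along(kme_table)) {
    kt <- kme_table[[i]]
    enr <- enriched_modules[[i]]
    present <- intersect(candidates, names(kt$own_module))
    own <- kt$own_module[present]
    ok <- !is.na(own) & own %in% enr
    val <- abs(kt$own_kme[present])
    hub_flag[present[ok & !is.na(val) & val > kme_threshold]] <- TRUE
    upd <- is.na(best_kme[present]) | (!is.na(val) & val > best_kme[present])
    best_kme[present][upd] <- val[upd]
  }
  dr <- degree_rank[match(candidates, degree_rank$gene_id), ]
  report <- data.frame(gene_id = candidates,
                       degree = dr$degree, degree_rank = dr$rank,
                       degree_top = dr$top,
                       pathway_count = as.integer(counts),
                       count_rank = count_rank, count_top = count_top,
                       best_abs_kme = as.numeric(best_kme),
                       hub_in_enriched = hub_flag,
                       stringsAsFactors = FALSE, row.names = NULL)
  report$key_gene <- report$degree_top & report$count_top &
    report$hub_in_enriched
  keys <- sort(report$gene_id[report$key_gene])
  if (!length(keys)) warning("no gene passes all three key-gene criteria")
  structure(list(report = report, key_genes = keys,
                 params = list(top_n = top_n, kme_threshold = kme_threshold)),
            class = "key_gene_report")
}

#' @export
print.key_gene_report <- function(x, ...) {
  cat(sprintf("key_gene_report: %d candidate(s), %d key gene(s)\n",
              nrow(x$report), length(x$key_genes)))
  if (length(x$key_genes)) {
    cat("  key genes:", paste(x$key_genes, collapse = ", "), "\n")
    sub <- x$report[x$report$key_gene,
                    c("gene_id", "degree", "pathway_count", "best_abs_kme")]
    print(format(sub, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
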