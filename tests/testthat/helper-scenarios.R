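# Shared fixture builders, all generated in code at test time.

toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

half_half_labels <- function(samples) {
  n <- length(samples)
  sample_labels(samples, rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2))))
}

# a ranked list straight from values (descending), as rank_genes would emit
as_ranked <- function(gene_ids, metric) {
  ord <- order(-metric, gene_ids)
  structure(data.frame(gene_id = gene_ids[ord], metric = metric[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

# a partition assigning all genes to one module
one_module_partition <- function(genes) {
  structure(list(labels = setNames(rep(1L, length(genes)), genes),
                 module_sizes = length(genes)),
            class = "module_partition")
}

# single planted module, no DE: the workhorse for MDC scenarios
one_module_config <- function(rhoA, rhoB, n_per_cond, n_genes = 50,
                              seed = 1) {
  sim_config(n_genes = n_genes, module_sizes = n_genes,
             rho = matrix(c(rhoA, rhoB), 1),
             samples_per_condition = list(c(n_per_cond, n_per_cond),
                                          c(13, 16)),
             key_module_lfc = 0, n_shared_up_background = 0,
             n_shared_down = 0, n_cohort_specific = 0, n_key_genes = 0,
             seed = seed)
}

# several planted modules with equal condition correlations, no DE
modules_only_config <- function(sizes, rho, n_per_cond, n_genes = sum(sizes),
                                seed = 1) {
  sim_config(n_genes = n_genes, module_sizes = sizes,
             rho = matrix(rep(rho, length.out = 2 * length(sizes)),
                          ncol = 2),
             samples_per_condition = list(c(n_per_cond, n_per_cond),
                                          c(13, 16)),
             key_module_lfc = 0, n_shared_up_background = 0,
             n_shared_down = 0, n_cohort_specific = 0, n_key_genes = 0,
             seed = seed)
}

# run the key-gene stages (no MDC/classifier) on a simulated paired study
run_keygene_stages <- function(config, k = 500, alpha = 0.05, top_n = 20,
                               kme_threshold = 0.85) {
  paired <- simulate_paired_cohorts(config)
  ppi <- simulate_ppi(paired$truth)
  catalog <- simulate_gene_sets(paired$truth)
  de <- lapply(paired[c("cohort1", "cohort2")], function(co)
    two_group_test(co$expr, co$labels))
  lists <- lapply(de, function(d)
    list(up = select_top_k(d, k, "up", alpha),
         down = select_top_k(d, k, "down", alpha)))
  common <- common_pattern_genes(lists[[1]], lists[[2]])
  candidates <- c(common$common_up, common$common_down)
  nets <- lapply(paired[c("cohort1", "cohort2")], function(co)
    suppressWarnings(fit_coexpression_network(co$expr)))
  ora <- ora_hypergeometric(candidates, catalog,
                            rownames(paired$cohort1$expr))
  counts <- pathway_membership_counts(candidates, ora, catalog, alpha)
  dr <- ppi_degree_rank(ppi, candidates, top_n)
  menr <- lapply(nets, function(nw)
    module_overrepresentation(candidates, nw$partition,
                              rownames(nw$expr), alpha))
  report <- select_key_genes(dr, counts,
                             kme_table = lapply(nets, `[[`, "kme"),
                             enriched_modules = lapply(menr, attr,
                                                       "enriched_modules"),
                             top_n = top_n, kme_threshold = kme_threshold)
  list(truth = paired$truth, common = common, report = report)
}
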