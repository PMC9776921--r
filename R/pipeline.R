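# End-to-end orchestration: two cohorts (simulated or loaded from files)
# through differential expression, cross-cohort intersection, enrichment,
# network construction, MDC, module over-representation, key-gene
# integration and the ROC classifier, writing every intermediate as
# tab-separated text plus a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with the study's printed constants as
#' defaults. Supply either `simulation` (a [sim_config()]) or the six input
#' file paths.
#'
#' @param simulation a [sim_config()], or NULL when reading files.
#' @param expr1,labels1,expr2,labels2 cohort input files (TSV).
#' @param gmt gene-set catalog file (GMT).
#' @param ppi PPI edge-list file (TSV).
#' @param k top-k list size per direction (default 500).
#' @param alpha significance threshold used throughout (default 0.05).
#' @param fc_threshold DEG fold-change threshold (default 2).
#' @param n_perm permutations for GSEA and MDC (default 1000).
#' @param beta soft power or "auto" (default 6).
#' @param keep_fraction variance-filter fraction (default 0.75).
#' @param min_module_size,merge_cut,cut_height module detection parameters.
#' @param kme_threshold hub |kME| cutoff (default 0.85).
#' @param top_n key-gene top-cut size (default 20).
#' @param folds cross-validation folds (default 3).
#' @param baseline_draws random-gene baseline draws (default 20).
#' @param seed global seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            expr1 = NULL, labels1 = NULL,
                            expr2 = NULL, labels2 = NULL,
                            gmt = NULL, ppi = NULL,
                            k = 500, alpha = 0.05, fc_threshold = 2,
                            n_perm = 1000, beta = 6, keep_fraction = 0.75,
                            min_module_size = 30, merge_cut = 0.25,
                            cut_height = 0.99, kme_threshold = 0.85,
                            top_n = 20, folds = 3, baseline_draws = 20,
                            seed = 1) {
  if (is.null(simulation)) {
    paths <- list(expr1 = expr1, labels1 = labels1, expr2 = expr2,
                  labels2 = labels2, gmt = gmt, ppi = ppi)
    missing <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing))
      .fail("file inputs required without a simulation config: %s",
            paste(missing, collapse = ", "))
  } else stopifnot(inherits(simulation, "sim_config"))
  stopifnot(alpha > 0, alpha < 1, k >= 1, n_perm >= 100,
            folds >= 2, top_n >= 1)
  structure(list(simulation = simulation, expr1 = expr1, labels1 = labels1,
                 expr2 = expr2, labels2 = labels2, gmt = gmt, ppi = ppi,
                 k = k, alpha = alpha, fc_threshold = fc_threshold,
                 n_perm = n_perm, beta = beta, keep_fraction = keep_fraction,
                 min_module_size = min_module_size, merge_cut = merge_cut,
                 cut_height = cut_height, kme_threshold = kme_threshold,
                 top_n = top_n, folds = folds,
                 baseline_draws = baseline_draws, seed = seed),
            class = "pipeline_config")
}

#' Run the full differential co-expression pipeline
#'
#' Executes, in order: data (simulate or load), differential expression per
#' cohort, cross-cohort common genes, enrichment (GSEA per cohort + ORA of
#' the common genes), co-expression network per cohort, MDC per cohort,
#' module over-representation per cohort, key-gene integration, and the
#' cross-validated classifier with a random-gene baseline. Every
#' intermediate is written under `output_dir` and recorded in the returned
#' manifest; identical config and seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for intermediates and the manifest.
#' @return a `run_manifest` (invisible list of stage records plus the main
#'   results in `$results`); also written as `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = tempfile("mdcnet_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  t_total <- Sys.time()

  stage <- function(name, inputs, fun) {
    t0 <- Sys.time()
    warns <- character(0)
    out <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        .fail("pipeline stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest[[name]] <<- list(
      stage = name, inputs = inputs, outputs = out$files,
      params = out$params,
      wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
      warnings = warns)
    out$value
  }
  path <- function(...) file.path(output_dir, paste0(...))

  # -- stage 1: data ----------------------------------------------------------
  data <- stage("data", inputs = if (is.null(config$simulation))
    unlist(config[c("expr1", "labels1", "expr2", "labels2", "gmt", "ppi")])
    else "simulation", function() {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, "simulate")
      paired <- simulate_paired_cohorts(sim)
      ppi <- simulate_ppi(paired$truth)
      catalog <- simulate_gene_sets(paired$truth)
      truth <- paired$truth
      cohorts <- list(paired$cohort1, paired$cohort2)
    } else {
      cohorts <- list(
        list(expr = read_expression(config$expr1),
             labels = read_sample_labels(config$labels1)),
        list(expr = read_expression(config$expr2),
             labels = read_sample_labels(config$labels2)))
      ppi <- read_edge_list(config$ppi)
      catalog <- read_gmt(config$gmt)
      truth <- NULL
    }
    files <- character(0)
    for (i in 1:2) {
      files <- c(files,
                 write_expression(cohorts[[i]]$expr, path("expr", i, ".tsv")),
                 write_sample_labels(cohorts[[i]]$labels,
                                     path("labels", i, ".tsv")))
    }
    files <- c(files, write_edge_list(ppi, path("ppi.tsv")),
               write_gmt(catalog, path("gene_sets.gmt")))
    list(value = list(cohorts = cohorts, ppi = ppi, catalog = catalog,
                      truth = truth),
         files = files, params = list(seed = config$seed))
  })

  # -- stage 2: differential expression --------------------------------------
  de <- stage("diffexpr", inputs = c("expr1", "expr2"), function() {
    de <- lapply(data$cohorts, function(co)
      two_group_test(co$expr, co$labels))
    files <- vapply(1:2, function(i) {
      f <- path("diffexpr", i, ".tsv")
      utils::write.table(as.data.frame(de[[i]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }, character(1))
    list(value = de, files = files, params = list())
  })

  # -- stage 3: cross-cohort common genes ------------------------------------
  common <- stage("common_genes", inputs = "diffexpr", function() {
    lists <- lapply(de, function(d)
      list(up = select_top_k(d, config$k, "up", config$alpha),
           down = select_top_k(d, config$k, "down", config$alpha)))
    cg <- common_pattern_genes(lists[[1]], lists[[2]])
    f <- path("common_genes.tsv")
    utils::write.table(
      data.frame(gene_id = c(cg$common_up, cg$common_down),
                 direction = rep(c("up", "down"),
                                 c(length(cg$common_up),
                                   length(cg$common_down)))),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = cg, files = f,
         params = list(k = config$k, alpha = config$alpha))
  })

  # -- stage 4: enrichment ----------------------------------------------------
  enr <- stage("enrichment", inputs = c("expr1", "expr2", "gene_sets"),
               function() {
    gsea <- lapply(1:2, function(i) {
      ranked <- rank_genes(data$cohorts[[i]]$expr, data$cohorts[[i]]$labels)
      res <- do.call(rbind, lapply(names(data$catalog$sets), function(nm) {
        r <- gsea_permutation_p(ranked, data$catalog$sets[[nm]],
                                n_perm = config$n_perm,
                                seed = derive_seed(config$seed,
                                                   paste0("gsea", i, nm)))
        cbind(set_name = nm, r)
      }))
      res
    })
    universe <- rownames(data$cohorts[[1]]$expr)
    query <- c(common$common_up, common$common_down)
    ora <- ora_hypergeometric(query, data$catalog, universe)
    files <- c(vapply(1:2, function(i) {
      f <- path("gsea", i, ".tsv")
      utils::write.table(gsea[[i]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    }, character(1)), {
      f <- path("ora_common.tsv")
      utils::write.table(as.data.frame(ora), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    })
    list(value = list(gsea = gsea, ora = ora),
         files = files, params = list(n_perm = config$n_perm))
  })

  # -- stage 5: co-expression networks ---------------------------------------
  nets <- stage("coexpression", inputs = c("expr1", "expr2"), function() {
    nets <- lapply(data$cohorts, function(co)
      fit_coexpression_network(co$expr, beta = config$beta,
                               keep_fraction = config$keep_fraction,
                               min_module_size = config$min_module_size,
                               merge_cut = config$merge_cut,
                               cut_height = config$cut_height,
                               hub_threshold = config$kme_threshold))
    files <- unlist(lapply(1:2, function(i) {
      f1 <- path("modules", i, ".tsv")
      utils::write.table(
        data.frame(gene_id = names(nets[[i]]$partition$labels),
                   module = nets[[i]]$partition$labels),
        f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- path("eigengenes", i, ".tsv")
      me <- nets[[i]]$eigengenes$eigengenes
      utils::write.table(data.frame(sample_id = rownames(me), me),
                         f2, sep = "\t", quote = FALSE, row.names = FALSE)
      f3 <- path("kme", i, ".tsv")
      utils::write.table(
        data.frame(gene_id = rownames(nets[[i]]$kme$kme), nets[[i]]$kme$kme),
        f3, sep = "\t", quote = FALSE, row.names = FALSE)
      c(f1, f2, f3)
    }))
    list(value = nets, files = files,
         params = config[c("beta", "keep_fraction", "min_module_size",
                           "merge_cut", "cut_height")])
  })

  # -- stage 6: modular differential connectivity ----------------------------
  mdc <- stage("mdc", inputs = "coexpression", function() {
    res <- lapply(1:2, function(i)
      mdc_permutation_test(nets[[i]]$expr, data$cohorts[[i]]$labels,
                           nets[[i]]$partition, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, paste0("mdc", i)),
                           alpha = config$alpha))
    files <- vapply(1:2, function(i) {
      f <- path("mdc", i, ".tsv")
      utils::write.table(as.data.frame(res[[i]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }, character(1))
    list(value = res, files = files, params = list(n_perm = config$n_perm))
  })

  # -- stage 7: module over-representation -----------------------------------
  menr <- stage("module_enrichment", inputs = c("common_genes", "coexpression"),
                function() {
    query <- c(common$common_up, common$common_down)
    res <- lapply(1:2, function(i)
      module_overrepresentation(query, nets[[i]]$partition,
                                rownames(nets[[i]]$expr),
                                alpha = config$alpha))
    files <- vapply(1:2, function(i) {
      f <- path("module_enrichment", i, ".tsv")
      utils::write.table(as.data.frame(res[[i]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }, character(1))
    list(value = res, files = files, params = list(alpha = config$alpha))
  })

  # -- stage 8: key genes -----------------------------------------------------
  keys <- stage("keygenes", inputs = c("common_genes", "ppi", "enrichment",
                                       "module_enrichment"), function() {
    candidates <- c(common$common_up, common$common_down)
    dr <- ppi_degree_rank(data$ppi, candidates, top_n = config$top_n)
    counts <- pathway_membership_counts(candidates, enr$ora, data$catalog,
                                        alpha = config$alpha)
    report <- select_key_genes(
      dr, counts,
      kme_table = lapply(nets, `[[`, "kme"),
      enriched_modules = lapply(menr, attr, "enriched_modules"),
      top_n = config$top_n, kme_threshold = config$kme_threshold)
    f <- path("key_genes.tsv")
    utils::write.table(report$report, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(value = report, files = f,
         params = list(top_n = config$top_n,
                       kme_threshold = config$kme_threshold))
  })

  # -- stage 9: classifier ----------------------------------------------------
  clf <- stage("classify", inputs = c("expr2", "keygenes"), function() {
    co <- data$cohorts[[2]]
    keyset <- keys$key_genes
    if (!length(keyset)) {
      warning("no key genes; classifier stage skipped on signature")
      return(list(value = NULL, files = character(0), params = list()))
    }
    roc <- cross_validated_roc(co$expr, co$labels, keyset,
                               k_folds = config$folds,
                               seed = derive_seed(config$seed, "classify"))
    baseline <- random_gene_baseline(co$expr, co$labels,
                                     n_genes = length(keyset),
                                     n_draws = config$baseline_draws,
                                     seed = derive_seed(config$seed,
                                                        "baseline"),
                                     exclude = keyset,
                                     k_folds = config$folds)
    f <- path("classifier.tsv")
    utils::write.table(
      data.frame(quantity = c(sprintf("fold%d_auc", seq_along(roc$fold_auc)),
                              "mean_auc", "baseline_mean_auc"),
                 value = c(roc$fold_auc, roc$mean_auc, mean(baseline))),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(roc = roc, baseline = baseline), files = f,
         params = list(folds = config$folds,
                       baseline_draws = config$baseline_draws))
  })

  results <- list(truth = data$truth, de = de, common = common,
                  enrichment = enr, networks = nets, mdc = mdc,
                  module_enrichment = menr, key_genes = keys,
                  classifier = clf)
  out <- list(stages = manifest, output_dir = output_dir,
              seed = config$seed,
              wall_time_s = round(as.numeric(Sys.time() - t_total,
                                             units = "secs"), 3),
              results = results)
  class(out) <- "run_manifest"
  jsonlite::write_json(
    lapply(manifest, function(s) s[c("stage", "inputs", "outputs",
                                     "params", "wall_time_s", "warnings")]),
    file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d stages in %.1f s -> %s\n",
              length(x$stages), x$wall_time_s, x$output_dir))
  for (s in x$stages)
    cat(sprintf("  %-18s %6.2f s  %d file(s)%s\n", s$stage, s$wall_time_s,
                length(s$outputs),
                if (length(s$warnings)) sprintf("  [%d warning(s)]",
                                                length(s$warnings)) else ""))
  if (!is.null(x$results$key_genes))
    cat("  key genes:",
        paste(x$results$key_genes$key_genes, collapse = ", "), "\n")
  invisible(x)
}
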