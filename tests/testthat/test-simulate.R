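test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(n_genes = 120, module_sizes = c(30, 30),
                    rho = rbind(c(0.8, 0.4), c(0.5, 0.5)),
                    samples_per_condition = list(c(10, 10), c(8, 8)),
                    n_shared_up_background = 5, n_shared_down = 5,
                    n_cohort_specific = 5, n_key_genes = 4, seed = 3)
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a$expr, b$expr)
  expect_identical(as.data.frame(a$labels), as.data.frame(b$labels))
  tr <- synthetic_truth(cfg)
  expect_identical(simulate_ppi(tr)$from, simulate_ppi(tr)$from)
  expect_identical(simulate_gene_sets(tr)$sets, simulate_gene_sets(tr)$sets)
})

test_that("factor model reproduces the planted within-module correlation", {
  # rho = 0.81, 500 condition-A samples, one 50-gene module
  cfg <- one_module_config(0.81, 0.81, 500, seed = 5)
  cfg$samples_per_condition <- list(c(500, 4), c(13, 16))
  co <- simulate_cohort(cfg, 1)
  X <- co$expr[, condition_samples(co$labels, "A")]
  r <- cor(t(X))
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.81), 0.05)
})

test_that("rho = 0 modules are asymptotically uncorrelated", {
  cfg <- one_module_config(0, 0, 200, seed = 6)
  co <- simulate_cohort(cfg, 1)
  X <- co$expr[, condition_samples(co$labels, "A")]
  r <- cor(t(X))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("paired cohorts share genes, modules and the shared DE genes", {
  cfg <- sim_config(seed = 2)
  paired <- simulate_paired_cohorts(cfg)
  expect_identical(rownames(paired$cohort1$expr),
                   rownames(paired$cohort2$expr))
  tr <- paired$truth
  expect_equal(sum(tr$gene_module > 0), sum(cfg$module_sizes))
  expect_equal(as.integer(table(tr$gene_module[tr$gene_module > 0])),
               cfg$module_sizes)
  # shared DE genes carry their shift in both cohorts, specific ones in one
  shared_up <- tr$de$gene[tr$de$shared & tr$de$lfc > 0]
  for (co in list(paired$cohort1, paired$cohort2)) {
    a <- rowMeans(co$expr[shared_up, condition_samples(co$labels, "A")])
    b <- rowMeans(co$expr[shared_up, condition_samples(co$labels, "B")])
    expect_gt(mean(b - a), 0.5)
  }
  spec1 <- tr$de$gene[!tr$de$shared & tr$de$cohort == 1]
  spec2 <- tr$de$gene[!tr$de$shared & tr$de$cohort == 2]
  expect_length(intersect(spec1, spec2), 0)
})

test_that("without planted DE the two conditions are exchangeable", {
  cfg <- one_module_config(0.5, 0.5, 50, seed = 9)
  co <- simulate_cohort(cfg, 1)
  de <- two_group_test(co$expr, co$labels)
  expect_gt(min(de$adj_p), 0.05)  # nothing should look regulated
})

test_that("planted PPI degree concentrates on the key genes", {
  cfg <- sim_config(seed = 4)
  tr <- synthetic_truth(cfg)
  g <- simulate_ppi(tr, background_edge_prob = 1e-4,
                    key_gene_degree_boost = 30)
  deg <- ppi_degree(g)
  top <- names(sort(deg, decreasing = TRUE))[seq_along(tr$key_genes)]
  expect_setequal(top, tr$key_genes)
  # empty graph when nothing is planted
  g0 <- simulate_ppi(tr, background_edge_prob = 0, key_gene_degree_boost = 0)
  expect_equal(nrow(g0), 0L)
})

test_that("planted gene sets make the key genes' membership recoverable", {
  cfg <- sim_config(seed = 8)
  tr <- synthetic_truth(cfg)
  catalog <- simulate_gene_sets(tr, n_sets = 40, sets_per_key_gene = 12)
  n_member <- vapply(tr$key_genes, function(g)
    sum(vapply(catalog$sets, function(s) g %in% s, logical(1))),
    integer(1))
  expect_true(all(n_member >= 12))
  # module-1 non-key genes never enter the signature sets
  m1_nonkey <- setdiff(names(tr$gene_module)[tr$gene_module == 1],
                       tr$key_genes)
  in_any <- vapply(m1_nonkey, function(g)
    any(vapply(catalog$sets[1:12], function(s) g %in% s, logical(1))),
    logical(1))
  expect_false(any(in_any))
})
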