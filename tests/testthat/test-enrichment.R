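test_that("signal-to-noise ranking matches the formula and its symmetries", {
  # group A: mean 1, sd 0.5; group B: mean 0, sd 0.5 -> metric exactly 1
  expr <- toy_expr(rbind(c(0.5, 1.0, 1.5, -0.5, 0.0, 0.5),
                         c(5, 5, 5, 5, 5, 5),
                         rnorm(6)),
                   genes = c("sig", "const", "noise"))
  labels <- half_half_labels(colnames(expr))
  r <- rank_genes(expr, labels)
  expect_equal(r$metric[r$gene_id == "sig"], 1)
  expect_equal(r$metric[r$gene_id == "const"], 0)

  swapped <- sample_labels(labels$sample_id,
                           ifelse(labels$condition == "A", "B", "A"))
  r2 <- rank_genes(expr, swapped)
  expect_equal(r2$metric[match(r$gene_id, r2$gene_id)], -r$metric)
})

test_that("enrichment score matches boundary cases and the walk oracle", {
  ranked <- as_ranked(sprintf("G%02d", 1:10), 10:1)
  top2 <- gsea_enrichment_score(ranked, c("G01", "G02"), weight = 0)
  expect_equal(top2$es, 1)
  all_in <- gsea_enrichment_score(ranked, ranked$gene_id)
  expect_equal(all_in$es, 1)
  expect_error(gsea_enrichment_score(ranked, "absent"), "no gene-set member")

  set.seed(20)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    ranked <- as_ranked(sprintf("G%02d", 1:N), sort(rnorm(N), TRUE))
    members <- sample(ranked$gene_id, sample(1:(N - 1), 1))
    w <- sample(c(0, 0.5, 1, 2), 1)
    got <- gsea_enrichment_score(ranked, members, weight = w)$es
    expect_equal(got, bf_es(ranked$gene_id, ranked$metric, members, w),
                 tolerance = 1e-12)
  }
})

test_that("fast positional ES equals the full walk", {
  set.seed(21)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    pos <- sort(sample.int(N, sample(1:(N - 1), 1)))
    hit <- seq_len(N) %in% pos
    expect_equal(mdcnet:::.es_positions(pos, metric, 1, N),
                 mdcnet:::.es_walk(hit, metric, 1)$es, tolerance = 1e-12)
  }
})

test_that("gene-set permutation p is seeded and attains the pseudocount floor", {
  metric <- c(100, 90, 80, 70, 60, sort(runif(45, 0, 0.01), TRUE))
  ranked <- as_ranked(sprintf("G%02d", 1:50), metric)
  top5 <- ranked$gene_id[1:5]
  res <- gsea_permutation_p(ranked, top5, n_perm = 200, seed = 42)
  expect_equal(res$p_value, 1 / 201)
  expect_gt(res$nes, 1)
  res2 <- gsea_permutation_p(ranked, top5, n_perm = 200, seed = 42)
  expect_equal(res$p_value, res2$p_value)
  expect_error(gsea_permutation_p(ranked, ranked$gene_id, n_perm = 100),
               "smaller than the ranked universe")
  expect_error(gsea_permutation_p(ranked, top5, n_perm = 50), ">= 100")
})

test_that("hypergeometric ORA matches the closed form", {
  universe <- sprintf("U%02d", 1:20)
  catalog <- gene_set_catalog(list(hit = universe[1:5],
                                   miss = universe[16:20]))
  res <- ora_hypergeometric(universe[1:5], catalog, universe)
  expect_equal(res$p_value[res$set_name == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$overlap[res$set_name == "miss"], 0L)
  expect_equal(res$p_value[res$set_name == "miss"], 1)
  expect_error(ora_hypergeometric("X99", catalog, universe), "outside")
  expect_error(ora_hypergeometric(character(0), catalog, universe), "empty")
})

test_that("pathway membership counts only significant sets", {
  universe <- sprintf("U%02d", 1:40)
  query <- universe[1:10]
  sets <- list(s1 = c(query[1:8], "U30"),   # enriched, contains X = U01
               s2 = c(query[1:7], "U31"),   # enriched, contains X
               s3 = c(query[2:9], "U32"),   # enriched, no... contains U02
               s4 = universe[30:35],        # not enriched
               s5 = universe[36:40])        # not enriched
  catalog <- gene_set_catalog(sets)
  ora <- ora_hypergeometric(query, catalog, universe)
  counts <- pathway_membership_counts(c("U01", "U02", "U39"), ora, catalog)
  sig <- ora$set_name[ora$adj_p <= 0.05]
  expect_true(all(c("s1", "s2", "s3") %in% sig))
  expect_false(any(c("s4", "s5") %in% sig))
  expect_equal(counts[["U01"]], 2L)
  expect_equal(counts[["U02"]], 3L)
  expect_equal(counts[["U39"]], 0L)
})
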