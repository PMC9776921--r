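test_that("Welch test handles degenerate, strong and swapped cases", {
  set.seed(1)
  n <- 50
  expr <- toy_expr(rbind(rep(3, 2 * n),
                         c(rnorm(n), rnorm(n, 3)),
                         rnorm(2 * n)),
                   genes = c("flat", "strong", "noise"))
  labels <- half_half_labels(colnames(expr))
  de <- two_group_test(expr, labels)
  expect_s3_class(de, "de_result")
  expect_equal(de$log2fc[de$gene_id == "flat"], 0)
  expect_equal(de$p_value[de$gene_id == "flat"], 1)
  expect_equal(de$statistic[de$gene_id == "flat"], 0)
  expect_lt(de$p_value[de$gene_id == "strong"], 1e-10)
  expect_lt(abs(de$log2fc[de$gene_id == "strong"] - 3), 0.5)
  expect_true(all(de$adj_p >= de$p_value))

  swapped <- sample_labels(labels$sample_id,
                           ifelse(labels$condition == "A", "B", "A"))
  de2 <- two_group_test(expr, swapped)
  expect_equal(de2$log2fc, -de$log2fc)
  expect_equal(de2$p_value, de$p_value)
})

test_that("Welch test validates its inputs", {
  expr <- toy_expr(matrix(rnorm(40), 4, 10))
  expect_error(
    two_group_test(expr, sample_labels(colnames(expr)[1:7],
                                       rep(c("A", "B"), c(3, 4)))),
    "unlabeled sample")
  expect_error(sample_labels(colnames(expr), rep(c("A", "B"), c(8, 2))),
               ">= 3")
})

test_that("BH adjustment matches the worked example and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
  }
})

test_that("top-k selection ranks, filters and breaks ties as stated", {
  de <- structure(
    data.frame(gene_id = c("G1", "G2", "G3", "G4", "G5"),
               log2fc = c(2, 1, -3, 0.5, 1.5),
               statistic = 1, p_value = 0.001,
               adj_p = c(0.01, 0.01, 0.001, 0.2, 0.04)),
    class = c("de_result", "data.frame"))
  # G1 and G2 tie on adjusted p; larger |log2FC| first
  expect_identical(select_top_k(de, 500, "up"), c("G1", "G2", "G5"))
  expect_identical(select_top_k(de, 2, "up"), c("G1", "G2"))
  expect_identical(select_top_k(de, 500, "down"), "G3")
  de$adj_p <- 0.9
  expect_warning(out <- select_top_k(de, 10, "up"), "no up-regulated")
  expect_length(out, 0)
})

test_that("the DEG definition applies both thresholds", {
  de <- structure(
    data.frame(gene_id = c("A", "B", "C"),
               log2fc = c(1.5, 0.5, -2), statistic = 1,
               p_value = 0.001, adj_p = c(0.01, 0.01, 0.2)),
    class = c("de_result", "data.frame"))
  expect_identical(deg_genes(de), "A")  # B fails FC, C fails adj p
})

test_that("common-pattern intersection behaves as a guarded set operation", {
  cg <- common_pattern_genes(list(up = c("G1", "G2", "G3"), down = "G9"),
                             list(up = c("G2", "G3", "G4"), down = "G8"))
  expect_identical(cg$common_up, c("G2", "G3"))
  expect_length(cg$common_down, 0)
  expect_warning(
    common_pattern_genes(list(up = "G1", down = "G2"),
                         list(up = "G3", down = "G4")),
    "no common")
  expect_error(
    common_pattern_genes(list(up = c("G1", "G2"), down = "G1"),
                         list(up = "G1", down = "G1")),
    "common_up and common_down")
})

test_that("cross-cohort intersection recovers planted shared DE genes", {
  cfg <- sim_config(n_genes = 2000, module_sizes = integer(0),
                    n_key_genes = 0, key_module_lfc = 0,
                    background_lfc = 3,
                    n_shared_up_background = 100, n_shared_down = 0,
                    n_cohort_specific = 50, seed = 21)
  paired <- simulate_paired_cohorts(cfg)
  de <- lapply(paired[c("cohort1", "cohort2")], function(co)
    two_group_test(co$expr, co$labels))
  lists <- lapply(de, function(d)
    list(up = select_top_k(d, 500, "up"),
         down = suppressWarnings(select_top_k(d, 500, "down"))))
  cg <- suppressWarnings(common_pattern_genes(lists[[1]], lists[[2]]))
  planted <- paired$truth$de$gene[paired$truth$de$shared]
  expect_true(all(planted %in% cg$common_up))
})
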