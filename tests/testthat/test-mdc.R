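test_that("module connectivity handles perfect, null and invariance cases", {
  x <- rnorm(20)
  expr <- toy_expr(rbind(x, 2 * x, x + 3), genes = c("a", "b", "c"))
  labels <- half_half_labels(colnames(expr))
  part <- one_module_partition(rownames(expr))
  expect_equal(module_connectivity(expr, labels, part, 1, "A"), 1)

  set.seed(40)
  noise <- toy_expr(matrix(rnorm(20 * 100), 20, 100))
  nl <- half_half_labels(colnames(noise))
  np <- one_module_partition(rownames(noise))
  expect_lt(module_connectivity(noise, nl, np, 1, "A"), 0.2)

  # invariant to gene and sample ordering
  perm_g <- sample(nrow(noise)); perm_s <- sample(ncol(noise))
  shuffled <- noise[perm_g, perm_s]
  expect_equal(module_connectivity(shuffled, nl, np, 1, "A"),
               module_connectivity(noise, nl, np, 1, "A"))
})

test_that("constant genes are excluded, fully degenerate modules error", {
  x <- rnorm(12)
  expr <- toy_expr(rbind(x, x + rnorm(12, 0, 0.1), rep(1, 12)),
                   genes = c("a", "b", "flat"))
  labels <- half_half_labels(colnames(expr))
  part <- one_module_partition(rownames(expr))
  expect_message(v <- module_connectivity(expr, labels, part, 1, "A"),
                 "1 constant gene")
  expect_gt(v, 0.5)
  flat <- toy_expr(rbind(rep(1, 12), rep(2, 12), rep(3, 12)))
  expect_error(
    suppressMessages(module_connectivity(flat, labels,
                                         one_module_partition(rownames(flat)),
                                         1, "A")),
    "all gene pairs excluded")
})

test_that("MDC is 1 for identical conditions and inverts under label swap", {
  set.seed(41)
  half <- matrix(rnorm(30 * 10), 30, 10)
  expr <- toy_expr(cbind(half, half))  # condition B duplicates condition A
  labels <- half_half_labels(colnames(expr))
  part <- one_module_partition(rownames(expr))
  res <- mdc_statistic(expr, labels, part)
  expect_equal(res$mdc, 1, tolerance = 1e-12)
  expect_equal(res$log2_mdc, 0, tolerance = 1e-12)

  cfg <- one_module_config(0.7, 0.3, 25, seed = 42)
  co <- simulate_cohort(cfg, 1)
  p2 <- one_module_partition(rownames(co$expr))
  fwd <- mdc_statistic(co$expr, co$labels, p2)
  swapped <- sample_labels(co$labels$sample_id,
                           ifelse(co$labels$condition == "A", "B", "A"))
  rev <- mdc_statistic(co$expr, swapped, p2)
  expect_equal(fwd$mdc * rev$mdc, 1, tolerance = 1e-9)
})

test_that("MDC estimates the planted connectivity ratio", {
  cfg <- one_module_config(0.6, 0.2, 100, seed = 43)
  co <- simulate_cohort(cfg, 1)
  part <- one_module_partition(rownames(co$expr))
  res <- mdc_statistic(co$expr, co$labels, part)
  expect_lt(abs(res$mdc - 3) / 3, 0.2)
})

test_that("permutation test is seeded and attains the pseudocount floor", {
  cfg <- one_module_config(0.95, 0.05, 40, seed = 44)
  co <- simulate_cohort(cfg, 1)
  part <- one_module_partition(rownames(co$expr))
  r1 <- mdc_permutation_test(co$expr, co$labels, part, n_perm = 100,
                             seed = 7)
  expect_equal(r1$p_value, 1 / 101)
  expect_true(r1$significant)
  r2 <- mdc_permutation_test(co$expr, co$labels, part, n_perm = 100,
                             seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(mdc_permutation_test(co$expr, co$labels, part, n_perm = 10),
               ">= 100")
})

test_that("small modules are reported as missing with a reason", {
  set.seed(45)
  expr <- toy_expr(matrix(rnorm(10 * 12), 10, 12))
  labels <- half_half_labels(colnames(expr))
  labs <- setNames(c(rep(1L, 8), 2L, 2L), rownames(expr))
  part <- structure(list(labels = labs, module_sizes = c(8L, 2L)),
                    class = "module_partition")
  res <- mdc_statistic(expr, labels, part)
  expect_true(is.na(res$mdc[res$module == 2]))
  expect_match(res$reason[res$module == 2], "fewer than 3")
  expect_false(is.na(res$mdc[res$module == 1]))
})
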