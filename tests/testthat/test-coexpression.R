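test_that("variance filter keeps the most variable genes deterministically", {
  base <- rep(c(-1, 1), 5)
  expr <- toy_expr(rbind(base * 1, base * sqrt(2), base * sqrt(3), base * 2),
                   genes = c("g1", "g2", "g3", "g4"))
  expect_identical(rownames(variance_filter(expr, 0.75)),
                   c("g2", "g3", "g4"))
  expect_identical(variance_filter(expr, 1), expr)
  # exact tie at the cut: lexicographically smaller id survives
  tied <- toy_expr(rbind(base, base * 2, base), genes = c("b", "a", "c"))
  expect_identical(rownames(variance_filter(tied, 2 / 3)), c("b", "a"))
})

test_that("unsigned adjacency is |cor|^beta with zero diagonal", {
  set.seed(30)
  x <- rnorm(30)
  expr <- toy_expr(rbind(x, 2 * x + 5, rnorm(30)))
  a <- adjacency_matrix(expr, 6)
  expect_equal(a["G1", "G2"], 1)
  expect_equal(a, t(a))
  expect_equal(unname(diag(a)), rep(0, 3))
  r <- cor(t(expr))
  expect_equal(a["G1", "G3"], abs(r["G1", "G3"])^6, tolerance = 1e-12)
  expr_const <- toy_expr(rbind(x, rep(1, 30)), genes = c("ok", "flat"))
  expect_error(adjacency_matrix(expr_const, 6), "flat")
})

test_that("topological overlap matches hand-computed and oracle values", {
  zero <- matrix(0, 4, 4)
  expect_equal(unname(topological_overlap(zero) - diag(4)),
               matrix(0, 4, 4))
  clique <- matrix(1, 3, 3) - diag(3)
  expect_equal(unname(topological_overlap(clique)), matrix(1, 3, 3))
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(unname(topological_overlap(a)), bf_tom(a),
                 tolerance = 1e-12)
  }
  bad <- matrix(runif(16), 4, 4)
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("two planted blocks are recovered exactly", {
  cfg <- modules_only_config(c(40, 40), 0.8, 50, seed = 32)
  co <- simulate_cohort(cfg, 1)
  tom <- topological_overlap(adjacency_matrix(co$expr, 6))
  part <- detect_modules(co$expr, 1 - tom)
  expect_length(part$module_sizes, 2L)
  truth <- synthetic_truth(cfg)$gene_module[names(part$labels)]
  expect_equal(ari(part$labels, truth), 1.0)
})

test_that("modules with near-identical eigengenes are merged", {
  cfg <- modules_only_config(80, 0.9, 60, seed = 33)
  co <- simulate_cohort(cfg, 1)
  genes <- rownames(co$expr)
  # an artificial split of one true module must be undone by the merge rule
  split_labs <- setNames(rep(c(1L, 2L), each = 40), genes)
  merged <- mdcnet:::.merge_close_modules(co$expr, split_labs, 0.25)
  expect_length(unique(merged), 1L)
  kept <- mdcnet:::.merge_close_modules(co$expr, split_labs, 0.001)
  expect_length(unique(kept), 2L)
})

test_that("undersized clusters are relabelled as background", {
  cfg <- modules_only_config(c(10, 10), 0.9, 40, n_genes = 30, seed = 34)
  co <- simulate_cohort(cfg, 1)
  tom <- topological_overlap(adjacency_matrix(co$expr, 6))
  expect_warning(part <- detect_modules(co$expr, 1 - tom,
                                        min_module_size = 25),
                 "min_module_size")
  expect_true(all(part$labels == 0L))
})

test_that("module eigengenes match the SVD oracle and orient consistently", {
  x <- rnorm(40)
  ident <- toy_expr(rbind(x, x, x))
  part <- one_module_partition(rownames(ident))
  eig <- module_eigengenes(ident, part)
  expect_equal(unname(eig$var_explained), 1)
  expect_equal(abs(cor(eig$eigengenes[, 1], x)), 1)
  expect_gt(cor(eig$eigengenes[, 1], x), 0)  # oriented with members
  expect_equal(sum(eig$eigengenes[, 1]^2), 1)  # unit norm

  set.seed(35)
  for (i in 1:10) {
    m <- toy_expr(matrix(rnorm(15 * 25), 15, 25))
    p <- one_module_partition(rownames(m))
    e <- module_eigengenes(m, p)$eigengenes[, 1]
    ms <- t(scale(t(m)))
    sv <- eigen(crossprod(ms))$vectors[, 1]  # independent route
    expect_gt(abs(cor(e, sv)), 1 - 1e-10)
    # flipping every member flips the eigengene
    e2 <- module_eigengenes(-m, p)$eigengenes[, 1]
    expect_equal(e2, -e, tolerance = 1e-8)
  }
})

test_that("kME flags hubs and stays within [-1, 1]", {
  set.seed(36)
  x <- rnorm(40)
  expr <- toy_expr(rbind(x, x + rnorm(40, 0, 0.01), rnorm(40)),
                   genes = c("m1", "m2", "bg"))
  part <- structure(list(labels = c(m1 = 1L, m2 = 1L, bg = 0L),
                         module_sizes = 2L), class = "module_partition")
  eig <- module_eigengenes(expr, part)
  kt <- kme(expr, eig, part)
  expect_true(all(abs(kt$kme) <= 1 + 1e-12))
  expect_true(kt$hub[["m1"]] && kt$hub[["m2"]])
  expect_false(kt$hub[["bg"]])             # unassigned, never a hub
  expect_lt(abs(kt$kme["bg", 1]), 0.85)    # independent gene, low kME
})

test_that("soft-power selection reaches the scale-free target on graded modules", {
  cfg <- sim_config(n_genes = 600,
                    module_sizes = c(30, 40, 60, 90, 130),
                    rho = matrix(rep(c(0.9, 0.8, 0.7, 0.55, 0.4), 2),
                                 ncol = 2),
                    samples_per_condition = list(c(40, 40), c(13, 16)),
                    key_module_lfc = 0, n_shared_up_background = 0,
                    n_shared_down = 0, n_cohort_specific = 0,
                    n_key_genes = 0, seed = 11)
  expr <- simulate_cohort(cfg, 1)$expr
  p <- pick_soft_power(expr, candidate_powers = c(2, 4, 6, 8, 10))
  fit <- attr(p, "fit")
  expect_gte(fit$signed_r2[fit$power == p], 0.8)
  expect_identical(as.integer(p),
                   as.integer(pick_soft_power(expr,
                                              candidate_powers = c(2, 4, 6, 8, 10))))
  expect_equal(as.integer(pick_soft_power(expr, candidate_powers = 7)), 7L)
})
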