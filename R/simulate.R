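# Synthetic paired-cohort generator.
#
# Each module is a single-factor Gaussian model: gene g in module m gets
#   x_gs = noise_sd * ( sqrt(rho_mc) * z_ms + sqrt(1 - rho_mc) * eps_gs )
# for a sample s in condition c, with independent standard-normal factor z
# and idiosyncratic eps, so the expected within-module pairwise correlation
# is exactly rho_mc and between-module correlation is 0. Differential
# expression is an additive log2-scale shift applied to condition B.
# Background genes are pure noise. The generator also plants a PPI graph
# whose degree concentrates on designated key genes, and gene-set catalogs
# aligned with them, so the full key-gene analysis is recoverable from
# known truth.

#' Configuration for the synthetic two-cohort study
#'
#' Defaults emulate a two-dataset carotid-plaque design: cohort 1 with 32+32
#' samples and cohort 2 with 13+16, five planted modules, a strongly
#' disease-regulated "key" module (module 1) whose intra-module correlation
#' drops between conditions, background differential genes shared across the
#' cohorts plus cohort-specific ones, and 8 designated key genes inside the
#' key module.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes (remaining genes
#'   are independent background). May be empty.
#' @param rho matrix with one row per module and columns A, B: intra-module
#'   correlation per condition, each in `[0, 1)`.
#' @param samples_per_condition list of two integer pairs `c(nA, nB)`, one per
#'   cohort.
#' @param key_module_lfc log2 fold change planted on every module-1 gene
#'   (shared across cohorts); 0 disables.
#' @param background_lfc log2 fold change of background DE genes.
#' @param n_shared_up_background,n_shared_down numbers of background genes
#'   shared-up / shared-down across cohorts.
#' @param n_cohort_specific number of cohort-specific DE genes per cohort.
#' @param n_key_genes number of designated key genes (first genes of module 1,
#'   or of the shared-up background when there are no modules).
#' @param noise_sd standard deviation scale of the factor-model draw.
#' @param seed integer seed; all simulation functions derive theirs from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       module_sizes = c(50, 100, 80, 70, 60),
                       rho = NULL,
                       samples_per_condition = list(c(32, 32), c(13, 16)),
                       key_module_lfc = 3,
                       background_lfc = 1.2,
                       n_shared_up_background = 10,
                       n_shared_down = 40,
                       n_cohort_specific = 50,
                       n_key_genes = 8,
                       noise_sd = 1,
                       seed = 1) {
  module_sizes <- as.integer(module_sizes)
  if (is.null(rho)) {
    default_rho <- rbind(c(0.81, 0.49), c(0.70, 0.30), c(0.30, 0.70),
                         c(0.50, 0.50), c(0.60, 0.60))
    rho <- default_rho[seq_along(module_sizes), , drop = FALSE]
    if (length(module_sizes) > nrow(default_rho))
      .fail("supply rho explicitly for more than 5 modules")
  }
  rho <- matrix(as.numeric(rho), ncol = 2,
                dimnames = list(NULL, c("A", "B")))
  if (nrow(rho) != length(module_sizes))
    .fail("rho needs one row per module")
  if (any(rho < 0 | rho >= 1)) .fail("rho must lie in [0, 1)")
  if (sum(module_sizes) > n_genes)
    .fail("sum(module_sizes) exceeds n_genes")
  if (noise_sd <= 0) .fail("noise_sd must be positive")
  if (length(samples_per_condition) != 2L ||
      !all(vapply(samples_per_condition, length, 0L) == 2L))
    .fail("samples_per_condition must be a list of two c(nA, nB) pairs")
  n_bg <- n_genes - sum(module_sizes)
  n_key_in_bg <- if (length(module_sizes)) 0L else n_key_genes
  need_bg <- n_shared_up_background + n_shared_down + 2L * n_cohort_specific +
    n_key_in_bg
  if (need_bg > n_bg)
    .fail("not enough background genes (%d) for the requested DE layout (%d)",
          n_bg, need_bg)
  if (length(module_sizes) && n_key_genes > module_sizes[1L])
    .fail("n_key_genes exceeds the size of module 1")
  structure(list(n_genes = n_genes, module_sizes = module_sizes, rho = rho,
                 samples_per_condition = samples_per_condition,
                 key_module_lfc = key_module_lfc,
                 background_lfc = background_lfc,
                 n_shared_up_background = n_shared_up_background,
                 n_shared_down = n_shared_down,
                 n_cohort_specific = n_cohort_specific,
                 n_key_genes = n_key_genes,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

# deterministic layout of modules, DE genes and key genes for a config
.sim_truth <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  gene_module <- setNames(integer(config$n_genes), genes)
  at <- 0L
  for (m in seq_along(config$module_sizes)) {
    idx <- at + seq_len(config$module_sizes[m])
    gene_module[idx] <- m
    at <- at + config$module_sizes[m]
  }
  bg <- genes[gene_module == 0L]
  take <- function(n) {
    out <- bg[seq_len(n)]
    bg <<- bg[-seq_len(n)]
    out
  }
  de <- list()
  key_genes <- character(0)
  if (length(config$module_sizes)) {
    m1 <- genes[gene_module == 1L]
    key_genes <- m1[seq_len(config$n_key_genes)]
    if (config$key_module_lfc != 0)
      de$key_module <- data.frame(gene = m1, lfc = config$key_module_lfc,
                                  shared = TRUE, cohort = NA_integer_)
  } else if (config$n_key_genes > 0L) {
    key_genes <- take(config$n_key_genes)
    de$key_bg <- data.frame(gene = key_genes, lfc = config$key_module_lfc,
                            shared = TRUE, cohort = NA_integer_)
  }
  if (config$n_shared_up_background > 0L)
    de$shared_up <- data.frame(gene = take(config$n_shared_up_background),
                               lfc = config$background_lfc,
                               shared = TRUE, cohort = NA_integer_)
  if (config$n_shared_down > 0L)
    de$shared_down <- data.frame(gene = take(config$n_shared_down),
                                 lfc = -config$background_lfc,
                                 shared = TRUE, cohort = NA_integer_)
  for (co in 1:2) if (config$n_cohort_specific > 0L)
    de[[paste0("specific", co)]] <-
      data.frame(gene = take(config$n_cohort_specific),
                 lfc = config$background_lfc, shared = FALSE, cohort = co)
  de <- if (length(de)) do.call(rbind, c(de, make.row.names = FALSE))
  else data.frame(gene = character(0), lfc = numeric(0),
                  shared = logical(0), cohort = integer(0))
  structure(list(gene_ids = genes, gene_module = gene_module,
                 rho = config$rho, de = de, key_genes = key_genes,
                 seed = config$seed, config = config),
            class = "synthetic_truth")
}

#' Ground truth of a synthetic study
#'
#' @param config a [sim_config()].
#' @return a `synthetic_truth` object: gene-to-module map, per-condition
#'   module correlations, the planted DE table (gene, log2 fold change,
#'   shared flag, cohort), designated key genes and the seed.
#' @export
synthetic_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_truth(config)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d genes, %d modules, %d DE rows ",
                     "(%d shared), %d key genes, seed %d\n"),
              length(x$gene_ids), length(x$config$module_sizes), nrow(x$de),
              sum(x$de$shared), length(x$key_genes), x$seed))
  invisible(x)
}

#' Simulate one two-condition cohort
#'
#' @param config a [sim_config()].
#' @param cohort 1 or 2 (selects sample sizes and cohort-specific DE genes).
#' @return list with `expr` (genes x samples matrix) and `labels`
#'   ([sample_labels()]).
#' @export
simulate_cohort <- function(config, cohort = 1) {
  stopifnot(inherits(config, "sim_config"), cohort %in% 1:2)
  truth <- .sim_truth(config)
  .simulate_cohort_impl(config, truth, cohort)
}

.simulate_cohort_impl <- function(config, truth, cohort) {
  set.seed(derive_seed(config$seed, paste0("cohort", cohort)))
  ns <- config$samples_per_condition[[cohort]]
  nA <- ns[1L]; nB <- ns[2L]; ntot <- nA + nB
  G <- config$n_genes
  conds <- rep(c("A", "B"), c(nA, nB))
  X <- matrix(rnorm(G * ntot), G, ntot)
  M <- length(config$module_sizes)
  for (cond in c("A", "B")) {
    cols <- which(conds == cond)
    if (M > 0L) {
      Z <- matrix(rnorm(M * length(cols)), M, length(cols))
      for (m in seq_len(M)) {
        idx <- which(truth$gene_module == m)
        r <- config$rho[m, cond]
        X[idx, cols] <- sqrt(r) * matrix(Z[m, ], length(idx), length(cols),
                                         byrow = TRUE) +
          sqrt(1 - r) * X[idx, cols]
      }
    }
  }
  X <- config$noise_sd * X
  de <- truth$de
  de <- de[de$shared | (!is.na(de$cohort) & de$cohort == cohort), , drop = FALSE]
  if (nrow(de)) {
    bcols <- which(conds == "B")
    idx <- match(de$gene, truth$gene_ids)
    X[idx, bcols] <- X[idx, bcols] + de$lfc
  }
  rownames(X) <- truth$gene_ids
  colnames(X) <- sprintf("C%d_S%03d", cohort, seq_len(ntot))
  labels <- sample_labels(colnames(X), conds)
  list(expr = X, labels = labels)
}

#' Simulate the paired two-cohort study
#'
#' Both cohorts share gene identifiers, module structure and the shared DE
#' genes; cohort-specific DE genes differ.
#'
#' @param config a [sim_config()].
#' @return list with `cohort1`, `cohort2` (each `expr` + `labels`) and
#'   `truth` (a [synthetic_truth()]).
#' @export
simulate_paired_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- .sim_truth(config)
  list(cohort1 = .simulate_cohort_impl(config, truth, 1L),
       cohort2 = .simulate_cohort_impl(config, truth, 2L),
       truth = truth)
}

#' Simulate a PPI graph concentrated on the key genes
#'
#' Every designated key gene receives `key_gene_degree_boost` edges to
#' partners drawn from the shared DE genes (its functional neighbourhood);
#' all other pairs follow an Erdos-Renyi background. Undirected, no
#' self-loops.
#'
#' @param truth a [synthetic_truth()].
#' @param background_edge_prob background edge probability per gene pair.
#' @param key_gene_degree_boost number of planted edges per key gene.
#' @param seed integer seed (default derived from the truth's seed).
#' @return a [ppi_graph()].
#' @export
simulate_ppi <- function(truth, background_edge_prob = 5e-4,
                         key_gene_degree_boost = 30, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(seed)) seed <- derive_seed(truth$seed, "ppi")
  set.seed(seed)
  genes <- truth$gene_ids
  G <- length(genes)
  from <- character(0); to <- character(0)
  if (background_edge_prob > 0) {
    npairs <- G * (G - 1) / 2
    m <- rbinom(1L, npairs, background_edge_prob)
    if (m > 0L) {
      seen <- character(0)
      while (length(seen) < m) {
        i <- sample.int(G, 2L * (m - length(seen)) + 10L, replace = TRUE)
        j <- sample.int(G, length(i), replace = TRUE)
        ok <- i != j
        key <- paste(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
        seen <- unique(c(seen, key))
      }
      seen <- seen[seq_len(m)]
      ij <- do.call(rbind, strsplit(seen, " ", fixed = TRUE))
      from <- genes[as.integer(ij[, 1L])]
      to <- genes[as.integer(ij[, 2L])]
    }
  }
  if (key_gene_degree_boost > 0L && length(truth$key_genes)) {
    shared <- truth$de$gene[truth$de$shared]
    for (kg in truth$key_genes) {
      pool <- setdiff(shared, kg)
      if (length(pool) < key_gene_degree_boost)
        .fail("shared-DE pool (%d) too small for key_gene_degree_boost = %d",
              length(pool), key_gene_degree_boost)
      partners <- sample(pool, key_gene_degree_boost)
      from <- c(from, rep(kg, length(partners)))
      to <- c(to, partners)
    }
  }
  suppressMessages(ppi_graph(from, to))
}

#' Simulate a gene-set catalog aligned with the key genes
#'
#' Plants `sets_per_key_gene` "signature" sets, each containing every key
#' gene plus `signature_extras` background shared-DE genes; the remaining
#' sets are decoys drawn from the non-DE background, with a fraction
#' `overlap_noise` of each decoy's members drawn from the whole universe.
#'
#' @param truth a [synthetic_truth()].
#' @param n_sets total number of sets.
#' @param sets_per_key_gene number of signature sets (each contains all key
#'   genes).
#' @param signature_extras background shared-DE members per signature set.
#' @param decoy_size_range integer range of decoy set sizes.
#' @param overlap_noise fraction of decoy members drawn from the full
#'   universe rather than the non-DE background.
#' @param seed integer seed (default derived from the truth's seed).
#' @return a [gene_set_catalog()].
#' @export
simulate_gene_sets <- function(truth, n_sets = 50, sets_per_key_gene = 15,
                               signature_extras = 7,
                               decoy_size_range = c(10, 30),
                               overlap_noise = 0.1, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(seed)) seed <- derive_seed(truth$seed, "gene_sets")
  set.seed(seed)
  genes <- truth$gene_ids
  non_de_bg <- setdiff(genes[truth$gene_module == 0L], truth$de$gene)
  shared_bg_de <- setdiff(truth$de$gene[truth$de$shared], truth$key_genes)
  shared_bg_de <- shared_bg_de[truth$gene_module[shared_bg_de] == 0L]
  n_signature <- if (length(truth$key_genes)) min(sets_per_key_gene, n_sets)
  else 0L
  sets <- list()
  descr <- character(0)
  for (s in seq_len(n_signature)) {
    extras <- if (length(shared_bg_de))
      sample(shared_bg_de, min(signature_extras, length(shared_bg_de)))
    else character(0)
    sets[[sprintf("SET%03d", s)]] <- c(truth$key_genes, extras)
    descr <- c(descr, "synthetic signature set")
  }
  for (s in seq_len(n_sets - n_signature) + n_signature) {
    size <- sample(decoy_size_range[1L]:decoy_size_range[2L], 1L)
    n_noise <- rbinom(1L, size, overlap_noise)
    members <- c(sample(non_de_bg, min(size - n_noise, length(non_de_bg))),
                 if (n_noise) sample(genes, n_noise))
    sets[[sprintf("SET%03d", s)]] <- unique(members)
    descr <- c(descr, "synthetic background set")
  }
  gene_set_catalog(sets, descr, namespace = "GOBP-like")
}
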