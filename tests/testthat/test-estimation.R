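test_that("normalization log-transforms then rescales each cell to the target sum", {
  one <- matrix(c(0, 7, 0), nrow = 1)
  expect_equal(as.numeric(normalize_cells(one)), c(0, 1e6, 0))
  two <- matrix(c(1, 1), nrow = 1)
  expect_equal(as.numeric(normalize_cells(two)), c(5e5, 5e5))
  logs <- matrix(c(exp(1) - 1, exp(2) - 1), nrow = 1)
  expect_equal(as.numeric(normalize_cells(logs)), c(1e6 / 3, 2e6 / 3))
  expect_error(normalize_cells(matrix(c(-1, 2), nrow = 1)), "negative")
})

test_that("all-zero cells stay zero and are flagged", {
  m <- rbind(c(0, 0), c(1, 3))
  n <- normalize_cells(m)
  expect_equal(attr(n, "zero_cells"), 1L)
  expect_equal(n[1, ], c(0, 0))
  expect_equal(sum(n[2, ]), 1e6)
})

test_that("normalization handles sparse matrices identically", {
  set.seed(2)
  m <- matrix(rpois(60, 1), nrow = 6,
              dimnames = list(paste0("c", 1:6), paste0("g", 1:10)))
  dense <- normalize_cells(m)
  sparse <- normalize_cells(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(as.matrix(sparse), dense, ignore_attr = TRUE)
  expect_equal(attr(sparse, "zero_cells"), attr(dense, "zero_cells"))
})

test_that("pseudobulk is the per-sample mean of cell values", {
  m <- matrix(c(0, 0, 10, 10, 10,
                1, 2, 3, 4, 5), ncol = 2,
              dimnames = list(paste0("c", 1:5), c("gA", "gB")))
  sc <- single_cell_dataset(m, rep("s1", 5), c(s1 = "C", s2 = "C"))
  expect_error(pseudobulk(sc), "no cells")     # s2 declared but empty
  sc1 <- single_cell_dataset(m, rep("s1", 5), c(s1 = "C"))
  pb <- pseudobulk(sc1)
  expect_equal(pb["s1", "gA"], 6)
  expect_equal(pb["s1", "gB"], 3)
  # one cell per sample: pseudobulk equals the cell
  sc5 <- single_cell_dataset(m, paste0("s", 1:5),
                             stats::setNames(rep("C", 5), paste0("s", 1:5)))
  expect_equal(unname(pseudobulk(sc5)), unname(m))
})

test_that("pseudobulk of simulated cells matches the donor-level prediction", {
  panel <- list(g = gene_archetype("g", group_params(25, 20, 0.5, 0.5, 0.5, 0.01)))
  fx <- generate_dataset(panel, samples_per_group = 3,
                         cells_per_sample = 2000, seed = 31)
  pb <- pseudobulk(fx$dataset)
  tr <- fx$truth
  pred <- tr$r * tr$mu_plus + (1 - tr$r) * tr$mu_minus
  # per-donor cell-mean SE from the mixture variance
  cell_var <- tr$r * 1 + (1 - tr$r) * 1 +
    tr$r * (1 - tr$r) * (tr$mu_plus - tr$mu_minus)^2
  se <- sqrt(cell_var / 2000)
  expect_true(all(abs(pb[tr$sample_id, "g"] - pred) < 4 * se))
})

test_that("the expression filter is strict at the threshold", {
  bulk <- matrix(c(5, 5, 20, 20, 25, 25), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("low", "edge", "high")))
  kept <- filter_genes(bulk, threshold = 20)
  expect_equal(as.character(kept), "high")
  expect_equal(attr(kept, "grand_means"),
               c(low = 5, edge = 20, high = 25))
  zero <- matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "dead"))
  expect_length(filter_genes(zero), 0)
})

test_that("DE/DV tests match direct Welch t and two-sided F computations", {
  set.seed(9)
  bulk <- cbind(gA = rnorm(12, 10), gB = c(rnorm(6, 10, 1), rnorm(6, 14, 3)))
  rownames(bulk) <- paste0("s", 1:12)
  groups <- rep(c("C", "D"), each = 6)
  res <- de_dv_test(bulk, groups)
  for (g in c("gA", "gB")) {
    x <- bulk[1:6, g]; y <- bulk[7:12, g]
    expect_equal(res$t_p[res$gene == g], t.test(y, x)$p.value)
    expect_equal(res$f_p[res$gene == g], var.test(y, x)$p.value)
  }
  expect_equal(res$t_p_adj, p.adjust(res$t_p, "BH"))
  expect_equal(res$f_p_adj, p.adjust(res$f_p, "BH"))
  expect_true(all(res$t_p_adj >= res$t_p))
  expect_equal(res$de, res$t_p_adj < 0.05)
})

test_that("BH-adjusted p-values are monotone and degrading p never adds flags", {
  set.seed(14)
  bulk <- matrix(rnorm(10 * 50, 100), nrow = 10,
                 dimnames = list(paste0("s", 1:10), paste0("g", 1:50)))
  bulk[6:10, 1] <- bulk[6:10, 1] + 50   # one strong DE gene
  groups <- rep(c("C", "D"), each = 5)
  res <- de_dv_test(bulk, groups)
  ord <- order(res$t_p)
  expect_true(all(diff(res$t_p_adj[ord]) >= -1e-12))
  expect_true(all(res$t_p_adj >= res$t_p & res$t_p_adj <= 1))
  # degrade: double every p (cap at 1) and re-apply BH
  degraded <- pmin(res$t_p * 2, 1)
  expect_true(all(p.adjust(degraded, "BH") >= res$t_p_adj - 1e-12))
  expect_lte(sum(p.adjust(degraded, "BH") < 0.05), sum(res$de))
})

test_that("zero-variance degeneracies follow the stated conventions", {
  bulk <- cbind(const_eq = rep(5, 8),
                const_ne = rep(c(1, 2), each = 4),
                half = c(rep(3, 4), rnorm(4)))
  rownames(bulk) <- paste0("s", 1:8)
  res <- de_dv_test(bulk, rep(c("C", "D"), each = 4))
  eq <- res[res$gene == "const_eq", ]
  expect_equal(eq$t_p, 1)
  expect_equal(eq$f_p, 1)
  expect_true(eq$degenerate)
  ne <- res[res$gene == "const_ne", ]
  expect_equal(ne$t_p, 0)
  expect_true(ne$degenerate)
  half <- res[res$gene == "half", ]
  expect_equal(half$f_p, 0)
  expect_true(half$degenerate)
})

test_that("testing refuses unbalanced or single-sample designs", {
  bulk <- matrix(rnorm(6), nrow = 3,
                 dimnames = list(paste0("s", 1:3), c("g1", "g2")))
  expect_error(de_dv_test(bulk, c("C", "C", "D")), "at least two samples")
  expect_error(de_dv_test(bulk, c("C", "C", "C")), "exactly two groups")
  expect_error(de_dv_test(bulk, c("A", "B", "C")), "exactly two groups")
})

test_that("decomposition returns the optimal threshold split", {
  est <- decompose_sample(c(0, 0, 0, 10, 10))
  expect_equal(est$mu_plus_hat, 10)
  expect_equal(est$mu_minus_hat, 0)
  expect_equal(est$r_hat, 0.4)
  expect_false(est$degenerate)
  same <- decompose_sample(rep(3.7, 6))
  expect_equal(same$mu_plus_hat, 3.7)
  expect_equal(same$mu_minus_hat, 3.7)
  expect_equal(same$r_hat, 0)
  expect_true(same$degenerate)
  expect_error(decompose_sample(numeric(0)), "at least one")
})

test_that("1-D 2-means matches the exhaustive-partition oracle", {
  set.seed(77)
  cases <- c(
    list(c(0, 0, 0, 10, 10), c(1, 2), c(-5, 0, 5), c(0, 1, 1, 1, 8)),
    lapply(1:60, function(i) {
      n <- sample(2:12, 1)
      if (runif(1) < 0.5) round(rnorm(n, 0, 3), 1)
      else c(rnorm(n %/% 2 + 1, 0, 1), rnorm(n - n %/% 2 - 1, 6, 1))
    }))
  for (v in cases) {
    if (length(unique(v)) < 2) next
    est <- decompose_sample(v)
    n_plus <- round(est$r_hat * length(v))
    got <- wss2(sort(v), seq_along(v) > length(v) - n_plus)
    expect_equal(got, best_partition_wss(v), tolerance = 1e-10)
  }
})

test_that("decomposition never does worse than Lloyd k-means from extreme init", {
  set.seed(78)
  for (i in 1:25) {
    v <- c(rnorm(15, 0), rnorm(10, 5))
    km <- stats::kmeans(v, centers = matrix(range(v)), algorithm = "Lloyd")
    est <- decompose_sample(v)
    n_plus <- round(est$r_hat * length(v))
    got <- wss2(sort(v), seq_along(v) > length(v) - n_plus)
    # exact threshold scan is the global optimum; Lloyd may only match it
    expect_lte(got, km$tot.withinss + 1e-8)
  }
})

test_that("subset parameters are recovered under strong separation", {
  arch <- gene_archetype("sep", group_params(2, 1, 0.6, 0.02, 0.02, 0.002),
                         v_y_plus = 0.01, v_y_minus = 0.01)
  fx <- generate_dataset(list(arch), samples_per_group = 3,
                         cells_per_sample = 5000, seed = 41)
  dec <- decompose_gene(fx$dataset, "sep")
  tr <- fx$truth[match(dec$sample_id, fx$truth$sample_id), ]
  expect_true(all(abs(dec$r_hat - tr$r) < 0.05))
  expect_true(all(abs(dec$mu_plus_hat - tr$mu_plus) < 0.05))
  expect_true(all(abs(dec$mu_minus_hat - tr$mu_minus) < 0.05))
})

test_that("recovery bias in r shrinks as component separation grows", {
  seps <- c(1, 3, 10)     # |mu+ - mu-| in units of the cell SD (Vy = 1)
  bias <- vapply(seps, function(s) {
    set.seed(50 + s)
    cfg <- sim_config(2, 4000)
    errs <- replicate(8, {
      y <- simulate_cells(list(mu_plus = s, mu_minus = 0, r = 0.4), cfg)
      abs(decompose_sample(y)$r_hat - 0.4)
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.02)
})

test_that("the pipeline flags engineered genes and refuses degenerate designs", {
  panel <- archetype_panel(n_null = 6)
  fx <- generate_dataset(panel, samples_per_group = 40,
                         cells_per_sample = 300, seed = 61)
  res <- run_pipeline(fx$dataset, normalize = FALSE,
                      decompose_genes = "cancel")
  expect_equal(res$log$n_genes_tested, length(panel))
  expect_equal(res$log$top_de_gene, "de")
  expect_true(res$tests$de[res$tests$gene == "de"])
  expect_true(all(c("de", "cancel") %in% res$decomposition$gene))
  expect_false(res$tests$de[res$tests$gene == "cancel"])
  # refusal with one sample in a group
  m <- fx$dataset$matrix[fx$dataset$cells$sample_id %in% c("C001", "C002", "D001"), 1:2]
  sub <- single_cell_dataset(
    m, rep(c("C001", "C002", "D001"), each = 300),
    c(C001 = "C", C002 = "C", D001 = "D"))
  expect_error(run_pipeline(sub, normalize = FALSE), ">= 2 samples")
})

test_that("an empty post-filter gene set warns and returns empty results", {
  low <- gene_archetype("low", group_params(3, 1, 0.5, 0.1, 0.1, 0.001),
                        label = "filtered")
  fx <- generate_dataset(list(low), samples_per_group = 2,
                         cells_per_sample = 30, seed = 71)
  expect_warning(res <- run_pipeline(fx$dataset, normalize = FALSE),
                 "no genes pass")
  expect_null(res$tests)
  expect_equal(res$log$n_genes_tested, 0)
})
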