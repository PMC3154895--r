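test_that("pearson_matrix reproduces hand-computed correlations", {
  vals <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
                g3 = c(4, 3, 2, 1), g4 = c(1, 3, 2, 4))
  colnames(vals) <- c("T01", "T02", "N01", "N02")
  em <- expr_matrix(vals, c(T01 = "tumor", T02 = "tumor",
                            N01 = "normal", N02 = "normal"))
  cm <- pearson_matrix(em)
  expect_equal(cm["g1", "g2"], 1.0)
  expect_equal(cm["g1", "g3"], -1.0)
  expect_equal(cm["g1", "g4"], 0.8)   # cov = 4/3; sd product = 5/3
  expect_equal(diag(cm), setNames(rep(1, 4), rownames(vals)))
})

test_that("pearson_matrix matches the two-pass formula on random data", {
  for (s in 1:5) {
    vals <- withr::with_seed(s, matrix(rnorm(50), 10, 5))
    rownames(vals) <- sprintf("g%02d", 1:10)
    colnames(vals) <- sprintf("%s%02d", c("T", "T", "T", "N", "N"), 1:5)
    em <- expr_matrix(vals, setNames(rep(c("tumor", "normal"), c(3, 2)),
                                     colnames(vals)))
    cm <- pearson_matrix(em)
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(cm[i, j], oracle_pearson(vals[i, ], vals[j, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate expression input is rejected or repaired", {
  vals <- rbind(g1 = c(1, 2), g2 = c(2, 1))
  colnames(vals) <- c("T01", "N01")
  em <- expr_matrix(vals, c(T01 = "tumor", N01 = "normal"))
  expect_error(pearson_matrix(em), "3 samples")

  vals2 <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(3, 1, 2))
  colnames(vals2) <- c("T01", "T02", "N01")
  em2 <- expr_matrix(vals2, c(T01 = "tumor", T02 = "tumor", N01 = "normal"))
  expect_warning(cm <- pearson_matrix(em2), "g2")
  expect_equal(rownames(cm), c("g1", "g3"))
})

test_that("thresholding keeps exactly the pairs at or above the cutoff", {
  cm <- diag(3)
  dimnames(cm) <- list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  cm["g1", "g2"] <- cm["g2", "g1"] <- 0.95
  cm["g1", "g3"] <- cm["g3", "g1"] <- 0.60
  cm["g2", "g3"] <- cm["g3", "g2"] <- 0.50
  g94 <- build_network(cm, 0.94)
  expect_equal(n_nodes(g94), 2)
  expect_equal(n_edges(g94), 1)
  g50 <- build_network(cm, 0.5)
  expect_equal(n_nodes(g50), 3)
  expect_equal(n_edges(g50), 3)

  cm["g1", "g2"] <- cm["g2", "g1"] <- -0.97
  gneg <- build_network(cm, 0.94)
  expect_equal(gneg$pcc, -0.97)
})

test_that("edge sets nest monotonically as the cutoff rises", {
  sim <- simulate_expression(sim_config(n_genes = 60,
                                        module_sizes = c(20L, 20L),
                                        background_genes = 20L, seed = 3))
  cm <- pearson_matrix(sim$expression)
  taus <- c(0.5, 0.7, 0.9, 0.95)
  nets <- lapply(taus, function(t) build_network(cm, t))
  for (i in seq_len(length(taus) - 1)) {
    lo <- paste(nets[[i]]$gene_a, nets[[i]]$gene_b)
    hi <- paste(nets[[i + 1]]$gene_a, nets[[i + 1]]$gene_b)
    expect_true(all(hi %in% lo))
  }
})

test_that("threshold scan saturates and empties at the extremes", {
  # four exactly collinear genes: every |r| = 1
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6),
                g3 = c(3, 2, 1), g4 = c(10, 20, 30))
  colnames(vals) <- c("T01", "T02", "N01")
  em <- expr_matrix(vals, c(T01 = "tumor", T02 = "tumor", N01 = "normal"))
  scan <- threshold_scan(pearson_matrix(em), with_modularity = FALSE)
  expect_true(all(scan$n_edges == 6))
  expect_true(all(diff(scan$n_edges) <= 0))

  cm0 <- diag(3) * 0 + 0.2
  diag(cm0) <- 1
  dimnames(cm0) <- list(paste0("g", 1:3), paste0("g", 1:3))
  scan0 <- threshold_scan(cm0, with_modularity = FALSE)
  expect_true(all(scan0$n_edges == 0))
})

test_that("planted modules fragment the network at stringent cutoffs", {
  sim <- simulate_expression(sim_config(n_genes = 100,
                                        module_sizes = rep(20L, 4),
                                        background_genes = 20L, seed = 8))
  scan <- threshold_scan(pearson_matrix(sim$expression),
                         with_modularity = FALSE)
  comp_050 <- scan$n_components[abs(scan$cutoff - 0.5) < 1e-9]
  comp_094 <- scan$n_components[abs(scan$cutoff - 0.94) < 1e-9]
  expect_gt(comp_094, comp_050)
})

test_that("cutoff selection maximises modularity under the node floor", {
  scan <- tibble::tibble(cutoff = c(0.5, 0.7, 0.94, 0.96),
                         n_nodes = c(100, 80, 40, 5),
                         n_edges = c(500, 200, 60, 4),
                         n_components = c(1, 3, 8, 2),
                         density = c(0.1, 0.06, 0.07, 0.4),
                         modularity = c(0.3, 0.6, 0.9, 0.95))
  expect_equal(select_cutoff(scan, min_node_fraction = 0.1, n_genes = 100),
               0.94)
  # flat modularity: tie broken toward the larger admissible cutoff
  scan$modularity <- 0.5
  expect_equal(select_cutoff(scan, 0.1, n_genes = 100), 0.94)
  # binding node floor
  expect_equal(select_cutoff(scan, 0.9, n_genes = 100), 0.5)
  expect_error(select_cutoff(scan, 0.9, n_genes = 200), "min_node_fraction")
})

test_that("at the selected cutoff most recovered edges are intra-module", {
  frac_within <- vapply(1:10, function(s) {
    sim <- simulate_expression(sim_config(n_genes = 100,
                                          module_sizes = rep(20L, 4),
                                          background_genes = 20L,
                                          loading = 0.95, noise_sd = 0.3,
                                          seed = s))
    cm <- pearson_matrix(sim$expression)
    scan <- threshold_scan(cm, seed = derive_seed_for_tests(s))
    net <- build_network(cm, select_cutoff(scan))
    mod <- setNames(sim$truth$module, sim$truth$gene)
    within <- mod[net$gene_a] == mod[net$gene_b] &
      mod[net$gene_a] != "background"
    mean(within)
  }, 1.0)
  expect_true(all(frac_within >= 0.9))
})
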