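test_that("modularity matches hand-evaluated partitions", {
  tt <- two_triangles_net()
  by_comp <- setNames(rep(c("x", "y"), each = 3), network_nodes(tt))
  expect_equal(modularity_q(tt, by_comp), 0.5)

  one <- setNames(rep("all", 6), network_nodes(tt))
  expect_equal(modularity_q(tt, one), 0.0)

  edge <- net_from_pairs("a", "b")
  singletons <- c(a = "1", b = "2")
  expect_equal(modularity_q(edge, singletons), -0.5)

  expect_error(modularity_q(tt, c(a = "1")), "cover")
})

test_that("louvain recovers the modularity-optimal toy partitions", {
  # two triangles joined by a bridge: optimum is the two triangles
  bt <- bridged_triangles_net()
  part <- louvain_cluster(bt, seed = 3)
  expect_equal(length(unique(part$community)), 2)
  expect_equal(attr(part, "Q"), 5 / 14, tolerance = 1e-12)
  lab <- setNames(part$community, part$gene)
  expect_equal(length(unique(lab[c("a", "b", "c")])), 1)
  expect_equal(length(unique(lab[c("d", "e", "f")])), 1)

  # complete graph: no split improves on a single community
  k5 <- louvain_cluster(complete_net(5), seed = 1)
  expect_equal(length(unique(k5$community)), 1)
  expect_equal(attr(k5, "Q"), 0)

  # disjoint triangles
  tt <- louvain_cluster(two_triangles_net(), seed = 9)
  expect_equal(length(unique(tt$community)), 2)
  expect_equal(attr(tt, "Q"), 0.5)
})

test_that("louvain Q is self-consistent and near the enumeration optimum", {
  for (s in 1:4) {
    nn <- withr::with_seed(s + 50, sample(6:7, 1))
    ne <- withr::with_seed(s + 60, sample(nn:(nn + 4), 1))
    g <- random_net(nn, ne, seed = s + 70)
    part <- louvain_cluster(g, seed = s)
    # reported Q equals an independent recomputation
    expect_equal(attr(part, "Q"),
                 modularity_q(g, setNames(part$community, part$gene)),
                 tolerance = 1e-12)
    # Q at or above the 95th percentile of ALL partitions of the nodes
    oracle <- oracle_best_modularity(g)
    expect_gte(attr(part, "Q"),
               stats::quantile(oracle$all_q, 0.95, names = FALSE) - 1e-12)
  }
  # and attains the exact maximum on the toy graphs
  bt <- bridged_triangles_net()
  expect_equal(attr(louvain_cluster(bt, seed = 2), "Q"),
               oracle_best_modularity(bt)$max_q, tolerance = 1e-12)
})

test_that("louvain is deterministic given a seed and agrees with igraph", {
  g <- random_net(25, 40, seed = 123)
  p1 <- louvain_cluster(g, seed = 11)
  p2 <- louvain_cluster(g, seed = 11)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  # independent implementation cross-check on a clean modular graph
  sim <- simulate_expression(sim_config(n_genes = 60,
                                        module_sizes = c(20L, 20L),
                                        background_genes = 20L, seed = 4))
  net <- build_network(pearson_matrix(sim$expression), 0.8)
  ours <- louvain_cluster(net, seed = 5)
  ig <- igraph::graph_from_data_frame(net[, 1:2], directed = FALSE)
  theirs <- withr::with_seed(5, igraph::cluster_louvain(ig))
  expect_equal(attr(ours, "Q"), max(theirs$modularity), tolerance = 0.02)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  expect_equal(phyper_tail_via_package(N = 10, K = 5, n = 5, k = 5),
               1 / 252, tolerance = 1e-12)
  expect_equal(phyper_tail_via_package(10, 5, 5, 0), 1.0)
  expect_equal(phyper_tail_via_package(10, 5, 5, 3),
               oracle_hyper_tail(10, 5, 5, 3), tolerance = 1e-12)
  for (k in 0:5) {
    expect_equal(phyper_tail_via_package(10, 5, 5, k),
                 oracle_hyper_tail(10, 5, 5, k), tolerance = 1e-12)
  }
})

test_that("cluster enrichment respects background, size floor and BH", {
  part <- tibble::tibble(gene = sprintf("g%02d", 1:30),
                         community = rep(c(1, 2, 3), c(12, 12, 6)))
  sets <- tibble::tibble(term_id = c("T1", "T2"),
                         description = c("set one", "set two"),
                         genes = list(sprintf("g%02d", 1:12),
                                      sprintf("g%02d", 13:24)))
  out <- hypergeom_enrich(part, sets, min_cluster_size = 10)
  # the 6-gene cluster is below the floor
  expect_setequal(unique(out$cluster), c("1", "2"))
  expect_equal(nrow(out), 4)
  top <- out[out$cluster == "1", ][1, ]
  expect_equal(top$term_id, "T1")
  expect_equal(top$k, 12)
  expect_true(all(out$p_adj >= out$p))
  expect_true(!is.unsorted(out$p))
  # genes outside the background are rejected
  expect_error(hypergeom_enrich(part, sets, background = sprintf("g%02d", 1:10)),
               "background")
})

test_that("louvain recovers planted modules and enrichment ranks them first", {
  stats <- purrr::map(1:10, function(s) {
    # ten 20-gene modules, no background, no group shifts: the clean
    # planted-structure regime; cutoff below the population
    # within-module correlation a^2 / (a^2 + sigma^2) ~ 0.91
    sim <- simulate_expression(sim_config(n_genes = 200,
                                          module_sizes = rep(20L, 10),
                                          background_genes = 0L,
                                          loading = 0.95, noise_sd = 0.3,
                                          de_fraction = 0, seed = s))
    net <- build_network(pearson_matrix(sim$expression), 0.8)
    part <- louvain_cluster(net, seed = 6000 + s)
    mod <- setNames(sim$truth$module, sim$truth$gene)[part$gene]
    ari <- mclust::adjustedRandIndex(part$community, mod)
    enr <- hypergeom_enrich(part, sim$gene_sets, min_cluster_size = 20)
    top_ok <- vapply(unique(enr$cluster), function(cl) {
      members <- part$gene[part$community == as.integer(cl)]
      dominant <- names(sort(table(mod[members]), decreasing = TRUE))[1]
      rows <- enr[enr$cluster == cl, ]
      rows$term_id[which.min(rows$p)] == dominant
    }, TRUE)
    list(ari = ari, top_ok = all(top_ok), n_tested = length(top_ok))
  })
  expect_gte(mean(vapply(stats, `[[`, 1.0, "ari")), 0.9)
  expect_true(all(vapply(stats, `[[`, TRUE, "top_ok")))
  expect_true(all(vapply(stats, `[[`, 1L, "n_tested") >= 5))
})
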