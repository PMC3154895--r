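test_that("pooled t-statistics match hand-derived values", {
  vals <- rbind(gA = c(4, 5, 6, 1, 2, 3),
                gB = c(1, 2, 3, 1, 2, 3),
                gC = c(1, 2, 3, 4, 5, 6))
  em <- make_em(vals, n_tumor = 3, n_normal = 3, genes = rownames(vals))
  de <- ttest_de(em)
  # pooled s^2 = 1, SE = sqrt(2/3), t = 3 / SE
  expect_equal(de$t[de$gene == "gA"], 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(de$p[de$gene == "gA"], 2 * pt(3 / sqrt(2 / 3), 4,
                                             lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(de$direction[de$gene == "gA"], "up")
  expect_equal(de$t[de$gene == "gB"], 0)
  expect_equal(de$p[de$gene == "gB"], 1)
  expect_false(de$significant[de$gene == "gB"])
  expect_equal(de$t[de$gene == "gC"], -de$t[de$gene == "gA"])
  expect_equal(de$direction[de$gene == "gC"], "down")
})

test_that("t-test columns agree with stats::t.test on random matrices", {
  for (s in 1:3) {
    vals <- withr::with_seed(s, matrix(rnorm(20 * 13), 20, 13))
    em <- make_em(vals, n_tumor = 9, n_normal = 4)
    de <- ttest_de(em)
    welch <- ttest_de(em, var_equal = FALSE)
    for (i in c(1, 7, 20)) {
      ref <- stats::t.test(vals[i, 1:9], vals[i, 10:13], var.equal = TRUE)
      expect_equal(de$t[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(de$p[i], ref$p.value, tolerance = 1e-10)
      refw <- stats::t.test(vals[i, 1:9], vals[i, 10:13])
      expect_equal(welch$t[i], unname(refw$statistic), tolerance = 1e-10)
      expect_equal(welch$p[i], refw$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate groups and constant genes are handled", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(2, 2, 2))
  em <- make_em(vals, n_tumor = 1, n_normal = 2, genes = rownames(vals))
  expect_error(ttest_de(em), "2 samples")

  vals2 <- rbind(g1 = c(5, 5, 5, 5), g2 = c(1, 2, 3, 4))
  em2 <- make_em(vals2, n_tumor = 2, n_normal = 2, genes = rownames(vals2))
  expect_warning(de <- ttest_de(em2), "zero pooled variance")
  expect_true(is.na(de$t[de$gene == "g1"]))
  expect_false(de$significant[de$gene == "g1"])
})

test_that("DE bookkeeping counts and percentages", {
  tab <- tibble::tibble(direction = c(rep("up", 539), rep("down", 401),
                                      rep(NA, 100)))
  counts <- de_counts(tab, background_size = 3470)
  expect_equal(counts$n_total, 940)
  expect_equal(counts$n_up, 539)
  expect_equal(counts$n_down, 401)
  expect_equal(counts$percent, 27)

  empty <- de_counts(tibble::tibble(direction = character()),
                     background_size = 0)
  expect_equal(unlist(empty), c(n_up = 0, n_down = 0, n_total = 0,
                                fraction = 0, percent = 0))
})

test_that("network overlay flags DE and listed genes per node", {
  g <- bridged_triangles_net()
  de <- tibble::tibble(gene = network_nodes(g),
                       significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                       direction = c("up", "down", NA, NA, NA, NA))
  class(de) <- c("de_table", class(de))
  ov <- overlay_network(g, de = de, gene_list = c("a", "d", "zz"))
  expect_equal(nrow(ov), 6)
  sm <- attr(ov, "summary")
  expect_equal(sm$n_de, 2)
  expect_equal(sm$pct_de, 33)
  expect_equal(sm$n_listed, 2)
  expect_equal(sm$pct_listed, 33)
  ov_none <- overlay_network(g, de = de, gene_list = character())
  expect_equal(attr(ov_none, "summary")$n_listed, 0)
  ov_all <- overlay_network(g, de = de, gene_list = network_nodes(g))
  expect_equal(attr(ov_all, "summary")$pct_listed, 100)
})

test_that("the CRE filter reproduces the published seven-gene panel calls", {
  panel <- tibble::tibble(
    gene = c("BEX1", "BICD1", "CHGB", "CPE", "GABRB3", "SCG2", "SCG3"),
    bv = c(5.0e-5, 1.3e-3, 7.5e-8, 1.1e-12, 1.2e-2, 1.7e-4, 2.5e-5),
    br = c(2.1, 1.7, 3.0, 7.4, 1.5, 1.9, 2.2))
  res <- cre_filter(panel$gene, panel)
  expect_setequal(res$gene, c("BEX1", "CHGB", "CPE", "SCG2", "SCG3"))
  expect_true("CPE" %in% res$gene)
  expect_false(any(c("BICD1", "GABRB3") %in% res$gene))
  # strict inequalities leave this panel unchanged (no passing gene
  # sits exactly on a threshold)
  strict <- cre_filter(panel$gene, panel, strict = TRUE)
  expect_setequal(strict$gene, res$gene)
  expect_equal(glance(res)$n_annotated, 7)

  empty <- cre_filter(character(), panel)
  expect_equal(nrow(empty), 0)
})

test_that("the CRE filter is monotone in both thresholds", {
  sim <- simulate_expression(sim_config(n_genes = 200,
                                        module_sizes = integer(0),
                                        background_genes = 200L,
                                        de_fraction = 0.5, seed = 17))
  up <- sim$truth$gene[sim$truth$direction %in% "up"]
  base <- cre_filter(up, sim$cre_table)$gene
  tighter_bv <- cre_filter(up, sim$cre_table, bv_max = 1e-5)$gene
  tighter_br <- cre_filter(up, sim$cre_table, br_min = 3)$gene
  expect_true(all(tighter_bv %in% base))
  expect_true(all(tighter_br %in% base))
})

test_that("type-I error is calibrated and planted shifts are detected", {
  # null: no planted DE, noise-only genes
  null_sim <- simulate_expression(sim_config(n_genes = 1000,
                                             module_sizes = integer(0),
                                             background_genes = 1000L,
                                             de_fraction = 0, seed = 23))
  de0 <- ttest_de(null_sim$expression)
  expect_lt(abs(mean(de0$significant) - 0.05),
            3 * sqrt(0.05 * 0.95 / 1000))
  # alternative: 3-sigma shifts on noise-scale genes are nearly always found
  alt_sim <- simulate_expression(sim_config(n_genes = 500,
                                            module_sizes = integer(0),
                                            background_genes = 500L,
                                            de_fraction = 0.3, de_effect = 3,
                                            seed = 29))
  de1 <- ttest_de(alt_sim$expression)
  power <- mean(de1$significant[alt_sim$truth$de])
  expect_gt(power, 0.9)
  hits <- de1$direction[alt_sim$truth$de]
  expect_true(mean(hits == alt_sim$truth$direction[alt_sim$truth$de],
                   na.rm = TRUE) > 0.95)
})
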