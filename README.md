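# coexnet

Gene co-expression network inference and graph-topology analysis for
small two-group transcriptome cohorts.

## The problem

Small-intestinal neuroendocrine tumors (SI NETs) are rare enough that
a typical expression study has a handful of arrays — the motivating
cohort is 9 primary tumors against 4 normal mucosa preparations. With
so few samples, single-gene statistics say little on their own; the
systems-level alternative is to ask how genes *co-vary*: build a
network whose edges connect gene pairs with strongly correlated
expression, and read biology off the graph — its modules, its hubs,
its stability. `coexnet` packages that workflow end to end for
anyone with a gene-by-sample intensity matrix and a tumor/normal
labelling:

1. **Inference** — all pairwise Pearson correlations; an edge where
   `|r| ≥ τ`. The cutoff is scanned over 0.5–1.0 and chosen as the
   most modular network that still retains a floor fraction of genes
   (`select_cutoff()`), formalising the usual qualitative rule.
2. **Topology** — degree distribution with a log–log power-law fit
   (the scale-free assessment), average-shortest-path "diameter",
   betweenness, clustering coefficients, components.
3. **Modules** — an in-package, seeded Louvain implementation
   maximising Newman modularity
   `Q = Σ_c [ l_c/m − (d_c/2m)² ]`, plus hypergeometric gene-set
   enrichment of each cluster against the network background with BH
   correction.
4. **Null models** — degree-preserving Maslov–Sneppen rewiring (4·m
   successful double-edge swaps) and edge-matched uniform G(n, m)
   graphs; 200 replicates each, overlap with the real network, and
   the non-randomness score `z = (m − mean_overlap)/sd_overlap`.
5. **Robustness** — diameter response to targeted hub removal
   (attack) versus random removal (error), the classic fragility
   signature of hub-dominated networks.
6. **DE overlay and CREB targets** — per-gene Student t (tumor −
   normal), up/down partition at p ≤ 0.05, overlay onto the network
   together with any user gene list (e.g. somatically mutated cancer
   genes), and the CREB-target filter: up-regulated genes with
   binding value BV ≤ 0.001 and binding ratio BR ≥ 1.5.

A seeded synthetic-data generator (`simulate_expression()`) plants
co-expression modules, hubs, group mean-shifts and CREB annotations
with known truth, so the whole pipeline is testable without any
download. Everything is tibble-in/tibble-out with `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(coexnet)

cfg <- run_config(simulation = default_paper_shape(),
                  null_replicates = 200, seed = 7)
run <- run_pipeline(cfg, "coexnet_out", quiet = TRUE)
print(run$report, n = 24)
```

```
   key                       value
 1 n_genes                500
 2 n_samples               13
 3 cutoff                   0.88
 4 n_nodes                249
 5 n_edges               1058
 6 average_degree           8.50
 7 density                  0.0343
 8 n_components            18
 9 diameter                 2.40
10 modularity_q             0.893
11 n_clusters              18
12 n_clusters_over_floor    1
13 power_law_slope         -0.269
14 power_law_r2             0.183
15 z_maslov_sneppen       109.
16 z_erdos_renyi          183.
17 min_z                  109.
18 de_up                   42
19 de_down                 34
20 de_total                76
21 de_percent              31
22 cre_pass                34
23 seed                     7
24 elapsed_s               13.8
```

Reading it: from a 500-gene, 13-sample simulated cohort the scan
picked `|r| ≥ 0.88` as the most modular admissible cutoff, giving a
249-node, 1058-edge network split into 18 components that Louvain
partitions at Q = 0.89 — strongly modular, as planted. Both null
models share so few edges with the network that the minimal z is
109: the network is decisively non-random. 76 of the 249 network
genes (31%) are differentially expressed, and 34 of the up-regulated
ones pass the CREB filter. Per-stage tables (`scan.tsv`,
`network.tsv`, `clusters.tsv`, `enrichment.tsv`, `null_summary.tsv`,
`robustness.tsv`, `de.tsv`, `cre_hits.tsv`, `report.tsv`) land in
the output directory; `autoplot()` works on the scan, the degree
histogram, the power-law fit, the null summaries and the robustness
curves.

A thin command-line wrapper with `simulate`, `infer` and `run`
subcommands is installed at `inst/cli/coexnet.R`.

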