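#' Pipeline run configuration
#'
#' Bundles every stage's inputs and thresholds into one list so a full
#' analysis is reproducible from a single object (or YAML file). Input
#' is either a [sim_config()] (synthetic cohort) or paths to an
#' expression matrix and metadata TSV; optional paths supply gene sets
#' (GMT), a flagged gene list and a CREB annotation table.
#'
#' @param simulation A [sim_config()], or `NULL` when reading from
#'   files.
#' @param expression,metadata Input TSV paths (ignored when
#'   `simulation` is given).
#' @param gmt,gene_list,cre Optional annotation file paths.
#' @param cutoff `"auto"` (constrained modularity selection over the
#'   scan) or a fixed numeric cutoff.
#' @param tau_min,tau_max,tau_step Cutoff scan grid.
#' @param min_node_fraction Node floor for [select_cutoff()].
#' @param alpha DE significance level.
#' @param bv_max,br_min CREB-filter thresholds.
#' @param min_cluster_size Enrichment cluster-size floor.
#' @param null_replicates Replicates per null model.
#' @param f_max,removal_step,error_trials Robustness settings.
#' @param seed Global seed; each stage derives its own seed from it by
#'   a fixed offset, so stages are independently reproducible.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL,
                       expression = NULL, metadata = NULL,
                       gmt = NULL, gene_list = NULL, cre = NULL,
                       cutoff = "auto",
                       tau_min = 0.5, tau_max = 1.0, tau_step = 0.02,
                       min_node_fraction = 0.1,
                       alpha = 0.05, bv_max = 0.001, br_min = 1.5,
                       min_cluster_size = 20,
                       null_replicates = 200,
                       f_max = 0.2, removal_step = 0.01, error_trials = 20,
                       seed = 1L) {
  if (is.null(simulation) && (is.null(expression) || is.null(metadata))) {
    abort("supply either `simulation` or `expression` + `metadata` paths")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    abort("`simulation` must be a sim_config")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns the config invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out <- out[!vapply(out, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(config)
}

stage_seeds <- function(seed) {
  list(simulate = derive_seed(seed, 11), scan = derive_seed(seed, 23),
       louvain = derive_seed(seed, 37), null = derive_seed(seed, 53),
       error = derive_seed(seed, 71))
}

#' Run the full co-expression analysis pipeline
#'
#' Executes, in dependency order: data acquisition (simulation or
#' loading), correlation and cutoff scan, network construction,
#' topology statistics, Louvain clustering (+ enrichment when gene
#' sets are available), both random-graph null models, attack/error
#' robustness, and differential expression with the CREB-target
#' filter. Stage outputs are written as TSVs under `out_dir` and a
#' key/value run report is written to `report.tsv`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages. Default `FALSE`.
#' @return Invisibly, a list of class `coexnet_run` holding every
#'   stage result plus the `report` tibble.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) inform(sprintf(...))

  # --- data ---------------------------------------------------------
  sim <- NULL
  gene_sets <- NULL
  cre_table <- NULL
  gene_list <- NULL
  if (!is.null(config$simulation)) {
    say("stage data: simulating cohort (seed %d)", config$simulation$seed)
    sim <- simulate_expression(config$simulation)
    write_simulation(sim, file.path(out_dir, "data"))
    em <- sim$expression
    gene_sets <- sim$gene_sets
    cre_table <- sim$cre_table
  } else {
    for (p in c(config$expression, config$metadata, config$gmt,
                config$gene_list, config$cre)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(paste0("input file not found: ", p))
      }
    }
    say("stage data: loading %s", config$expression)
    em <- load_expression(config$expression, config$metadata)
  }
  if (!is.null(config$gmt)) gene_sets <- read_gmt(config$gmt)
  if (!is.null(config$cre)) cre_table <- read_cre_table(config$cre)
  if (!is.null(config$gene_list)) gene_list <- readLines(config$gene_list)

  # --- network inference -------------------------------------------
  cmat <- pearson_matrix(em)
  scan <- NULL
  if (identical(config$cutoff, "auto")) {
    say("stage infer: scanning cutoffs %.2f..%.2f", config$tau_min, config$tau_max)
    scan <- threshold_scan(cmat, config$tau_min, config$tau_max,
                           config$tau_step, seed = seeds$scan)
    readr::write_tsv(as_tibble(scan), file.path(out_dir, "scan.tsv"),
                     progress = FALSE)
    cutoff <- select_cutoff(scan, config$min_node_fraction)
  } else {
    cutoff <- as.numeric(config$cutoff)
  }
  say("stage infer: building network at |PCC| >= %.2f", cutoff)
  net <- build_network(cmat, cutoff)
  if (n_edges(net) == 0) abort("network is empty at the chosen cutoff")
  write_edge_list(net, file.path(out_dir, "network.tsv"))

  # --- topology -----------------------------------------------------
  topo <- topology_summary(net)
  nodes_tab <- node_statistics(net)
  readr::write_tsv(nodes_tab, file.path(out_dir, "topology.tsv"),
                   progress = FALSE)
  dh <- degree_distribution(net)
  readr::write_tsv(as_tibble(dh), file.path(out_dir, "degree_hist.tsv"),
                   progress = FALSE)
  plf <- tryCatch(power_law_fit(dh), error = function(e) NULL)

  # --- communities --------------------------------------------------
  say("stage modules: Louvain clustering")
  part <- louvain_cluster(net, seed = seeds$louvain)
  readr::write_tsv(as_tibble(as.data.frame(part)),
                   file.path(out_dir, "clusters.tsv"), progress = FALSE)
  enrich <- NULL
  if (!is.null(gene_sets)) {
    enrich <- hypergeom_enrich(part, gene_sets,
                               min_cluster_size = config$min_cluster_size)
    readr::write_tsv(enrich, file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
  }

  # --- null models --------------------------------------------------
  say("stage null: %d replicates per model", config$null_replicates)
  null_ms <- null_model_summary(net, "maslov_sneppen",
                                config$null_replicates, seed = seeds$null)
  null_er <- null_model_summary(net, "erdos_renyi",
                                config$null_replicates,
                                seed = derive_seed(seeds$null, 1))
  nulls <- bind_rows(as_tibble(null_ms), as_tibble(null_er))
  readr::write_tsv(nulls, file.path(out_dir, "null_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble(model = rep(nulls$model, each = config$null_replicates),
                          overlap = c(attr(null_ms, "overlaps"),
                                      attr(null_er, "overlaps"))),
                   file.path(out_dir, "null_overlaps.tsv"), progress = FALSE)

  # --- robustness ---------------------------------------------------
  say("stage robustness: attack and error curves")
  atk <- attack_curve(net, config$f_max, config$removal_step)
  err <- error_curve(net, config$f_max, config$removal_step,
                     seed = seeds$error, n_trials = config$error_trials)
  readr::write_tsv(bind_rows(as_tibble(atk), as_tibble(err)),
                   file.path(out_dir, "robustness.tsv"), progress = FALSE)

  # --- differential expression + CRE filter ------------------------
  say("stage DE: t-tests at alpha = %g", config$alpha)
  de <- suppressWarnings(ttest_de(em, alpha = config$alpha))
  readr::write_tsv(as_tibble(as.data.frame(de)), file.path(out_dir, "de.tsv"),
                   progress = FALSE)
  net_de <- de[de$gene %in% network_nodes(net), ]
  counts <- de_counts(net_de, background_size = n_nodes(net))
  overlay <- overlay_network(net, de = de, gene_list = gene_list,
                             partition = part)
  readr::write_tsv(overlay, file.path(out_dir, "overlay.tsv"), progress = FALSE)
  cre_hits <- NULL
  if (!is.null(cre_table)) {
    up <- de$gene[de$significant & de$direction %in% "up"]
    cre_hits <- cre_filter(up, cre_table, config$bv_max, config$br_min)
    readr::write_tsv(as_tibble(as.data.frame(cre_hits)),
                     file.path(out_dir, "cre_hits.tsv"), progress = FALSE)
  }

  # --- report -------------------------------------------------------
  cl_sizes <- table(part$community)
  report <- tibble(
    key = c("n_genes", "n_samples", "cutoff", "n_nodes", "n_edges",
            "average_degree", "density", "n_components", "diameter",
            "modularity_q", "n_clusters", "n_clusters_over_floor",
            "power_law_slope", "power_law_r2",
            "z_maslov_sneppen", "z_erdos_renyi", "min_z",
            "de_up", "de_down", "de_total", "de_percent",
            "cre_pass", "seed", "elapsed_s"),
    value = c(n_genes(em), n_samples(em), cutoff, topo$n_nodes, topo$n_edges,
              topo$average_degree, topo$density, topo$n_components,
              topo$diameter, attr(part, "Q"), length(cl_sizes),
              sum(cl_sizes > config$min_cluster_size),
              if (is.null(plf)) NA_real_ else plf$slope,
              if (is.null(plf)) NA_real_ else plf$r_squared,
              null_ms$z, null_er$z, min_z(null_ms, null_er),
              counts$n_up, counts$n_down, counts$n_total, counts$percent,
              if (is.null(cre_hits)) NA_real_ else nrow(cre_hits),
              config$seed,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  readr::write_tsv(report, file.path(out_dir, "report.tsv"), progress = FALSE)

  invisible(structure(
    list(config = config, expression = em, sim = sim, scan = scan,
         cutoff = cutoff, network = net, topology = topo,
         node_statistics = nodes_tab, degree_hist = dh, power_law = plf,
         partition = part, enrichment = enrich, null_ms = null_ms,
         null_er = null_er, attack = atk, error = err, de = de,
         de_counts = counts, overlay = overlay, cre_hits = cre_hits,
         report = report),
    class = "coexnet_run"))
}

#' @export
print.coexnet_run <- function(x, ...) {
  cat("<coexnet_run>\n")
  print(x$report, n = nrow(x$report))
  invisible(x)
}
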