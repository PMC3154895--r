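#' Gene-gene Pearson correlation matrix
#'
#' Standard sample Pearson correlation between every pair of gene
#' expression vectors. Genes with zero variance across samples are
#' dropped with a warning (their correlation is undefined); fewer than
#' three samples is an error.
#'
#' @param em An [expr_matrix()].
#' @return A symmetric numeric matrix with unit diagonal and gene ids
#'   as dimnames.
#' @export
pearson_matrix <- function(em) {
  if (n_samples(em) < 3) abort("need at least 3 samples for correlations")
  v <- apply(em$values, 1, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warn(paste0("dropping zero-variance gene(s): ",
                paste(rownames(em$values)[!keep], collapse = ", ")))
  }
  cor(t(em$values[keep, , drop = FALSE]))
}

#' Build a co-expression network at an absolute-correlation cutoff
#'
#' An edge joins genes `i` and `j` iff `|r_ij| >= cutoff`; the signed
#' correlation is kept as the edge weight. Genes without any passing
#' edge do not appear in the network.
#'
#' @param cmat Correlation matrix from [pearson_matrix()].
#' @param cutoff Absolute-correlation threshold in `(0, 1]`.
#' @return A [gene_network()].
#' @export
build_network <- function(cmat, cutoff) {
  if (cutoff <= 0 || cutoff > 1) abort("`cutoff` must be in (0, 1]")
  idx <- which(upper.tri(cmat) & abs(cmat) >= cutoff, arr.ind = TRUE)
  genes <- rownames(cmat)
  gene_network(tibble(gene_a = genes[idx[, 1]],
                      gene_b = genes[idx[, 2]],
                      pcc = cmat[idx]),
               cutoff = cutoff)
}

#' Scan co-expression cutoffs and summarise the resulting networks
#'
#' For each cutoff on a grid (default 0.5 to 1.0 in steps of 0.02) the
#' network is built and its node count, edge count, number of connected
#' components, density and Louvain modularity are recorded. Edge counts
#' are non-increasing in the cutoff by construction.
#'
#' @param cmat Correlation matrix from [pearson_matrix()].
#' @param tau_min,tau_max,step Cutoff grid.
#' @param with_modularity Compute the Louvain modularity column
#'   (required by [select_cutoff()]). Default `TRUE`.
#' @param seed Seed for the Louvain node ordering.
#' @return A tibble of class `threshold_scan` with columns `cutoff`,
#'   `n_nodes`, `n_edges`, `n_components`, `density`, `modularity`.
#' @export
threshold_scan <- function(cmat, tau_min = 0.5, tau_max = 1.0, step = 0.02,
                           with_modularity = TRUE, seed = 1L) {
  if (!(tau_min > 0 && tau_max <= 1 && tau_min <= tau_max && step > 0)) {
    abort("invalid cutoff grid")
  }
  taus <- seq(tau_min, tau_max, by = step)
  rows <- purrr::imap(taus, function(tau, i) {
    g <- build_network(cmat, tau)
    q <- NA_real_
    n_comp <- 0L
    if (n_edges(g) > 0) {
      n_comp <- igraph::count_components(as_igraph(g))
      if (with_modularity) {
        q <- attr(louvain_cluster(g, seed = derive_seed(seed, i)), "Q")
      }
    }
    tibble(cutoff = tau, n_nodes = n_nodes(g), n_edges = n_edges(g),
           n_components = n_comp,
           density = graph_density(n_nodes(g), n_edges(g)),
           modularity = q)
  })
  out <- bind_rows(rows)
  attr(out, "n_genes") <- nrow(cmat)
  class(out) <- c("threshold_scan", class(out))
  out
}

#' Select the co-expression cutoff by constrained modularity
#'
#' Returns the cutoff maximising Louvain modularity among scan rows
#' that retain at least `min_node_fraction` of the genes, formalising
#' the "most modular while retaining a reasonable number of genes"
#' selection rule; ties are broken toward the larger (more stringent)
#' cutoff.
#'
#' @param scan A `threshold_scan` tibble.
#' @param min_node_fraction Minimum fraction of all genes that must
#'   remain in the network. Default 0.1.
#' @param n_genes Total gene count the fraction refers to; taken from
#'   the scan attribute when available.
#' @return The selected cutoff (scalar).
#' @export
select_cutoff <- function(scan, min_node_fraction = 0.1, n_genes = NULL) {
  if (nrow(scan) == 0) abort("empty scan")
  n_genes <- n_genes %||% attr(scan, "n_genes")
  if (is.null(n_genes)) abort("supply `n_genes` (scan carries no gene count)")
  if (all(is.na(scan$modularity))) abort("scan has no modularity column values")
  ok <- !is.na(scan$modularity) & scan$n_nodes >= min_node_fraction * n_genes
  if (!any(ok)) {
    abort(sprintf(paste0("no cutoff keeps >= %.0f%% of genes in the network; ",
                         "lower `min_node_fraction`"), 100 * min_node_fraction))
  }
  cand <- scan[ok, ]
  best <- cand[cand$modularity >= max(cand$modularity) - 1e-12, ]
  max(best$cutoff)
}

#' @export
autoplot.threshold_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("n_nodes", "n_edges", "n_components",
                                "density", "modularity"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "absolute PCC cutoff", y = NULL,
                  title = "Network properties across correlation cutoffs")
}
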