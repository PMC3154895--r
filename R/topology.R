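#' Average node degree
#'
#' `2 * n_edges / n_nodes`.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return Average degree (scalar).
#' @export
average_degree <- function(n_nodes, n_edges) {
  if (n_nodes <= 0) abort("average degree undefined for an empty graph")
  2 * n_edges / n_nodes
}

#' Average shortest-path "diameter"
#'
#' The mean unweighted shortest-path length over all unordered pairs of
#' distinct nodes lying in the same connected component. This is the
#' diameter definition used throughout the pipeline (the convention of
#' the original network study); the classical maximum-eccentricity
#' diameter is available as [max_eccentricity()].
#'
#' @param g A [gene_network()].
#' @return Mean intra-component shortest-path length.
#' @export
network_diameter <- function(g) {
  if (n_edges(g) == 0) abort("diameter undefined for a graph with no edges")
  d <- igraph::distances(as_igraph(g))
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

#' Classical diameter (maximum eccentricity)
#'
#' Longest shortest path within any connected component.
#'
#' @param g A [gene_network()].
#' @return Integer-valued path length.
#' @export
max_eccentricity <- function(g) {
  if (n_edges(g) == 0) abort("diameter undefined for a graph with no edges")
  d <- igraph::distances(as_igraph(g))
  max(d[is.finite(d)])
}

#' Betweenness centrality per gene
#'
#' Unnormalised shortest-path betweenness: for each node, the number of
#' shortest paths between other node pairs passing through it, with
#' equal-length paths splitting the count.
#'
#' @param g A [gene_network()].
#' @param normalized Divide by the number of other node pairs
#'   (`(n-1)(n-2)/2`). Default `FALSE`.
#' @return Tibble with columns `gene`, `betweenness`.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  ig <- as_igraph(g)
  b <- igraph::betweenness(ig, directed = FALSE, normalized = normalized)
  tibble(gene = names(b), betweenness = unname(b))
}

#' Local clustering coefficient per gene
#'
#' `2 * (edges among neighbours) / (k (k - 1))` for nodes of degree
#' `k >= 2`, and 0 for degree below 2.
#'
#' @param g A [gene_network()].
#' @return Tibble with columns `gene`, `clustering`; the mean is
#'   attached as attribute `mean_clustering`.
#' @export
clustering_coefficients <- function(g) {
  ig <- as_igraph(g)
  cc <- unname(igraph::transitivity(ig, type = "local", isolates = "zero"))
  cc[is.nan(cc)] <- 0
  out <- tibble(gene = igraph::V(ig)$name, clustering = cc)
  attr(out, "mean_clustering") <- mean(cc)
  out
}

#' Degree histogram
#'
#' Exact node counts per degree value. The network contains no
#' isolated genes, so there is never a degree-0 bin.
#'
#' @param g A [gene_network()].
#' @return Tibble with columns `degree`, `count`, sorted by degree.
#' @export
degree_distribution <- function(g) {
  deg <- igraph::degree(as_igraph(g))
  tab <- table(deg)
  out <- tibble(degree = as.integer(names(tab)), count = as.integer(tab))
  class(out) <- c("degree_histogram", class(out))
  out
}

#' Log-log power-law fit of a degree histogram
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)` over the
#' non-empty bins — the classical straight-line assessment of a
#' scale-free degree distribution. At least three distinct degrees are
#' required.
#'
#' @param hist Tibble with columns `degree`, `count` (from
#'   [degree_distribution()]).
#' @return A `power_law_fit` list with `slope`, `intercept`,
#'   `r_squared` and the fitted points.
#' @export
power_law_fit <- function(hist) {
  hist <- hist[hist$count > 0, ]
  if (nrow(hist) < 3) abort("power-law fit needs >= 3 distinct degrees")
  x <- log10(hist$degree)
  y <- log10(hist$count)
  fit <- lm(y ~ x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (tss < 1e-15) 1 else 1 - rss / tss,
                 points = tibble(log10_degree = x, log10_count = y)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> slope %.3f, intercept %.3f, R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared)
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$log10_degree, y = .data$log10_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "log10 degree", y = "log10 count",
                  title = sprintf("Degree distribution (slope %.2f, R² %.2f)",
                                  object$slope, object$r_squared))
}

#' @export
autoplot.degree_histogram <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "degree", y = "number of genes",
                  title = "Node degree frequency distribution")
}

#' One-row topology summary of a network
#'
#' @param g A [gene_network()].
#' @return Tibble with `n_nodes`, `n_edges`, `average_degree`,
#'   `density`, `n_components`, `diameter` (average shortest path),
#'   `max_eccentricity`, `mean_clustering`.
#' @export
topology_summary <- function(g) {
  ig <- as_igraph(g)
  cc <- clustering_coefficients(g)
  tibble(n_nodes = n_nodes(g),
         n_edges = n_edges(g),
         average_degree = average_degree(n_nodes(g), n_edges(g)),
         density = graph_density(n_nodes(g), n_edges(g)),
         n_components = igraph::count_components(ig),
         diameter = network_diameter(g),
         max_eccentricity = max_eccentricity(g),
         mean_clustering = attr(cc, "mean_clustering"))
}

#' Per-gene topology table
#'
#' Degree, betweenness and local clustering coefficient for every
#' network gene.
#'
#' @param g A [gene_network()].
#' @param normalized_betweenness Normalise betweenness by the number of
#'   other node pairs. Default `FALSE`.
#' @return Tibble with columns `gene`, `degree`, `betweenness`,
#'   `clustering`.
#' @export
node_statistics <- function(g, normalized_betweenness = FALSE) {
  deg <- igraph::degree(as_igraph(g))
  tibble(gene = names(deg), degree = unname(deg)) |>
    left_join(betweenness_centrality(g, normalized = normalized_betweenness),
              by = "gene") |>
    left_join(clustering_coefficients(g), by = "gene")
}
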