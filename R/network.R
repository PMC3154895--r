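#' Gene co-expression network
#'
#' An undirected graph over gene symbols stored as a canonical edge
#' tibble (`gene_a < gene_b`, one row per unordered pair) with the
#' signed Pearson correlation as edge weight. Only genes with at least
#' one edge are nodes; isolated genes are excluded by construction.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `pcc`.
#' @param cutoff The absolute-correlation cutoff the network was built
#'   at (in `(0, 1]`), or `NA` when unknown.
#' @return A `gene_network`: a tibble of edges with attributes
#'   `cutoff` and `nodes`.
#' @export
gene_network <- function(edges, cutoff = NA_real_) {
  edges <- as_tibble(edges)[, c("gene_a", "gene_b", "pcc")]
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$pcc <- as.numeric(edges$pcc)
  if (any(edges$gene_a == edges$gene_b)) abort("self-loop edge not allowed")
  edges <- canonical_edges(edges)
  if (anyDuplicated(edge_keys(edges)) > 0) abort("parallel edge not allowed")
  if (!is.na(cutoff) && nrow(edges) > 0 && any(abs(edges$pcc) < cutoff - 1e-12)) {
    abort("edge weight below the stated cutoff")
  }
  structure(edges,
            cutoff = cutoff,
            nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
            class = c("gene_network", class(tibble())))
}

#' @rdname gene_network
#' @param g A `gene_network`.
#' @export
network_nodes <- function(g) attr(g, "nodes")

#' @rdname gene_network
#' @export
n_nodes <- function(g) length(attr(g, "nodes"))

#' @rdname gene_network
#' @export
n_edges <- function(g) nrow(g)

# igraph view of the network; edge correlation kept as attribute "pcc"
# (deliberately not "weight": all topology is computed on the unweighted
# skeleton).
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$gene_a, to = g$gene_b),
    directed = FALSE,
    vertices = data.frame(name = network_nodes(g))
  )
  igraph::E(ig)$pcc <- g$pcc
  ig
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges (cutoff %s)\n",
              n_nodes(x), n_edges(x),
              ifelse(is.na(attr(x, "cutoff")), "unknown",
                     format(attr(x, "cutoff")))))
  NextMethod()
}

#' @export
tidy.gene_network <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @export
glance.gene_network <- function(x, ...) {
  tibble(n_nodes = n_nodes(x), n_edges = n_edges(x),
         cutoff = attr(x, "cutoff"),
         average_degree = if (n_nodes(x) > 0) 2 * n_edges(x) / n_nodes(x) else 0,
         density = graph_density(n_nodes(x), n_edges(x)))
}

graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Write / read a network edge list
#'
#' Tab-separated columns `gene_a`, `gene_b`, `pcc`; correlations are
#' written with 6 decimals and the round trip reproduces the graph
#' exactly at that precision (signed weights preserved).
#'
#' @param g A `gene_network`.
#' @param path File path.
#' @return `write_edge_list()` returns `g` invisibly; `read_edge_list()`
#'   returns a `gene_network`.
#' @export
write_edge_list <- function(g, path) {
  out <- data.frame(gene_a = g$gene_a, gene_b = g$gene_b,
                    pcc = sprintf("%.6f", g$pcc))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(g)
}

#' @rdname write_edge_list
#' @param cutoff Optional cutoff to record on the re-read network.
#' @export
read_edge_list <- function(path, cutoff = NA_real_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) abort("edge-list file is empty (no header)")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(gene_network(tibble(gene_a = character(), gene_b = character(),
                               pcc = numeric()), cutoff))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed edge-list line %d", bad[1] + 1L))
  }
  m <- do.call(rbind, parts)
  pcc <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(pcc)) {
    abort(sprintf("malformed edge-list line %d (non-numeric pcc)",
                  which(is.na(pcc))[1] + 1L))
  }
  gene_network(tibble(gene_a = m[, 1], gene_b = m[, 2], pcc = pcc), cutoff)
}
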