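#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomises the network by repeated double-edge swaps — pick edges
#' `(a,b)` and `(c,d)` and rewire them to `(a,d)` and `(c,b)` —
#' rejecting any swap that would create a self-loop or a parallel
#' edge, so every node keeps its exact degree. The target is
#' `4 * n_edges` successful swaps (rejected attempts do not count); if
#' the attempt budget runs out before the target (possible only for
#' very constrained graphs such as a triangle, where no legal swap
#' exists) the current graph is returned with a warning.
#'
#' @param g A [gene_network()] with at least 2 edges.
#' @param seed Integer seed.
#' @param swaps_per_edge Successful swaps per edge (default 4).
#' @param max_tries_factor Attempt budget, as a multiple of the swap
#'   target (default 100).
#' @return A rewired `gene_network` (edge weights carried along with
#'   the rewired endpoints; the cutoff attribute is dropped).
#' @export
rewire_maslov_sneppen <- function(g, seed = 1L, swaps_per_edge = 4,
                                  max_tries_factor = 100) {
  m <- n_edges(g)
  if (m < 2) abort("rewiring needs at least 2 edges")
  nodes <- network_nodes(g)
  nn <- length(nodes)
  a <- match(g$gene_a, nodes)
  b <- match(g$gene_b, nodes)
  # unordered pair -> flat index into a presence vector
  present <- logical(nn * nn)
  present[(pmin(a, b) - 1) * nn + pmax(a, b)] <- TRUE
  target <- ceiling(swaps_per_edge * m)
  budget <- max_tries_factor * target
  done <- 0L
  with_seed(seed, {
    tries <- 0L
    chunk <- 8192L
    pos <- chunk + 1L
    buf <- integer(0)
    while (done < target && tries < budget) {
      if (pos >= chunk) {
        buf <- sample.int(m, 2L * chunk, replace = TRUE)
        pos <- 1L
      }
      i <- buf[pos]; j <- buf[pos + 1L]; pos <- pos + 2L
      tries <- tries + 1L
      if (i == j) next
      # swap (a_i, b_i), (a_j, b_j) -> (a_i, b_j), (a_j, b_i)
      na1 <- a[i]; nb1 <- b[j]; na2 <- a[j]; nb2 <- b[i]
      if (na1 == nb1 || na2 == nb2) next
      k1 <- if (na1 < nb1) (na1 - 1L) * nn + nb1 else (nb1 - 1L) * nn + na1
      k2 <- if (na2 < nb2) (na2 - 1L) * nn + nb2 else (nb2 - 1L) * nn + na2
      if (k1 == k2 || present[k1] || present[k2]) next
      oa <- a[i]; ob <- b[i]
      present[if (oa < ob) (oa - 1L) * nn + ob else (ob - 1L) * nn + oa] <- FALSE
      oa <- a[j]; ob <- b[j]
      present[if (oa < ob) (oa - 1L) * nn + ob else (ob - 1L) * nn + oa] <- FALSE
      present[k1] <- TRUE
      present[k2] <- TRUE
      b[i] <- nb1
      b[j] <- nb2
      done <- done + 1L
    }
  })
  if (done < target) {
    warn(sprintf("rewiring stopped after %d/%d successful swaps (budget exhausted)",
                 done, target))
  }
  gene_network(tibble(gene_a = nodes[a], gene_b = nodes[b], pcc = g$pcc))
}

#' Edge-matched uniform random graph, G(n, m)
#'
#' Keeps the node set of the input network and draws exactly the same
#' number of edges uniformly at random, without replacement, from all
#' node pairs.
#'
#' @param g A [gene_network()].
#' @param seed Integer seed.
#' @return A `gene_network` on the same node set with `n_edges(g)`
#'   uniformly random edges (edge weights set to `NA`).
#' @note Nodes that end up with no incident edge in a draw are absent
#'   from the returned network's node list (networks never carry
#'   isolated nodes); overlap counting is unaffected.
#' @export
random_gnm <- function(g, seed = 1L) {
  nodes <- network_nodes(g)
  n <- length(nodes)
  m <- n_edges(g)
  n_pairs <- n * (n - 1) / 2
  if (m > n_pairs) abort("more edges requested than node pairs available")
  pick <- with_seed(seed, sample(n_pairs, m))
  # map linear pair index (column-major upper triangle) to (i, j), i < j
  j <- ceiling((1 + sqrt(1 + 8 * pick)) / 2)
  i <- pick - (j - 1) * (j - 2) / 2
  gene_network(tibble(gene_a = nodes[i], gene_b = nodes[j],
                      pcc = NA_real_))
}

#' Number of edges shared by two networks
#'
#' Counts unordered node pairs that are edges in both graphs.
#'
#' @param g1,g2 [gene_network()] objects.
#' @return Integer overlap count.
#' @export
edge_overlap <- function(g1, g2) {
  length(intersect(edge_keys(g1), edge_keys(g2)))
}

#' Null-model overlap summary and non-randomness z-score
#'
#' Generates `n_replicates` random networks under the chosen model,
#' intersects each with the original network, and summarises the
#' shared-edge counts. The non-randomness z-score compares the
#' observed edge count (a graph trivially shares all `m` edges with
#' itself) with the null overlap distribution:
#' `z = (m_observed - mean_overlap) / sd_overlap` (sample SD).
#'
#' @param g A [gene_network()].
#' @param model `"maslov_sneppen"` or `"erdos_renyi"` (the G(n,m)
#'   edge-matched model).
#' @param n_replicates Number of random networks (default 200).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return A `null_model_summary`: one-row tibble `model`,
#'   `n_replicates`, `m_observed`, `mean_overlap`, `sd_overlap`, `z`,
#'   with the per-replicate overlaps as attribute `overlaps`. `z` is
#'   `NA` (with a warning) when the overlap SD is zero.
#' @export
null_model_summary <- function(g, model = c("maslov_sneppen", "erdos_renyi"),
                               n_replicates = 200, seed = 1L) {
  model <- match.arg(model)
  if (n_replicates < 2) abort("need at least 2 replicates")
  gen <- switch(model,
                maslov_sneppen = function(s) suppressWarnings(
                  rewire_maslov_sneppen(g, seed = s)),
                erdos_renyi = function(s) random_gnm(g, seed = s))
  overlaps <- vapply(seq_len(n_replicates), function(r) {
    edge_overlap(g, gen(derive_seed(seed, r)))
  }, 1L)
  mo <- mean(overlaps)
  so <- sd(overlaps)
  m_obs <- n_edges(g)
  z <- if (so > 0) overlap_z(m_obs, mo, so) else NA_real_
  if (is.na(z)) warn("overlap SD is zero; z-score undefined")
  out <- tibble(model = model, n_replicates = as.integer(n_replicates),
                m_observed = m_obs, mean_overlap = mo, sd_overlap = so, z = z)
  attr(out, "overlaps") <- overlaps
  class(out) <- c("null_model_summary", class(out))
  out
}

#' Non-randomness z-score from an overlap summary
#'
#' `z = (m_observed - mean_overlap) / sd_overlap`: how many standard
#' deviations the network's own edge count lies above the mean number
#' of edges the null model shares with it.
#'
#' @param m_observed Edge count of the original network.
#' @param mean_overlap,sd_overlap Null overlap mean and (sample) SD.
#' @return The z-score.
#' @export
overlap_z <- function(m_observed, mean_overlap, sd_overlap) {
  if (sd_overlap <= 0) abort("sd_overlap must be positive")
  (m_observed - mean_overlap) / sd_overlap
}

#' Minimal z-score across null models
#'
#' The conservative non-randomness statistic: the smallest z across
#' the supplied null-model summaries.
#'
#' @param ... `null_model_summary` objects (or data frames with a `z`
#'   column), or a single list of them.
#' @return Minimum defined z.
#' @export
min_z <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]])) {
    args <- args[[1]]
  }
  zs <- unlist(purrr::map(args, ~.x$z))
  zs <- zs[!is.na(zs)]
  if (length(zs) == 0) abort("no summary with a defined z-score")
  min(zs)
}

#' @export
autoplot.null_model_summary <- function(object, ...) {
  df <- tibble(overlap = attr(object, "overlaps"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "edges shared with the original network",
                  y = "replicates",
                  title = sprintf("%s null (%d replicates), z = %.1f",
                                  object$model, object$n_replicates, object$z))
}
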