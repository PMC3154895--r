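#' Newman modularity of a partition
#'
#' `Q = sum_c [ l_c / m - (d_c / 2m)^2 ]` over communities `c`, where
#' `l_c` is the number of intra-community edges, `d_c` the summed
#' degree of the community and `m` the total edge count. Computed on
#' the unweighted edge skeleton.
#'
#' @param g A [gene_network()].
#' @param partition Data frame with columns `gene`, `community`, or a
#'   named vector mapping gene to community label. Must cover every
#'   network node.
#' @return Modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(g, partition) {
  lab <- partition_labels(partition)
  missing <- setdiff(network_nodes(g), names(lab))
  if (length(missing) > 0) {
    abort(paste0("partition does not cover node(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- n_edges(g)
  if (m == 0) abort("modularity undefined for a graph with no edges")
  ca <- lab[g$gene_a]
  cb <- lab[g$gene_b]
  intra <- sum(ca == cb)
  deg <- table(factor(c(g$gene_a, g$gene_b), levels = network_nodes(g)))
  d_c <- tapply(as.numeric(deg), lab[names(deg)], sum)
  intra / m - sum((d_c / (2 * m))^2)
}

partition_labels <- function(partition) {
  if (is.data.frame(partition)) {
    setNames(as.character(partition$community), partition$gene)
  } else {
    setNames(as.character(partition), names(partition))
  }
}

#' Louvain community detection
#'
#' Greedy two-phase modularity optimisation: (1) local moving — nodes
#' are visited in a seeded random order and each is moved to the
#' neighbouring community with the largest positive modularity gain,
#' repeating until a full pass makes no move; (2) aggregation —
#' communities collapse to super-nodes (intra-community edges become
#' self-loops) and phase 1 repeats on the smaller graph. Iteration
#' stops when the modularity gain of a level falls below `1e-7`. Ties
#' in gain keep the current community, otherwise the lowest community
#' label wins, so results are deterministic given the seed.
#'
#' @param g A non-empty [gene_network()].
#' @param seed Integer seed for the node visiting order.
#' @return A `module_partition`: tibble `gene`, `community` (integer
#'   labels, numbered by decreasing community size) with attribute `Q`.
#' @export
louvain_cluster <- function(g, seed = 1L) {
  if (n_edges(g) == 0) abort("cannot cluster a graph with no edges")
  nodes <- network_nodes(g)
  n <- length(nodes)
  ea <- match(g$gene_a, nodes)
  eb <- match(g$gene_b, nodes)
  membership <- with_seed(seed, louvain_run(ea, eb, rep(1, length(ea)), n))
  # relabel communities by decreasing size (ties: smallest member index)
  sizes <- table(membership)
  first <- tapply(seq_len(n), membership, min)
  ord <- order(-as.numeric(sizes), as.numeric(first))
  relab <- integer(length(sizes))
  relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
  part <- tibble(gene = nodes, community = relab[membership])
  q <- modularity_q(g, part)
  structure(part, Q = q, class = c("module_partition", class(tibble())))
}

# One full Louvain run on an integer edge list; returns a membership
# vector for the original n nodes. Assumes RNG state is set by caller.
louvain_run <- function(ea, eb, w, n) {
  membership <- seq_len(n)
  q_prev <- -Inf
  repeat {
    res <- louvain_local_move(ea, eb, w, n)
    labels <- res$labels
    membership <- labels[membership]
    if (res$q - q_prev < 1e-7) break
    q_prev <- res$q
    # aggregate: communities become nodes, intra edges become self-loops
    comm <- sort(unique(labels))
    relab <- match(labels, comm)
    membership <- relab[membership]
    na <- relab[ea]
    nb <- relab[eb]
    lo <- pmin(na, nb)
    hi <- pmax(na, nb)
    key <- paste(lo, hi)
    agg <- tapply(w, key, sum)
    pair <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    ea <- as.integer(pair[, 1])
    eb <- as.integer(pair[, 2])
    w <- as.numeric(agg)
    n <- length(comm)
    if (n == 1) break
  }
  membership
}

# Phase 1: local moving on a weighted graph with self-loops
# (ea == eb rows). Returns final labels and the achieved modularity.
louvain_local_move <- function(ea, eb, w, n) {
  self <- ea == eb
  # node strengths; a self-loop contributes twice to its node
  k <- numeric(n)
  for (e in seq_along(ea)) {
    if (self[e]) k[ea[e]] <- k[ea[e]] + 2 * w[e]
    else {
      k[ea[e]] <- k[ea[e]] + w[e]
      k[eb[e]] <- k[eb[e]] + w[e]
    }
  }
  m2 <- sum(k)               # = 2m
  # incidence lists over non-self edges
  ns <- which(!self)
  src <- c(ea[ns], eb[ns])
  dst <- c(eb[ns], ea[ns])
  ww <- c(w[ns], w[ns])
  f <- factor(src, levels = seq_len(n))
  nbr <- split(dst, f)
  nbw <- split(ww, f)
  labels <- seq_len(n)
  tot <- k                   # per-community summed strength
  order_nodes <- sample.int(n)
  repeat {
    moved <- FALSE
    for (i in order_nodes) {
      ci <- labels[i]
      neigh <- nbr[[i]]
      if (length(neigh) == 0) next
      wts <- nbw[[i]]
      cn <- labels[neigh]
      w_to <- tapply(wts, cn, sum)
      tot[ci] <- tot[ci] - k[i]
      cand <- as.integer(names(w_to))
      gain <- as.numeric(w_to) - tot[cand] * k[i] / m2
      stay <- if (ci %in% cand) gain[cand == ci] else 0 - tot[ci] * k[i] / m2
      best_gain <- max(gain)
      if (best_gain > stay + 1e-12) {
        winners <- cand[gain >= best_gain - 1e-12]
        target <- min(winners)
        if (target != ci) {
          labels[i] <- target
          tot[target] <- tot[target] + k[i]
          moved <- TRUE
        } else {
          tot[ci] <- tot[ci] + k[i]
        }
      } else {
        tot[ci] <- tot[ci] + k[i]
      }
    }
    if (!moved) break
  }
  # modularity of the current labelling on this (weighted) graph
  same <- labels[ea] == labels[eb]
  l_c <- tapply(w[same], labels[ea][same], sum)
  d_c <- tapply(k, labels, sum)
  q <- (if (length(l_c) > 0) sum(l_c) else 0) / (m2 / 2) - sum((d_c / m2)^2)
  list(labels = labels, q = q)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d genes in %d communities, Q = %.4f\n",
              nrow(x), length(unique(x$community)), attr(x, "Q")))
  NextMethod()
}

#' @export
glance.module_partition <- function(x, ...) {
  sizes <- table(x$community)
  tibble(Q = attr(x, "Q"), n_communities = length(sizes),
         largest = max(sizes), n_genes = nrow(x))
}

#' Hypergeometric gene-set enrichment of network clusters
#'
#' For every cluster of at least `min_cluster_size` genes and every
#' gene set, tests whether the overlap `k` between the cluster (size
#' `n`) and the set (size `K` within the background) is larger than
#' expected under sampling without replacement from the background
#' (all `N` network genes): the upper-tail hypergeometric probability
#' `P(X >= k)`. Benjamini-Hochberg adjustment is applied across all
#' (cluster, term) tests.
#'
#' @param partition A `module_partition` (or tibble `gene`,
#'   `community`).
#' @param sets Gene-set tibble as returned by [read_gmt()].
#' @param background Character vector of background genes; defaults to
#'   all genes in the partition. Set genes are intersected with the
#'   background before counting.
#' @param min_cluster_size Smallest cluster tested (default 20).
#' @return Tibble `cluster`, `term_id`, `N`, `K`, `n`, `k`, `p`,
#'   `p_adj`, sorted by `p`.
#' @export
hypergeom_enrich <- function(partition, sets, background = NULL,
                             min_cluster_size = 20) {
  part <- as_tibble(as.data.frame(partition))
  background <- unique(background %||% part$gene)
  if (length(background) == 0) abort("empty background")
  outside <- setdiff(part$gene, background)
  if (length(outside) > 0) {
    abort("background must contain every clustered gene")
  }
  N <- length(background)
  clusters <- split(part$gene, part$community)
  clusters <- clusters[lengths(clusters) >= min_cluster_size]
  if (length(clusters) == 0 || nrow(sets) == 0) {
    return(tibble(cluster = character(), term_id = character(),
                  N = integer(), K = integer(), n = integer(), k = integer(),
                  p = numeric(), p_adj = numeric()))
  }
  set_genes <- purrr::map(sets$genes, ~intersect(.x, background))
  rows <- purrr::imap(clusters, function(cl_genes, cl_name) {
    n_cl <- length(cl_genes)
    k <- vapply(set_genes, function(sg) length(intersect(sg, cl_genes)), 1L)
    K <- lengths(set_genes)
    tibble(cluster = cl_name, term_id = sets$term_id,
           N = N, K = as.integer(K), n = n_cl, k = as.integer(k),
           p = phyper(k - 1, K, N - K, n_cl, lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}
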