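# Small graph builders and brute-force oracles used across the suite.
# Oracles are deliberately naive (enumeration / BFS) and independent of
# the package's implementation paths.

net_from_pairs <- function(a, b, pcc = NULL, cutoff = NA_real_) {
  gene_network(tibble::tibble(gene_a = a, gene_b = b,
                              pcc = pcc %||% rep(1, length(a))),
               cutoff = cutoff)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

triangle_net <- function(labels = c("a", "b", "c")) {
  net_from_pairs(labels[c(1, 2, 3)], labels[c(2, 3, 1)])
}

path_net <- function(labels = c("a", "b", "c")) {
  net_from_pairs(labels[-length(labels)], labels[-1])
}

star_net <- function(n_leaves = 5) {
  net_from_pairs(rep("hub", n_leaves), sprintf("leaf%02d", seq_len(n_leaves)))
}

complete_net <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  net_from_pairs(v[idx[1, ]], v[idx[2, ]])
}

cycle_net <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  net_from_pairs(v, v[c(2:n, 1)])
}

# two triangles a-b-c and d-e-f joined by bridge c-d
bridged_triangles_net <- function() {
  net_from_pairs(c("a", "b", "c", "d", "e", "f", "c"),
                 c("b", "c", "a", "e", "f", "d", "d"))
}

two_triangles_net <- function() {
  net_from_pairs(c("a", "b", "c", "d", "e", "f"),
                 c("b", "c", "a", "e", "f", "d"))
}

random_net <- function(n_nodes, n_edges, seed) {
  v <- sprintf("v%02d", seq_len(n_nodes))
  idx <- utils::combn(n_nodes, 2)
  withr::with_seed(seed, {
    pick <- sample(ncol(idx), n_edges)
    net_from_pairs(v[idx[1, pick]], v[idx[2, pick]],
                   pcc = round(runif(n_edges, -1, 1), 3))
  })
}

# adjacency list from a gene_network
adj_list <- function(g) {
  nodes <- network_nodes(g)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in seq_len(nrow(g))) {
    adj[[g$gene_a[e]]] <- c(adj[[g$gene_a[e]]], g$gene_b[e])
    adj[[g$gene_b[e]]] <- c(adj[[g$gene_b[e]]], g$gene_a[e])
  }
  adj
}

# plain BFS all-pairs shortest paths; Inf when unreachable
bfs_distances <- function(g) {
  nodes <- network_nodes(g)
  adj <- adj_list(g)
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_diameter <- function(g) {
  d <- bfs_distances(g)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

# betweenness by shortest-path counting: sigma_s(v) path counts via BFS
# levels, then the pair-dependency formula summed over unordered pairs
oracle_betweenness <- function(g) {
  nodes <- network_nodes(g)
  adj <- adj_list(g)
  d <- bfs_distances(g)
  sigma <- function(s) {
    cnt <- stats::setNames(rep(0, length(nodes)), nodes)
    cnt[s] <- 1
    for (dist in seq_len(max(d[s, is.finite(d[s, ])]))) {
      for (v in nodes[d[s, ] == dist]) {
        preds <- adj[[v]][d[s, adj[[v]]] == dist - 1]
        cnt[v] <- sum(cnt[preds])
      }
    }
    cnt
  }
  sig <- sapply(nodes, sigma)        # sig[v, s] = #shortest s->v paths
  bt <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j || !is.finite(d[i, j])) next
      s <- nodes[i]; t <- nodes[j]
      for (v in nodes) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && d[s, v] + d[v, t] == d[s, t]) {
          bt[v] <- bt[v] + sig[v, s] * sig[t, v] / sig[t, s]
        }
      }
    }
  }
  bt
}

# all set partitions of seq_len(n) as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1)) grow(c(labels, lab), max(k, lab))
  }
  grow(integer(0), 0L)
  out
}

# independent modularity evaluation: pairwise (A_ij - k_i k_j / 2m)
# summed over same-community pairs, straight from the definition
oracle_modularity <- function(g, labels) {
  nodes <- network_nodes(g)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(g))) {
    A[g$gene_a[e], g$gene_b[e]] <- 1
    A[g$gene_b[e], g$gene_a[e]] <- 1
  }
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in nodes) for (j in nodes) {
    if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  unname(q / m2)
}

oracle_best_modularity <- function(g) {
  nodes <- network_nodes(g)
  parts <- all_partitions(length(nodes))
  qs <- vapply(parts, function(p) {
    oracle_modularity(g, stats::setNames(p, nodes))
  }, 1.0)
  list(max_q = max(qs), all_q = qs)
}

# hypergeometric upper tail by exhaustive enumeration of draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # treat 1..K as the category
  mean(hits >= k)
}

# two-pass Pearson correlation from the defining formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

make_em <- function(values, n_tumor, n_normal,
                    genes = sprintf("g%02d", seq_len(nrow(values)))) {
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, stats::setNames(rep(c("tumor", "normal"),
                                          c(n_tumor, n_normal)), samples))
}

# drive the package's hypergeometric path for arbitrary (N, K, n, k) by
# constructing a two-cluster partition with the requested overlap
phyper_tail_via_package <- function(N, K, n, k) {
  genes <- sprintf("x%03d", seq_len(N))
  part <- tibble::tibble(gene = genes,
                         community = rep(c(1, 2), c(n, N - n)))
  term <- c(genes[seq_len(k)], genes[n + seq_len(K - k)])
  sets <- tibble::tibble(term_id = "T", description = "t",
                         genes = list(term))
  out <- hypergeom_enrich(part, sets, min_cluster_size = 1)
  out$p[out$cluster == "1"]
}

# order-free representation of an edge set for equality checks
canonical_form <- function(g) {
  sort(paste(pmin(g$gene_a, g$gene_b), pmax(g$gene_a, g$gene_b)))
}

# 4-regular circulant: ring plus next-nearest-neighbour chords
circulant_net <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  net_from_pairs(c(v, v), c(v[c(2:n, 1)], v[c(3:n, 1, 2)]))
}
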