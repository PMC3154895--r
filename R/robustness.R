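# Diameter (average intra-component shortest path) and largest-component
# size of an igraph, with the convention that a graph with no surviving
# intra-component pair reports diameter 0 and defined = FALSE so curves
# stay plottable through collapse.
survival_stats <- function(ig) {
  nv <- igraph::vcount(ig)
  if (nv == 0) return(list(diameter = 0, defined = FALSE, lcc = 0L))
  lcc <- max(igraph::components(ig)$csize)
  if (igraph::ecount(ig) == 0) {
    return(list(diameter = 0, defined = FALSE, lcc = as.integer(lcc)))
  }
  d <- igraph::distances(ig)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    return(list(diameter = 0, defined = FALSE, lcc = as.integer(lcc)))
  }
  list(diameter = mean(vals), defined = TRUE, lcc = as.integer(lcc))
}

removal_grid <- function(n, f_max, step) {
  fr <- seq(0, f_max, by = step)
  tibble(fraction = fr, n_removed = pmin(n, round(fr * n)))
}

curve_over_removals <- function(ig, order_fun, grid) {
  rows <- vector("list", nrow(grid))
  removed <- 0L
  for (i in seq_len(nrow(grid))) {
    while (removed < grid$n_removed[i] && igraph::vcount(ig) > 0) {
      victim <- order_fun(ig)
      ig <- igraph::delete_vertices(ig, victim)
      removed <- removed + 1L
    }
    st <- survival_stats(ig)
    rows[[i]] <- tibble(fraction = grid$fraction[i], n_removed = removed,
                        diameter = st$diameter, defined = st$defined,
                        lcc_size = st$lcc)
  }
  bind_rows(rows)
}

#' Targeted hub-removal (attack) robustness curve
#'
#' Iteratively removes the currently highest-degree node (ties broken
#' toward the lexicographically smallest gene id), recording the
#' average shortest-path diameter and largest-component size at each
#' removal-fraction grid point. With `adaptive = FALSE` nodes are
#' ranked once by their initial degree instead of re-ranking after
#' every removal.
#'
#' @param g A non-empty [gene_network()].
#' @param f_max,step Removal-fraction grid (defaults 0.2 by 0.01).
#' @param adaptive Re-rank hubs after each removal (default `TRUE`).
#' @return A `robustness_curve` tibble: `mode`, `fraction`,
#'   `n_removed`, `diameter`, `defined` (whether any intra-component
#'   pair survived), `lcc_size`.
#' @export
attack_curve <- function(g, f_max = 0.2, step = 0.01, adaptive = TRUE) {
  if (n_nodes(g) == 0) abort("empty network")
  ig <- as_igraph(g)
  grid <- removal_grid(n_nodes(g), f_max, step)
  if (adaptive) {
    pick <- function(h) {
      deg <- igraph::degree(h)
      nm <- names(deg)[deg == max(deg)]
      min(nm)
    }
    out <- curve_over_removals(ig, pick, grid)
  } else {
    deg <- igraph::degree(ig)
    ord <- names(deg)[order(-deg, names(deg))]
    i <- 0L
    pick <- function(h) {
      i <<- i + 1L
      ord[i]
    }
    out <- curve_over_removals(ig, pick, grid)
  }
  out$mode <- "attack"
  new_robustness_curve(out)
}

#' Random node-removal (error) robustness curve
#'
#' Removes uniformly random nodes and records the same quantities as
#' [attack_curve()], averaged over `n_trials` seeded trials (`defined`
#' becomes the proportion of trials with a defined diameter;
#' undefined diameters enter the average as 0).
#'
#' @param g A non-empty [gene_network()].
#' @param f_max,step Removal-fraction grid.
#' @param seed Integer seed; trial seeds are derived from it.
#' @param n_trials Number of random-removal trials (default 20).
#' @return A `robustness_curve` tibble as in [attack_curve()].
#' @export
error_curve <- function(g, f_max = 0.2, step = 0.01, seed = 1L, n_trials = 20) {
  if (n_nodes(g) == 0) abort("empty network")
  ig0 <- as_igraph(g)
  grid <- removal_grid(n_nodes(g), f_max, step)
  trials <- purrr::map(seq_len(n_trials), function(tr) {
    ord <- with_seed(derive_seed(seed, tr),
                     sample(network_nodes(g)))
    i <- 0L
    pick <- function(h) {
      i <<- i + 1L
      ord[i]
    }
    curve_over_removals(ig0, pick, grid)
  })
  all <- bind_rows(trials)
  out <- all |>
    group_by(.data$fraction, .data$n_removed) |>
    summarise(diameter = mean(.data$diameter),
              defined = mean(.data$defined),
              lcc_size = mean(.data$lcc_size),
              .groups = "drop")
  out$mode <- "error"
  new_robustness_curve(out)
}

new_robustness_curve <- function(x) {
  x <- x[, c("mode", "fraction", "n_removed", "diameter", "defined",
             "lcc_size")]
  class(x) <- c("robustness_curve", class(tibble()))
  x
}

#' @export
autoplot.robustness_curve <- function(object, ...) {
  extra <- list(...)
  df <- as_tibble(object)
  for (o in extra) df <- bind_rows(df, as_tibble(o))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$diameter,
                                   colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "average shortest-path diameter",
                  title = "Network stability under attack and error")
}
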