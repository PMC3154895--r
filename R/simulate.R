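#' Configuration for the synthetic expression generator
#'
#' The generator emulates a small two-group microarray cohort whose
#' genes are organised into tightly co-expressed modules: each module
#' has a latent factor drawn per sample, module genes load on it with a
#' common coefficient, a few hub genes additionally load on a second
#' module, and background genes are pure noise. A chosen fraction of
#' genes is differentially expressed as a mean shift on the tumor
#' samples, and up-regulated DE genes receive CREB-binding annotations
#' with a controlled pass rate.
#'
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes.
#' @param background_genes Number of genes not assigned to any module;
#'   `sum(module_sizes) + background_genes` must equal `n_genes`.
#' @param loading Within-module factor loading `a` in (0, 1); the
#'   population within-module correlation is `a^2 / (a^2 + noise_sd^2)`.
#' @param noise_sd Residual noise standard deviation (> 0).
#' @param n_hubs_per_module Number of genes per module that also load
#'   (with coefficient `loading / 2`) on the next module, creating
#'   high-degree hubs.
#' @param n_tumor,n_normal Sample counts per group.
#' @param de_fraction Fraction of genes differentially expressed
#'   between the groups, chosen uniformly over all genes.
#' @param de_effect Mean shift added to the tumor samples of DE genes,
#'   in units of `noise_sd` (sign drawn with equal probability).
#' @param cre_pass_fraction Fraction of up-regulated DE genes whose
#'   CREB annotation passes the BV <= 0.001 and BR >= 1.5 thresholds.
#' @param seed Integer seed governing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       module_sizes = rep(20L, 10),
                       background_genes = 300L,
                       loading = 0.95,
                       noise_sd = 0.3,
                       n_hubs_per_module = 1L,
                       n_tumor = 9L,
                       n_normal = 4L,
                       de_fraction = 0,
                       de_effect = 3,
                       cre_pass_fraction = 0.6,
                       seed = 101L) {
  cfg <- list(n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              background_genes = as.integer(background_genes),
              loading = loading, noise_sd = noise_sd,
              n_hubs_per_module = as.integer(n_hubs_per_module),
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              de_fraction = de_fraction, de_effect = de_effect,
              cre_pass_fraction = cre_pass_fraction,
              seed = as.integer(seed))
  if (sum(cfg$module_sizes) + cfg$background_genes != cfg$n_genes) {
    abort("sum(module_sizes) + background_genes must equal n_genes")
  }
  if (cfg$n_tumor + cfg$n_normal < 4) abort("need at least 4 samples in total")
  if (cfg$loading <= 0 || cfg$loading >= 1) abort("`loading` must be in (0, 1)")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) abort("`de_fraction` in [0, 1]")
  if (cfg$de_fraction > 0 && cfg$n_tumor == 0) {
    abort("de_fraction > 0 requires tumor samples")
  }
  if (cfg$cre_pass_fraction < 0 || cfg$cre_pass_fraction > 1) {
    abort("`cre_pass_fraction` in [0, 1]")
  }
  if (any(cfg$module_sizes < cfg$n_hubs_per_module)) {
    abort("n_hubs_per_module exceeds a module size")
  }
  structure(cfg, class = "sim_config")
}

#' Default configuration mirroring the studied cohort shape
#'
#' 500 genes (10 modules of 20 plus 300 background), 9 tumor and 4
#' normal samples, 27% of genes differentially expressed — the sample
#' design and DE rate of the small-intestinal NET cohort the pipeline
#' was built around, at a desk-scale gene count.
#'
#' @return A `sim_config`.
#' @export
default_paper_shape <- function() {
  sim_config(n_genes = 500, module_sizes = rep(20L, 10),
             background_genes = 300L, loading = 0.95, noise_sd = 0.3,
             n_hubs_per_module = 1L, n_tumor = 9L, n_normal = 4L,
             de_fraction = 0.27, de_effect = 3, cre_pass_fraction = 0.6,
             seed = 101L)
}

#' Simulate an expression cohort with planted structure
#'
#' @param config A [sim_config()].
#' @return A list of class `coexnet_sim` with elements
#'   \describe{
#'     \item{expression}{an [expr_matrix()]}
#'     \item{truth}{tibble `gene`, `module`, `is_hub`, `de`,
#'       `direction`, `cre_pass`}
#'     \item{gene_sets}{tibble (GMT shape) with one term per planted
#'       module}
#'     \item{cre_table}{tibble `gene`, `bv`, `br` for up-regulated DE
#'       genes}
#'   }
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  n_mod <- length(cfg$module_sizes)
  n_samp <- cfg$n_normal + cfg$n_tumor
  sample_ids <- c(sprintf("N%02d", seq_len(cfg$n_normal)),
                  sprintf("T%02d", seq_len(cfg$n_tumor)))
  groups <- setNames(rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor)),
                     sample_ids)
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
  module_of <- rep(c(sprintf("M%02d", seq_len(n_mod)), "background"),
                   c(cfg$module_sizes, cfg$background_genes))

  # latent factors, one row per module, one column per sample
  fac <- matrix(rnorm(n_mod * n_samp), n_mod, n_samp)
  vals <- matrix(rnorm(cfg$n_genes * n_samp, sd = cfg$noise_sd),
                 cfg$n_genes, n_samp, dimnames = list(genes, sample_ids))
  is_hub <- logical(cfg$n_genes)
  for (c_idx in seq_len(n_mod)) {
    rows <- which(module_of == sprintf("M%02d", c_idx))
    vals[rows, ] <- vals[rows, , drop = FALSE] +
      cfg$loading * matrix(fac[c_idx, ], length(rows), n_samp, byrow = TRUE)
    if (cfg$n_hubs_per_module > 0 && n_mod > 1) {
      hubs <- rows[seq_len(cfg$n_hubs_per_module)]
      other <- c_idx %% n_mod + 1L
      vals[hubs, ] <- vals[hubs, , drop = FALSE] +
        (cfg$loading / 2) * matrix(fac[other, ], length(hubs), n_samp, byrow = TRUE)
      is_hub[hubs] <- TRUE
    }
  }

  # differential expression: mean shift on tumor samples only
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_genes <- sort(sample.int(cfg$n_genes, n_de))
  direction <- rep(NA_character_, cfg$n_genes)
  if (n_de > 0) {
    dir_draw <- sample(c("up", "down"), n_de, replace = TRUE)
    direction[de_genes] <- dir_draw
    shift <- cfg$de_effect * cfg$noise_sd
    tum <- which(groups == "tumor")
    signs <- ifelse(dir_draw == "up", 1, -1)
    vals[de_genes, tum] <- vals[de_genes, tum, drop = FALSE] + signs * shift
  }

  truth <- tibble(gene = genes, module = module_of, is_hub = is_hub,
                  de = seq_len(cfg$n_genes) %in% de_genes,
                  direction = direction,
                  cre_pass = NA)

  gene_sets <- tibble(
    term_id = sprintf("M%02d", seq_len(n_mod)),
    description = sprintf("planted module %d", seq_len(n_mod)),
    genes = purrr::map(sprintf("M%02d", seq_len(n_mod)),
                       function(m) genes[module_of == m])
  )

  # CREB annotations for up-regulated DE genes; BV spans the published
  # binding-value range [1e-13, 1e-1] log-uniformly, BR spans [1, 8]
  up <- genes[!is.na(direction) & direction == "up"]
  n_pass <- round(cfg$cre_pass_fraction * length(up))
  pass_idx <- if (length(up) > 0) sample(seq_along(up), n_pass) else integer()
  bv <- br <- numeric(length(up))
  is_pass <- seq_along(up) %in% pass_idx
  if (any(is_pass)) {
    bv[is_pass] <- 10^runif(sum(is_pass), -13, -3)
    br[is_pass] <- runif(sum(is_pass), 1.5, 8)
  }
  if (any(!is_pass)) {
    # failures miss the binding-value threshold (BV > 0.001)
    bv[!is_pass] <- 10^runif(sum(!is_pass), -3 + 1e-9, -1)
    br[!is_pass] <- runif(sum(!is_pass), 1, 8)
  }
  cre_table <- tibble(gene = up, bv = bv, br = br)
  truth$cre_pass <- ifelse(truth$gene %in% up[is_pass], TRUE,
                           ifelse(truth$gene %in% up, FALSE, NA))

  structure(list(expression = expr_matrix(vals, groups),
                 truth = truth, gene_sets = gene_sets,
                 cre_table = cre_table, config = cfg),
            class = "coexnet_sim")
}

#' Write a simulated cohort to a directory
#'
#' Writes `expression.tsv`, `metadata.tsv`, `truth.tsv`, `modules.gmt`
#' and `cre.tsv`.
#'
#' @param sim A `coexnet_sim` from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "coexnet_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(sim$expression,
                   file.path(dir, "expression.tsv"),
                   file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  write_gmt(sim$gene_sets, file.path(dir, "modules.gmt"))
  readr::write_tsv(sim$cre_table, file.path(dir, "cre.tsv"), progress = FALSE)
  invisible(dir)
}
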