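#' Two-group differential expression by Student's t-test
#'
#' Per-gene two-sample t-test of tumor versus normal, with the sign
#' convention tumor mean minus normal mean (positive t = up-regulated
#' in tumor). The default is the classic equal-variance Student test
#' with `n1 + n2 - 2` degrees of freedom; `var_equal = FALSE` gives
#' the Welch variant. Significance is called at raw `p <= alpha` with
#' no multiple-testing correction (a BH-adjusted column is emitted
#' alongside for modern use). Genes with zero pooled variance get an
#' undefined (`NA`) statistic and are never called significant.
#'
#' @param em An [expr_matrix()] with at least 2 samples per group.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return A `de_table` tibble: `gene`, `mean_tumor`, `mean_normal`,
#'   `t`, `df`, `p`, `p_adj`, `significant`, `direction` (`"up"` /
#'   `"down"` for significant genes, `NA` otherwise).
#' @export
ttest_de <- function(em, alpha = 0.05, var_equal = TRUE) {
  tum <- em$values[, em$groups == "tumor", drop = FALSE]
  nor <- em$values[, em$groups == "normal", drop = FALSE]
  n1 <- ncol(tum)
  n2 <- ncol(nor)
  if (n1 < 2 || n2 < 2) abort("need at least 2 samples per group")
  m1 <- rowMeans(tum)
  m2 <- rowMeans(nor)
  v1 <- apply(tum, 1, stats::var)
  v2 <- apply(nor, 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tval <- unname(ifelse(se > 0, (m1 - m2) / se, NA_real_))
  p <- 2 * pt(abs(tval), unname(df), lower.tail = FALSE)
  sig <- !is.na(p) & p <= alpha
  out <- tibble(gene = rownames(em$values),
                mean_tumor = unname(m1), mean_normal = unname(m2),
                t = unname(tval), df = unname(df), p = unname(p),
                p_adj = p.adjust(p, method = "BH"),
                significant = sig,
                direction = ifelse(sig, ifelse(tval > 0, "up", "down"),
                                   NA_character_))
  if (any(is.na(tval))) {
    warn(sprintf("%d gene(s) with zero pooled variance: t undefined",
                 sum(is.na(tval))))
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("de_table", class(out))
  out
}

#' Differential-expression bookkeeping
#'
#' Counts up- and down-regulated significant genes and the fraction of
#' the background they represent.
#'
#' @param de A `de_table` from [ttest_de()] (any data frame with a
#'   `direction` column works).
#' @param background_size Number of background genes the fraction
#'   refers to (default: rows of `de`).
#' @return One-row tibble: `n_up`, `n_down`, `n_total`, `fraction`,
#'   `percent` (rounded to the nearest integer).
#' @export
de_counts <- function(de, background_size = nrow(de)) {
  n_up <- sum(de$direction == "up", na.rm = TRUE)
  n_down <- sum(de$direction == "down", na.rm = TRUE)
  n_total <- n_up + n_down
  fraction <- if (background_size > 0) n_total / background_size else 0
  tibble(n_up = n_up, n_down = n_down, n_total = n_total,
         fraction = fraction, percent = round(100 * fraction))
}

#' Annotate network nodes with DE status and gene-list membership
#'
#' Per-node table combining differential expression, membership in a
#' user-supplied gene list (e.g. somatically mutated cancer genes) and,
#' optionally, the community label; plus summary percentages rounded
#' to the nearest integer.
#'
#' @param g A [gene_network()].
#' @param de Optional `de_table` from [ttest_de()].
#' @param gene_list Optional character vector of flagged genes.
#' @param partition Optional `module_partition`.
#' @return Tibble with one row per network node: `gene`, `degree`,
#'   `significant`, `direction`, `in_list`, `community`; summary
#'   attached as attribute `summary` (tibble `n_nodes`, `n_de`,
#'   `pct_de`, `n_listed`, `pct_listed`).
#' @export
overlay_network <- function(g, de = NULL, gene_list = NULL, partition = NULL) {
  deg <- igraph::degree(as_igraph(g))
  out <- tibble(gene = names(deg), degree = unname(deg))
  if (!is.null(de)) {
    out <- left_join(out, select(as_tibble(as.data.frame(de)),
                                 "gene", "significant", "direction"),
                     by = "gene")
  } else {
    out$significant <- NA
    out$direction <- NA_character_
  }
  out$in_list <- out$gene %in% (gene_list %||% character())
  if (!is.null(partition)) {
    out <- left_join(out, rename(as_tibble(as.data.frame(partition)),
                                 community = "community"),
                     by = "gene")
  }
  n <- nrow(out)
  n_de <- sum(out$significant %in% TRUE)
  n_listed <- sum(out$in_list)
  attr(out, "summary") <- tibble(
    n_nodes = n, n_de = n_de,
    pct_de = if (n > 0) round(100 * n_de / n) else 0,
    n_listed = n_listed,
    pct_listed = if (n > 0) round(100 * n_listed / n) else 0)
  out
}

#' CREB-target filter on up-regulated genes
#'
#' A gene passes when it is annotated in the CREB-binding table with
#' binding value `BV <= bv_max` and binding ratio `BR >= br_min`
#' (strict inequalities with `strict = TRUE`). Genes without an
#' annotation are excluded silently but counted.
#'
#' @param up_genes Character vector of up-regulated genes.
#' @param cre CRE annotation tibble (`gene`, `bv`, `br`), e.g. from
#'   [read_cre_table()].
#' @param bv_max Binding-value threshold (default 0.001).
#' @param br_min Binding-ratio threshold (default 1.5).
#' @param strict Use `BV < bv_max` and `BR > br_min` instead of the
#'   inclusive comparisons. Default `FALSE`.
#' @return A `cre_filter_result`: tibble of passing genes with their
#'   `bv`, `br`; attributes `n_input`, `n_annotated`, `bv_max`,
#'   `br_min`, `strict`.
#' @export
cre_filter <- function(up_genes, cre, bv_max = 0.001, br_min = 1.5,
                       strict = FALSE) {
  cre <- validate_cre_table(cre)
  ann <- cre[cre$gene %in% up_genes, ]
  pass <- if (strict) ann$bv < bv_max & ann$br > br_min
          else ann$bv <= bv_max & ann$br >= br_min
  out <- ann[pass, ]
  out <- arrange(out, .data$bv)
  attr(out, "n_input") <- length(unique(up_genes))
  attr(out, "n_annotated") <- nrow(ann)
  attr(out, "bv_max") <- bv_max
  attr(out, "br_min") <- br_min
  attr(out, "strict") <- strict
  class(out) <- c("cre_filter_result", class(out))
  out
}

#' @export
print.cre_filter_result <- function(x, ...) {
  cat(sprintf(
    "<cre_filter_result> %d/%d annotated up-regulated genes pass BV %s %g, BR %s %g\n",
    nrow(x), attr(x, "n_annotated"),
    ifelse(attr(x, "strict"), "<", "<="), attr(x, "bv_max"),
    ifelse(attr(x, "strict"), ">", ">="), attr(x, "br_min")))
  NextMethod()
}

#' @export
glance.cre_filter_result <- function(x, ...) {
  tibble(n_input = attr(x, "n_input"), n_annotated = attr(x, "n_annotated"),
         n_pass = nrow(x), bv_max = attr(x, "bv_max"),
         br_min = attr(x, "br_min"), strict = attr(x, "strict"))
}
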