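#' Expression matrix with sample group labels
#'
#' Container for a genes-by-samples intensity matrix plus a `tumor` /
#' `normal` label per sample. This is the single upstream input of the
#' pipeline; every value is validated on construction (unique gene ids,
#' no missing cells, a group for every sample).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param groups Named character vector mapping each sample id to
#'   `"tumor"` or `"normal"`, or a data frame with columns `sample_id`
#'   and `group`.
#' @return An object of class `expr_matrix`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, c(s1 = "tumor", s2 = "tumor",
#'                        s3 = "normal", s4 = "normal"))
#' n_genes(em)
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene rownames and sample colnames.")
  }
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("metadata must have columns `sample_id` and `group`.")
    }
    groups <- setNames(as.character(groups$group), as.character(groups$sample_id))
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    abort(paste0("duplicated gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf("missing value at gene '%s', sample '%s'",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  missing_meta <- setdiff(colnames(values), names(groups))
  if (length(missing_meta) > 0) {
    abort(paste0("sample(s) missing from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  groups <- groups[colnames(values)]
  bad_grp <- setdiff(unique(groups), c("tumor", "normal"))
  if (length(bad_grp) > 0) {
    abort(paste0("group labels must be 'tumor' or 'normal'; found: ",
                 paste(bad_grp, collapse = ", ")))
  }
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x,em An `expr_matrix`.
#' @export
n_genes <- function(em) nrow(em$values)

#' @rdname expr_matrix
#' @export
n_samples <- function(em) ncol(em$values)

#' @rdname expr_matrix
#' @export
gene_ids <- function(em) rownames(em$values)

#' Long tibble view of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `group`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    gene_id   = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    group     = rep(unname(x$groups), each = nrow(x$values)),
    value     = as.vector(x$values)
  )
}

#' @export
glance.expr_matrix <- function(x, ...) {
  tibble(n_genes = n_genes(x), n_samples = n_samples(x),
         n_tumor = sum(x$groups == "tumor"),
         n_normal = sum(x$groups == "normal"))
}

#' Load an expression matrix and its sample metadata
#'
#' Reads a tab-delimited intensity table (first column `gene_id`, one
#' column per sample) together with a metadata table (`sample_id`,
#' `group`) and returns a validated [expr_matrix()]. Row and column
#' order are preserved from the files. Lines starting with `#` are
#' ignored in both files.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param log2 If `TRUE`, apply `log2(x + 1)` to the intensities after
#'   loading. Default `FALSE`: values are used as given.
#' @return An `expr_matrix`.
#' @export
load_expression <- function(matrix_path, metadata_path, log2 = FALSE) {
  raw <- readr::read_tsv(matrix_path, comment = "#", na = character(),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression file needs a gene_id column plus >= 1 sample")
  gene <- as.character(raw[[1]])
  samp <- names(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samp),
                 dimnames = list(gene, samp))
  for (j in seq_along(samp)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(col))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                    col[bad[1]], gene[bad[1]], samp[j]))
    }
    vals[, j] <- num
  }
  meta <- readr::read_tsv(metadata_path, comment = "#",
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (isTRUE(log2)) vals <- log2(vals + 1)
  expr_matrix(vals, meta)
}

#' Write an expression matrix and metadata to TSV files
#'
#' Inverse of [load_expression()]; round-trips exactly up to numeric
#' formatting.
#'
#' @param em An `expr_matrix`.
#' @param matrix_path,metadata_path Output paths.
#' @return `em`, invisibly.
#' @export
write_expression <- function(em, matrix_path, metadata_path) {
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE)
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  readr::write_tsv(tibble(sample_id = names(em$groups),
                          group = unname(em$groups)),
                   metadata_path, progress = FALSE)
  invisible(em)
}

#' Collapse probe-level rows to gene level by per-sample median
#'
#' When several probes map to one gene, the retained gene row is the
#' per-sample median of the probes' intensities (for an even number of
#' probes, the mean of the two central values). Gene order follows the
#' first appearance of each gene in the probe matrix.
#'
#' @param em An `expr_matrix` whose rows are probe ids.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene allowed).
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(em, probe_map) {
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` must have columns `probe_id` and `gene_id`.")
  }
  map <- setNames(as.character(probe_map$gene_id), as.character(probe_map$probe_id))
  probes <- rownames(em$values)
  unmapped <- setdiff(probes, names(map))
  if (length(unmapped) > 0) {
    abort(paste0("unmapped probe(s): ", paste(unmapped, collapse = ", ")))
  }
  gene_of <- unname(map[probes])
  genes <- unique(gene_of)
  out <- matrix(NA_real_, length(genes), ncol(em$values),
                dimnames = list(genes, colnames(em$values)))
  for (g in genes) {
    rows <- em$values[gene_of == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2, median)
  }
  expr_matrix(out, em$groups)
}
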