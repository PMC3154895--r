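#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term_id TAB description TAB gene...`.
#' Duplicate genes within a line are collapsed; a line with fewer than
#' three fields, or whose gene list is empty after deduplication, is an
#' error naming the line.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `description` and a
#'   list-column `genes` (character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(parts, function(p, i) {
    if (length(p) < 3) abort(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- unique(p[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) abort(sprintf("GMT line %d has an empty gene list", i))
    tibble(term_id = p[1], description = p[2], genes = list(genes))
  })
  bind_rows(rows)
}

#' Write a GMT gene-set collection
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(term_id, description, genes, ...) {
    paste(c(term_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(sets)
}

#' Read a CREB-target annotation table
#'
#' Tab-separated columns `gene`, `bv` (binding value, a p-value-like
#' confidence in `(0, 1]`) and `br` (binding ratio, non-negative), one
#' row per gene.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `bv`, `br`.
#' @export
read_cre_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           gene = readr::col_character(),
                           bv = readr::col_double(),
                           br = readr::col_double()))
  validate_cre_table(tab)
}

validate_cre_table <- function(tab) {
  tab <- as_tibble(tab)
  if (!all(c("gene", "bv", "br") %in% names(tab))) {
    abort("CRE table must have columns `gene`, `bv`, `br`.")
  }
  if (anyDuplicated(tab$gene) > 0) {
    abort(paste0("duplicated CRE gene(s): ",
                 paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", ")))
  }
  if (any(!is.finite(tab$bv)) || any(tab$bv <= 0) || any(tab$bv > 1)) {
    abort("binding values must lie in (0, 1]")
  }
  if (any(!is.finite(tab$br)) || any(tab$br < 0)) {
    abort("binding ratios must be >= 0")
  }
  tab[, c("gene", "bv", "br")]
}
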