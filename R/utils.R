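# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream so library code never perturbs
# (or depends on) the caller's random state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed from a parent seed and an offset, kept
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 10007 + offset) %% 2147483647)
}

# Canonicalise an edge table so gene_a < gene_b lexicographically and rows
# are sorted; used everywhere two edge sets must be comparable.
canonical_edges <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

edge_keys <- function(edges) paste(edges$gene_a, edges$gene_b, sep = "\r")

`%||%` <- rlang::`%||%`
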