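# Small fixtures built in code.

# minimal hand-written catalog: lengths chosen for easy FPKM arithmetic
toy_catalog <- function(lengths = c(g1 = 1000L, g2 = 2000L, g3 = 500L),
                        categories = NULL) {
  n <- length(lengths)
  categories <- categories %||% rep("other", n)
  tibble::tibble(
    gene_id = names(lengths),
    scaffold_id = "s1",
    start = cumsum(c(1L, utils::head(lengths, -1) + 100L)),
    end = cumsum(c(1L, utils::head(lengths, -1) + 100L)) + lengths - 1L,
    strand = "+",
    length_nt = unname(lengths),
    category = categories,
    pathway_tag = "hyp"
  )
}

# counts tibble from a named matrix
counts_tbl <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = rownames(m)),
    tibble::as_tibble(m)
  ))
}

# coupling map with every category flat (null simulation)
null_coupling <- function() {
  stats::setNames(rep(0, length(gene_categories())), gene_categories())
}

# flat per-category baseline (no expression-scale differences)
flat_scale <- function() {
  stats::setNames(rep(1, length(gene_categories())), gene_categories())
}

`%||%` <- rlang::`%||%`
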