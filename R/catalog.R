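#' Generate a synthetic gene catalog
#'
#' Draws a catalog of protein-coding genes laid out head-to-tail on
#' artificial scaffolds, each gene carrying one functional-category label
#' drawn from [gene_categories()].  The default category weights mirror a
#' ~6,500-gene sulfate-reducer genome: a few dozen dissimilatory sulfate
#' reduction and ribosomal protein genes, COG D/L/M growth genes at roughly
#' 73/280/215 per 6,440 CDS, and a large uncharacterised remainder.
#'
#' @param n_genes Number of genes to generate (positive integer).
#' @param category_weights Named numeric vector of multinomial category
#'   probabilities over [gene_categories()]; must sum to 1 (tolerance 1e-9).
#'   Missing categories get weight 0.
#' @param length_range Length-2 integer vector; gene lengths are drawn
#'   uniformly from this range (nt, within 100-10000).
#' @param seed Integer seed; the catalog is deterministic given the seed.
#' @param genes_per_scaffold Genes per artificial scaffold.
#'
#' @return A tibble of class `zg_catalog` with columns `gene_id`,
#'   `scaffold_id`, `start`, `end`, `strand`, `length_nt`, `category`,
#'   `pathway_tag`.
#' @export
#' @examples
#' cat6 <- generate_gene_catalog(60, seed = 1)
#' dplyr::count(cat6, category)
generate_gene_catalog <- function(n_genes,
                                  category_weights = default_category_weights(),
                                  length_range = c(200, 3000),
                                  seed = 1L,
                                  genes_per_scaffold = 50L) {
  zg_check(length(n_genes) == 1 && n_genes >= 1, "`n_genes` must be a positive integer")
  zg_check(all(length_range >= 100) && all(length_range <= 10000) &&
             length_range[1] <= length_range[2],
           "`length_range` must lie within [100, 10000] nt")
  w <- rep(0, length(gene_categories()))
  names(w) <- gene_categories()
  zg_check(all(names(category_weights) %in% gene_categories()),
           "unknown category in `category_weights`")
  w[names(category_weights)] <- category_weights
  zg_check(abs(sum(w) - 1) <= 1e-9, "`category_weights` must sum to 1")

  withr::with_seed(seed, {
    category <- sample(names(w), n_genes, replace = TRUE, prob = w)
    length_nt <- sample(seq(length_range[1], length_range[2]), n_genes,
                        replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  # multiple of 3 so lengths look like CDS
  length_nt <- pmax(3L, (length_nt %/% 3L) * 3L)

  scaffold_idx <- ((seq_len(n_genes) - 1L) %/% genes_per_scaffold) + 1L
  scaffold_id <- sprintf("scaffold_%04d", scaffold_idx)
  # head-to-tail layout with a fixed 100 nt spacer, restarting per scaffold
  start <- integer(n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    if (i > 1L && scaffold_idx[i] != scaffold_idx[i - 1L]) pos <- 1L
    start[i] <- pos
    pos <- pos + length_nt[i] + 100L
  }

  tag <- default_pathway_tags(category)
  out <- tibble(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    scaffold_id = scaffold_id,
    start = start,
    end = start + length_nt - 1L,
    strand = strand,
    length_nt = length_nt,
    category = category,
    pathway_tag = tag
  )
  class(out) <- c("zg_catalog", class(out))
  out
}

#' @rdname generate_gene_catalog
#' @details `default_category_weights()` returns the default multinomial
#'   weights: COG D/L/M at the 73/280/215-per-6,440 proportions of the focal
#'   genome, small sulfate-reduction, ribosomal, central-energy, stress,
#'   sporulation and phage-response sets, remainder `other`.
#' @export
default_category_weights <- function() {
  w <- c(
    sulfate_reduction = 0.010,
    ribosomal         = 0.010,
    central_energy    = 0.020,
    growth_division   = 73 / 6440,
    growth_replication = 280 / 6440,
    growth_envelope   = 215 / 6440,
    stress            = 0.005,
    sporulation       = 0.015,
    phage_response    = 0.005
  )
  c(w, other = 1 - sum(w))
}

# representative locus tags per category, cycled deterministically
default_pathway_tags <- function(category) {
  tags <- list(
    sulfate_reduction = c("dsrA", "dsrB", "aprA", "aprB", "sat", "qmoA"),
    ribosomal = c("rpsA", "rplB", "rpmE", "rpsL"),
    central_energy = c("atpA", "atpD", "nuoF", "nuoG"),
    growth_division = c("ftsZ", "minE", "ftsA"),
    growth_replication = c("gyrA", "gyrB", "dnaC", "dnaG"),
    growth_envelope = c("murA", "murB", "murC", "mraY"),
    stress = c("uspA", "groEL", "groES", "dnaK", "clpP"),
    sporulation = c("spo0A", "spoIIE", "spoVT"),
    phage_response = c("nrdE", "nrdF", "gatA", "gatB"),
    other = c("hyp")
  )
  vapply(seq_along(category), function(i) {
    pool <- tags[[category[i]]]
    pool[((i - 1L) %% length(pool)) + 1L]
  }, character(1))
}

#' Validate a gene catalog
#'
#' Checks the catalog invariants: unique gene ids, lengths consistent with
#' coordinates and at least one codon, categories from the closed set.
#'
#' @param catalog A gene catalog tibble.
#' @return The catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  need <- c("gene_id", "scaffold_id", "start", "end", "strand",
            "length_nt", "category")
  zg_check(all(need %in% names(catalog)),
           paste("catalog missing columns:",
                 paste(setdiff(need, names(catalog)), collapse = ", ")))
  zg_check(!anyDuplicated(catalog$gene_id), "gene_id values must be unique")
  zg_check(all(catalog$length_nt >= 3), "length_nt must be >= 3")
  zg_check(all(catalog$length_nt == catalog$end - catalog$start + 1),
           "length_nt must equal end - start + 1")
  zg_check(all(catalog$category %in% gene_categories()),
           "category outside the closed category set")
  zg_check(all(catalog$strand %in% c("+", "-")), "strand must be '+' or '-'")
  invisible(catalog)
}

#' Write / read a gene catalog as GFF3
#'
#' Round-trips the catalog through standard GFF3 using `rtracklayer`.
#' Category and pathway tag travel in the attribute column.
#'
#' @param catalog A gene catalog tibble.
#' @param path Output (or input) GFF3 path.
#' @return `write_catalog_gff3()` returns `path` invisibly;
#'   `read_catalog_gff3()` returns a `zg_catalog` tibble.
#' @export
write_catalog_gff3 <- function(catalog, path) {
  validate_catalog(catalog)
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$scaffold_id,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end),
    strand = catalog$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- catalog$gene_id
  gr$category <- catalog$category
  gr$pathway_tag <- catalog$pathway_tag %||% NA_character_
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_catalog_gff3
#' @export
read_catalog_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- tibble(
    gene_id = as.character(gr$ID),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length_nt = GenomicRanges::width(gr),
    category = as.character(gr$category),
    pathway_tag = as.character(gr$pathway_tag)
  )
  class(out) <- c("zg_catalog", class(out))
  validate_catalog(out)
  out
}
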