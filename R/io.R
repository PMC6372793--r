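# Plain-text IO: TSV for all tabular inputs and outputs.  Column contracts
# are validated on read so downstream errors surface at the boundary.

#' Read / write a count matrix as TSV
#'
#' Rows are genes, columns are samples; first column `gene_id`, header row
#' of sample ids.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @return `read_counts_tsv()` a tibble; writers return `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  zg_check("gene_id" %in% names(out), "counts TSV must have a gene_id column")
  counts_matrix(out)  # validates numeric, non-negative
  out
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample design TSV
#'
#' Expects columns `sample_id`, `substrate`, `sulfate`, `day`, `replicate`
#' (extra columns such as `library_depth` pass through).
#'
#' @param path File path.
#' @return Design tibble.
#' @export
read_design_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "substrate", "sulfate", "day", "replicate")
  zg_check(all(need %in% names(out)),
           paste("design TSV missing:", paste(setdiff(need, names(out)), collapse = ", ")))
  zg_check(!anyDuplicated(out[c("substrate", "sulfate", "day", "replicate")]),
           "design rows must be unique over (substrate, sulfate, day, replicate)")
  out
}

#' Read a per-scaffold coverage table TSV
#'
#' Expects `scaffold_id`, `length_nt`, `gc_percent`, `coverage_a`,
#' `coverage_b`.
#'
#' @param path File path.
#' @return Scaffold tibble.
#' @export
read_scaffolds_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("scaffold_id", "length_nt", "gc_percent", "coverage_a", "coverage_b")
  zg_check(all(need %in% names(out)),
           paste("scaffold TSV missing:", paste(setdiff(need, names(out)), collapse = ", ")))
  zg_check(all(out$gc_percent >= 0 & out$gc_percent <= 100),
           "gc_percent must lie in [0, 100]")
  zg_check(all(out$coverage_a >= 0 & out$coverage_b >= 0),
           "coverages must be >= 0")
  out
}

#' Read a homology hit table TSV
#'
#' Expects `query_id`, `subject_id`, `percent_identity`,
#' `percent_query_coverage`, `evidence_tier`; optional `synteny_support`.
#'
#' @param path File path.
#' @return Hit tibble.
#' @export
read_hits_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("query_id", "subject_id", "percent_identity",
            "percent_query_coverage", "evidence_tier")
  zg_check(all(need %in% names(out)),
           paste("hit TSV missing:", paste(setdiff(need, names(out)), collapse = ", ")))
  out
}

#' Read a qPCR series TSV
#'
#' Expects design columns plus `copies_per_cm3` (> 0).
#'
#' @param path File path.
#' @return qPCR tibble.
#' @export
read_qpcr_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  zg_check(all(c("day", "copies_per_cm3") %in% names(out)),
           "qPCR TSV needs `day` and `copies_per_cm3` columns")
  zg_check(all(out$copies_per_cm3 > 0), "copies_per_cm3 must be > 0")
  out
}
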