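# Support analyses around the focal genome: the stable-isotope-probing
# differential-coverage GC transform and rectangular bin gating, homology
# threshold annotation calls, and rrn-corrected population quantification.

#' GC-transform SIP coverage
#'
#' Sequencing a 13C-labelled SIP fraction skews apparent coverage with G+C
#' content (heavier, GC-rich DNA co-migrates into the labelled density
#' window).  The transform `t = (coverage / gc^9) * 1e15`, with GC on the
#' 0-100 percent scale, flattens that skew before differential-coverage
#' binning; with a rare genome at GC 42.6 percent and SIP coverage 34 it
#' yields a transformed coverage of ~74, the same order as the raw value.
#' The exponent and scale constant are configurable.
#'
#' @param coverage Mean per-base coverage (>= 0), vectorized.
#' @param gc_percent G+C content on the 0-100 scale (> 0), vectorized.
#' @param exponent GC exponent (default 9).
#' @param scale Multiplicative constant (default 1e15).
#' @return Transformed coverage, same length as the inputs.
#' @export
#' @examples
#' gc_transform_coverage(34, 42.6)  # ~73.6
gc_transform_coverage <- function(coverage, gc_percent, exponent = 9,
                                  scale = 1e15) {
  zg_check(all(gc_percent > 0), "`gc_percent` must be > 0")
  zg_check(all(coverage >= 0), "`coverage` must be >= 0")
  coverage / gc_percent^exponent * scale
}

#' Select a genome bin by rectangular coverage gates
#'
#' Keeps scaffolds falling inside axis-aligned ranges on native-soil
#' coverage (`coverage_a`), GC-transformed SIP coverage, and optionally GC
#' percent — the manual gate of a differential-coverage binning plot.
#'
#' @param scaffolds Tibble with `scaffold_id`, `length_nt`, `gc_percent`,
#'   `coverage_a`, `coverage_b`.
#' @param cov_a_range,cov_b_t_range Length-2 inclusive gates on
#'   `coverage_a` and on the transformed `coverage_b`.
#' @param gc_range Optional inclusive gate on `gc_percent`.
#' @param exponent,scale Passed to [gc_transform_coverage()].
#' @return Object of class `zg_bin`: list with `scaffolds` (the subset,
#'   with a `coverage_b_transformed` column) and `summary` (n scaffolds,
#'   total bp, mean GC, mean coverages).
#' @export
select_bin <- function(scaffolds, cov_a_range, cov_b_t_range,
                       gc_range = NULL, exponent = 9, scale = 1e15) {
  zg_check(cov_a_range[1] <= cov_a_range[2] &&
             cov_b_t_range[1] <= cov_b_t_range[2],
           "gate ranges must be non-empty (low <= high)")
  sc <- scaffolds %>%
    mutate(coverage_b_transformed = gc_transform_coverage(
      .data$coverage_b, .data$gc_percent, exponent, scale
    ))
  keep <- sc$coverage_a >= cov_a_range[1] & sc$coverage_a <= cov_a_range[2] &
    sc$coverage_b_transformed >= cov_b_t_range[1] &
    sc$coverage_b_transformed <= cov_b_t_range[2]
  if (!is.null(gc_range)) {
    zg_check(gc_range[1] <= gc_range[2], "gc gate must be non-empty")
    keep <- keep & sc$gc_percent >= gc_range[1] & sc$gc_percent <= gc_range[2]
  }
  subset <- sc[keep, , drop = FALSE]
  structure(
    list(
      scaffolds = subset,
      gates = list(cov_a = cov_a_range, cov_b_transformed = cov_b_t_range,
                   gc = gc_range, exponent = exponent, scale = scale),
      summary = tibble(
        n_scaffolds = nrow(subset),
        total_bp = sum(subset$length_nt),
        mean_gc = if (nrow(subset)) mean(subset$gc_percent) else NA_real_,
        mean_coverage_a = if (nrow(subset)) mean(subset$coverage_a) else NA_real_,
        mean_coverage_b = if (nrow(subset)) mean(subset$coverage_b) else NA_real_
      )
    ),
    class = "zg_bin"
  )
}

#' Homology annotation call
#'
#' Tiered identity/coverage thresholds for calling a protein a homolog of a
#' database hit: a true homolog needs >= 40 percent amino acid identity
#' over >= 80 percent of the sequence to a curated source (curated
#' database, curated annotation, or the literature); a putative homolog
#' needs >= 25 percent identity over >= 80 percent coverage to any source.
#' Thresholds are inclusive.  Synteny (operon membership) counts as
#' additional support and promotes a putative call to true.
#'
#' @param percent_identity Amino acid identity, 0-100 (vectorized).
#' @param percent_query_coverage Query coverage, 0-100 (vectorized).
#' @param evidence_tier One of `"curated_db"`, `"curated_annotation"`,
#'   `"literature"`, `"general_db"`.
#' @param synteny_support Logical; promotes putative to true.
#' @return Character vector: `"true_homolog"`, `"putative_homolog"` or
#'   `"no_call"`.
#' @export
#' @examples
#' call_homology(40, 80, "curated_db")     # true_homolog
#' call_homology(25, 80, "general_db")     # putative_homolog
#' call_homology(50, 79.9, "curated_db")   # no_call
call_homology <- function(percent_identity, percent_query_coverage,
                          evidence_tier = "general_db",
                          synteny_support = FALSE) {
  tiers <- c("curated_db", "curated_annotation", "literature", "general_db")
  zg_check(all(evidence_tier %in% tiers), "unknown evidence tier")
  zg_check(all(percent_identity >= 0 & percent_identity <= 100) &&
             all(percent_query_coverage >= 0 & percent_query_coverage <= 100),
           "percentages must lie in [0, 100]")
  n <- max(length(percent_identity), length(percent_query_coverage),
           length(evidence_tier))
  pid <- rep_len(percent_identity, n)
  cov <- rep_len(percent_query_coverage, n)
  tier <- rep_len(evidence_tier, n)
  syn <- rep_len(synteny_support, n)

  curated <- tier %in% c("curated_db", "curated_annotation", "literature")
  true_h <- pid >= 40 & cov >= 80 & curated
  putative <- !true_h & pid >= 25 & cov >= 80
  true_h <- true_h | (putative & syn)
  putative <- putative & !true_h
  dplyr::case_when(true_h ~ "true_homolog",
                   putative ~ "putative_homolog",
                   TRUE ~ "no_call")
}

#' Annotate a homology hit table
#'
#' Applies [call_homology()] row-wise to a hit table.
#'
#' @param hits Tibble with `query_id`, `subject_id`, `percent_identity`,
#'   `percent_query_coverage`, `evidence_tier` and optionally
#'   `synteny_support`.
#' @return The table with a `call` column appended.
#' @export
annotate_homologs <- function(hits) {
  syn <- hits[["synteny_support"]] %||% FALSE
  mutate(hits, call = call_homology(
    .data$percent_identity, .data$percent_query_coverage,
    .data$evidence_tier, syn
  ))
}

#' rrn-corrected population quantification
#'
#' 16S rRNA gene copies overestimate cell numbers because genomes carry
#' multiple rrn operons; dividing by the genus-average copy number (9.3 per
#' genome by default) yields cells, and relative abundance follows against
#' a total community cell count.
#'
#' @param copies_per_cm3 16S rRNA gene copies per cm^3 (> 0).
#' @param rrn_per_genome rrn operons per genome (> 0, default 9.3).
#' @param total_community_cells Optional total cells per cm^3 (> 0).
#' @return Tibble `(copies_per_cm3, rrn_per_genome, cells_per_cm3,
#'   relative_abundance_percent)`.
#' @export
#' @examples
#' rrn_correct_relative_abundance(1.2e6, 9.3, 1.2e6 / 9.3 / 0.00018)
rrn_correct_relative_abundance <- function(copies_per_cm3,
                                           rrn_per_genome = 9.3,
                                           total_community_cells = NULL) {
  zg_check(all(copies_per_cm3 > 0), "`copies_per_cm3` must be > 0")
  zg_check(rrn_per_genome > 0, "`rrn_per_genome` must be > 0")
  cells <- copies_per_cm3 / rrn_per_genome
  rel <- if (is.null(total_community_cells)) {
    NA_real_
  } else {
    zg_check(all(total_community_cells > 0), "`total_community_cells` must be > 0")
    100 * cells / total_community_cells
  }
  tibble(
    copies_per_cm3 = copies_per_cm3,
    rrn_per_genome = rrn_per_genome,
    cells_per_cm3 = cells,
    relative_abundance_percent = rel
  )
}
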