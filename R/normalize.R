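# Normalization of gene x sample fragment counts: FPKM, median-of-ratios
# size factors, a shifted-log variance-stabilizing transform, 0-1 profile
# scaling, per-sample mRNA totals and fold changes vs the no-substrate
# control.

# internal: counts tibble (gene_id + sample columns) -> numeric matrix;
# normalized/transformed profiles may be negative, raw counts may not
counts_matrix <- function(counts, allow_negative = FALSE) {
  zg_check("gene_id" %in% names(counts), "counts must carry a `gene_id` column")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  zg_check(is.numeric(m), "count columns must be numeric")
  if (!allow_negative) {
    zg_check(all(m >= 0, na.rm = TRUE), "counts must be non-negative")
  }
  rownames(m) <- counts$gene_id
  m
}

matrix_to_tbl <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

#' FPKM normalization
#'
#' Fragments per kilobase of gene per million total fragments:
#' `FPKM_ij = K_ij / ((length_nt_i/1000) * (N_j/1e6))`.  The depth
#' denominator `N_j` is either the total fragments mapped to the focal
#' genome's CDS (`denominator = "focal"`, the default: quantities compared
#' within the genome) or the whole metatranscriptome library size
#' (`denominator = "library"`, required for cross-sample activity totals
#' and percent-of-all-transcripts summaries), supplied via `depths`.
#'
#' @param counts Count tibble (`gene_id` + one numeric column per sample).
#' @param catalog Gene catalog with `gene_id` and `length_nt`.
#' @param denominator `"focal"` or `"library"`.
#' @param depths Named per-sample library sizes (total fragments), required
#'   when `denominator = "library"`.
#' @return FPKM tibble with the same shape as `counts`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' catalog <- tibble::tibble(gene_id = "g1", length_nt = 1000)
#' compute_fpkm(counts, catalog, denominator = "library",
#'              depths = c(s1 = 1e6))  # FPKM = 10
compute_fpkm <- function(counts, catalog,
                         denominator = c("focal", "library"),
                         depths = NULL) {
  denominator <- match.arg(denominator)
  m <- counts_matrix(counts)
  idx <- match(rownames(m), catalog$gene_id)
  zg_check(!anyNA(idx), "all count genes must be present in the catalog")
  len_kb <- catalog$length_nt[idx] / 1000
  zg_check(all(len_kb > 0), "catalog gene lengths must be positive")

  if (denominator == "focal") {
    N <- colSums(m)
  } else {
    zg_check(!is.null(depths), "`depths` is required for denominator = \"library\"")
    zg_check(all(colnames(m) %in% names(depths)),
             "`depths` must name every sample")
    N <- depths[colnames(m)]
  }
  zg_check(all(N > 0), "zero-depth sample: every sample needs total fragments > 0")

  fpkm <- sweep(m / len_kb, 2, N / 1e6, "/")
  matrix_to_tbl(fpkm)
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors s_j computed as the median, over reference genes,
#' of the ratio of the sample's count to the gene's across-sample geometric
#' mean.  Genes with a zero in any sample are excluded from the reference
#' set; if no gene is positive everywhere, a pseudocount of 1 is added to
#' form the reference (with a warning).  Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Count tibble.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    warn("no gene has positive counts in every sample; using a +1 pseudo-reference")
    m <- m + 1
    keep <- rep(TRUE, nrow(m))
  }
  ref <- m[keep, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  s <- apply(ref, 2, function(col) exp(median(log(col) - log_geo)))
  s <- s / exp(mean(log(s)))
  zg_check(all(s > 0) && all(is.finite(s)), "size factors must be positive and finite")
  s
}

#' Shifted-log variance stabilization
#'
#' `v_ij = log2(K_ij / s_j + pseudocount)`: a monotone shifted-log
#' transform of size-factor-normalized counts, used before Pearson
#' correlation and response-group clustering.  This is a deliberately
#' simple, exactly testable stabilizer; see the methods vignette for why it
#' stands in for regularized-log transforms.
#'
#' @param counts Count tibble.
#' @param size_factors Positive per-sample factors (default
#'   [median_ratio_size_factors()]).
#' @param pseudocount Positive shift, default 1.
#' @return Tibble of variance-stabilized values, same shape as `counts`.
#' @export
variance_stabilize <- function(counts,
                               size_factors = median_ratio_size_factors(counts),
                               pseudocount = 1) {
  zg_check(pseudocount > 0, "`pseudocount` must be > 0")
  m <- counts_matrix(counts)
  zg_check(all(size_factors > 0), "size factors must be > 0")
  s <- size_factors[colnames(m)]
  zg_check(!anyNA(s), "size factors must name every sample")
  matrix_to_tbl(log2(sweep(m, 2, s, "/") + pseudocount))
}

#' Scale a vector to the unit interval
#'
#' `(x - min(x)) / max(x - min(x))`, the per-gene 0-1 scaling used to
#' overlay expression profiles of genes with very different absolute
#' levels.  A constant vector maps to all zeros by convention.
#'
#' @param x Finite numeric vector, length >= 1.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' scale_unit_interval(c(2, 4, 6))  # 0 0.5 1
scale_unit_interval <- function(x) {
  zg_check(length(x) >= 1, "empty vector")
  zg_check(all(is.finite(x)), "non-finite input")
  shifted <- x - min(x)
  mx <- max(shifted)
  if (mx == 0) return(rep(0, length(x)))
  shifted / mx
}

#' Per-sample total mRNA
#'
#' Column sums of a (normalized) expression tibble over a gene subset; the
#' default subset is all genes, i.e. the focal genome's total relative mRNA
#' signal per sample.
#'
#' @param values Expression tibble (`gene_id` + sample columns), typically
#'   FPKM.
#' @param gene_subset Optional character vector of gene ids.
#' @return Named numeric vector of per-sample totals, in sample order.
#' @export
total_mrna <- function(values, gene_subset = NULL) {
  m <- counts_matrix(values, allow_negative = TRUE)
  if (!is.null(gene_subset)) {
    zg_check(length(gene_subset) > 0, "empty gene subset")
    zg_check(all(gene_subset %in% rownames(m)),
             "gene subset contains ids absent from the matrix")
    m <- m[gene_subset, , drop = FALSE]
  }
  colSums(m)
}

#' Fold change of totals versus the no-substrate control
#'
#' For one incubation day, the ratio of the replicate-mean total mRNA of
#' each treatment to the replicate-mean of the control condition
#' (no substrate, sulfate-amended by default).
#'
#' @param totals Named per-sample totals ([total_mrna()]).
#' @param design Sample design tibble.
#' @param day Incubation day to compare at.
#' @param control Length-2 character `(substrate, sulfate)` of the control.
#' @return Tibble `(substrate, sulfate, day, n_replicates, mean_total,
#'   fold)` for every non-control condition present at `day`.
#' @export
fold_change_vs_control <- function(totals, design, day = 36,
                                   control = c("none", "plusS")) {
  df <- design %>%
    filter(.data$day == !!day) %>%
    mutate(total = unname(totals[.data$sample_id]))
  zg_check(!anyNA(df$total), "totals must cover every design sample at `day`")
  ctrl <- df %>% filter(.data$substrate == control[1], .data$sulfate == control[2])
  zg_check(nrow(ctrl) >= 1, "control condition absent at the requested day")
  ctrl_mean <- mean(ctrl$total)
  zg_check(ctrl_mean > 0, "control mean total is zero")
  df %>%
    group_by(.data$substrate, .data$sulfate, .data$day) %>%
    summarise(
      n_replicates = dplyr::n(),
      mean_total = mean(.data$total),
      .groups = "drop"
    ) %>%
    mutate(fold = .data$mean_total / ctrl_mean) %>%
    filter(!(.data$substrate == control[1] & .data$sulfate == control[2]))
}
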