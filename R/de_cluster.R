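# Pairwise differential expression (negative-binomial moment/Wald test)
# between day-36 sulfate-stimulated treatments, and response-group
# clustering of the significant genes in 1 - Pearson correlation distance.

#' Negative-binomial moment/Wald differential expression
#'
#' A deliberately transparent two-group count test: counts are divided by
#' size factors, the per-gene log2 fold change is the ratio of group means
#' with a pseudocount of 0.5 on each side, a single per-gene NB dispersion
#' is estimated by the method of moments pooled across both groups (floored
#' at 1e-8), the standard error comes from the delta method
#' `Var(log2 m) = Var(m) / (m^2 ln(2)^2)` with `Var(K/s) = mu + phi mu^2`,
#' and the two-sided p value refers the Wald statistic LFC/SE to a t
#' distribution on `n_A + n_B` degrees of freedom, followed by BH
#' adjustment over all tested genes.  The reference matters at 2-3
#' replicates per group: the asymptotic normal is badly anti-conservative
#' (the dispersion estimate is noisy), while t on the residual
#' `n_A + n_B - 2` df over-corrects because part of the NB variance (the
#' Poisson term) is pinned by the estimated means rather than the
#' residuals; `n_A + n_B` df matches the statistic's sampling distribution
#' in calibration simulations (see the methods vignette).  Genes with zero
#' counts in every compared sample are dropped before testing.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param size_factors Named positive per-sample factors; default computed
#'   from the compared samples only.
#' @param samples_a,samples_b Disjoint character vectors of sample ids,
#'   each with >= 2 replicates.  The fold change is A over B.
#' @param group_labels Length-2 labels recorded in the output.
#' @return Tibble of class `zg_de`: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `standard_error`, `p_raw`, `p_adj`, `group_a`,
#'   `group_b`.
#' @export
nb_moment_de <- function(counts, samples_a, samples_b,
                         size_factors = NULL,
                         group_labels = c("A", "B")) {
  m <- counts_matrix(counts)
  zg_check(length(intersect(samples_a, samples_b)) == 0,
           "groups must be disjoint")
  zg_check(length(samples_a) >= 2 && length(samples_b) >= 2,
           "need at least 2 replicates per group")
  zg_check(all(c(samples_a, samples_b) %in% colnames(m)),
           "unknown sample id in group definition")
  use <- c(samples_a, samples_b)
  if (is.null(size_factors)) {
    size_factors <- median_ratio_size_factors(
      counts[c("gene_id", use)]
    )
  }
  s <- size_factors[use]
  zg_check(!anyNA(s) && all(s > 0), "size factors must be positive for all samples")

  norm <- sweep(m[, use, drop = FALSE], 2, s, "/")
  a <- norm[, samples_a, drop = FALSE]
  b <- norm[, samples_b, drop = FALSE]

  keep <- rowSums(m[, use, drop = FALSE]) > 0
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)

  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)

  # pooled method-of-moments dispersion: Var = mu + phi mu^2 within group
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  pooled_mu <- (na * ma + nb * mb) / (na + nb)
  phi <- pmax((pooled_var - pooled_mu) / pooled_mu^2, 1e-8)
  phi[!is.finite(phi)] <- 1e-8

  ma_p <- ma + 0.5
  mb_p <- mb + 0.5
  lfc <- log2(ma_p / mb_p)
  var_ma <- (ma_p + phi * ma_p^2) / na
  var_mb <- (mb_p + phi * mb_p^2) / nb
  se <- sqrt(var_ma / ma_p^2 + var_mb / mb_p^2) / log(2)
  z <- lfc / se
  p <- 2 * pt(-abs(z), df = na + nb)

  out <- tibble(
    gene_id = rownames(a),
    base_mean = unname(pooled_mu),
    log2_fold_change = unname(lfc),
    standard_error = unname(se),
    p_raw = unname(p),
    p_adj = benjamini_hochberg(unname(p)),
    group_a = group_labels[1],
    group_b = group_labels[2]
  )
  class(out) <- c("zg_de", class(out))
  out
}

#' All pairwise day-36 comparisons
#'
#' Runs [nb_moment_de()] for every pair of treatments at one incubation day
#' within one sulfate regime — by default each substrate against the
#' no-substrate control and, optionally, against each other — and stacks
#' the per-comparison tables.  Treatments in which every gene has zero
#' counts are skipped (too few transcripts to test).
#'
#' @param counts Count tibble.
#' @param design Sample design.
#' @param day Incubation day (default 36).
#' @param sulfate Sulfate regime compared within (default `"plusS"`).
#' @param comparisons `"vs_control"` or `"all_pairs"`.
#' @param control Substrate considered the control.
#' @param alpha FDR level used by downstream cluster gating.
#' @return Tibble of class `zg_de` with an extra `comparison` column.
#' @export
de_pairwise <- function(counts, design, day = 36, sulfate = "plusS",
                        comparisons = c("vs_control", "all_pairs"),
                        control = "none", alpha = 0.05) {
  comparisons <- match.arg(comparisons)
  des <- design %>% filter(.data$day == !!day, .data$sulfate == !!sulfate)
  zg_check(nrow(des) > 0, "no samples at the requested day / sulfate regime")
  subs <- unique(des$substrate)
  ids <- function(sub) des$sample_id[des$substrate == sub]
  m <- counts_matrix(counts)
  nonzero <- vapply(subs, function(sub) sum(m[, ids(sub), drop = FALSE]) > 0,
                    logical(1))
  subs <- subs[nonzero]

  pairs <- if (comparisons == "vs_control") {
    zg_check(control %in% subs, "control treatment absent or all-zero")
    tibble(a = setdiff(subs, control), b = control)
  } else {
    cmb <- utils::combn(subs, 2)
    tibble(a = cmb[1, ], b = cmb[2, ])
  }
  out <- purrr::pmap_dfr(pairs, function(a, b) {
    nb_moment_de(counts, ids(a), ids(b), group_labels = c(a, b)) %>%
      mutate(comparison = paste0(a, "_vs_", b))
  })
  class(out) <- c("zg_de", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Correlation distance between gene profiles
#'
#' `d = 1 - r` with r the pairwise Pearson correlation of (variance
#' stabilized) expression rows; d lies in \[0, 2\], is symmetric, and has a
#' zero diagonal.
#'
#' @param values Expression tibble (`gene_id` + sample columns); every gene
#'   row must be non-constant.
#' @return A symmetric numeric matrix with gene ids as dimnames.
#' @export
pearson_distance <- function(values) {
  m <- counts_matrix(values, allow_negative = TRUE)
  zg_check(nrow(m) >= 2, "need at least 2 genes")
  sds <- apply(m, 1, sd)
  zg_check(all(sds > 0), "constant gene row: correlation distance undefined")
  d <- 1 - cor(t(m))
  d[d < 0] <- 0  # clip -1e-16-scale rounding
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (stats::hclust) of a symmetric distance matrix,
#' average linkage by default.
#'
#' @param distance Symmetric distance matrix (e.g. [pearson_distance()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(distance,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  zg_check(is.matrix(distance) && nrow(distance) == ncol(distance),
           "`distance` must be a square matrix")
  zg_check(!anyNA(distance), "NaN/NA distances")
  zg_check(max(abs(distance - t(distance))) < 1e-8, "non-symmetric distance matrix")
  hclust(as.dist(distance), method = linkage)
}

#' Cut a dendrogram into response groups
#'
#' Deterministic tree cut by group count `k` or merge `height`
#' (stats::cutree).
#'
#' @param tree An `hclust` tree.
#' @param k Number of groups (1..n), or
#' @param height Cut height (>= 0); exactly one of `k`/`height`.
#' @return Tibble `(gene_id, cluster_id, linkage_height)` where
#'   `linkage_height` is the height at which the gene's cluster last merged
#'   below the cut.
#' @export
cut_clusters <- function(tree, k = NULL, height = NULL) {
  zg_check(inherits(tree, "hclust"), "`tree` must be an hclust object")
  zg_check(xor(is.null(k), is.null(height)), "give exactly one of `k` or `height`")
  n <- length(tree$labels)
  if (!is.null(k)) {
    zg_check(k >= 1 && k <= n, "`k` out of range")
    cl <- cutree(tree, k = k)
  } else {
    zg_check(height >= 0, "`height` must be >= 0")
    cl <- cutree(tree, h = height)
  }
  tibble(
    gene_id = names(cl),
    cluster_id = as.integer(cl),
    linkage_height = cluster_merge_height(tree, cl)
  )
}

# height of the last merge inside each gene's cluster (0 for singletons)
cluster_merge_height <- function(tree, cl) {
  heights <- setNames(rep(0, length(cl)), names(cl))
  leaf_sets <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    get_set <- function(j) if (j < 0) -j else leaf_sets[[j]]
    set <- c(get_set(tree$merge[i, 1]), get_set(tree$merge[i, 2]))
    leaf_sets[[i]] <- set
    labs <- tree$labels[set]
    same <- length(unique(cl[labs])) == 1
    if (same) heights[labs] <- pmax(heights[labs], tree$height[i])
  }
  unname(heights[names(cl)])
}

#' Significant genes across pairwise comparisons
#'
#' Gene ids significant (`p_adj < alpha`) in at least one comparison of a
#' stacked [de_pairwise()] table — the set that enters response-group
#' clustering.
#'
#' @param de A `zg_de` tibble.
#' @param alpha FDR level (default from the table's attribute, else 0.05).
#' @return Character vector of gene ids.
#' @export
significant_genes <- function(de, alpha = NULL) {
  alpha <- alpha %||% attr(de, "alpha") %||% 0.05
  de %>%
    filter(!is.na(.data$p_adj), .data$p_adj < alpha) %>%
    pull("gene_id") %>%
    unique()
}

#' Export a gene dendrogram as Newick
#'
#' @param tree An `hclust` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
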