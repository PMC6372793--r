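# Activity-correlation screening: per-gene Spearman rank correlation of
# normalized transcript counts against the total mRNA signal, with
# Benjamini-Hochberg FDR control, functional-category summaries and the
# zero-growth population-state call.

# all permutations of 1..n as an (n! x n) matrix; n <= 9
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * nrow(sub) + 1L):(k * nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Pearson correlation of two rank vectors (midranks handle ties)
rank_cor <- function(rx, ry) {
  sx <- rx - mean(rx)
  sy <- ry - mean(ry)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Spearman's rho computed as the Pearson correlation of midranks.  The
#' two-sided p value comes from exact enumeration of all n! rank
#' permutations for n < 10 and from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length n >= 3, each with at least
#'   two distinct values.
#' @return List with `rho`, `p_raw`, `n_pairs`, `method`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho  # 0.6
spearman_rho <- function(x, y) {
  zg_check(length(x) == length(y), "`x` and `y` must have equal length")
  n <- length(x)
  zg_check(n >= 3, "need at least 3 pairs")
  zg_check(length(unique(x)) > 1 && length(unique(y)) > 1,
           "rho undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- rank_cor(rx, ry)
  if (n < 10) {
    pm <- perms(n)
    null_rho <- apply(pm, 1, function(idx) rank_cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- spearman_p_t(rho, n)
    method <- "t approximation"
  }
  list(rho = rho, p_raw = p, n_pairs = n, method = method)
}

# vectorized t-approximation p value
spearman_p_t <- function(rho, n) {
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical FDR step-up: sort p ascending, `p_(i) * m / i`, take the
#' cumulative minimum from the largest rank down, cap at 1, and return in
#' the original input order.
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA allowed; NAs are kept
#'   out of the family and returned as NA).
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
benjamini_hochberg <- function(p) {
  ok <- !is.na(p)
  zg_check(all(p[ok] >= 0 & p[ok] <= 1), "p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv)
    adj <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
    tmp <- rep(NA_real_, m)
    tmp[o] <- adj
    out[ok] <- tmp
  }
  out
}

#' Activity-correlation screen
#'
#' For every gene, Spearman's rank correlation of its normalized expression
#' (FPKM) across all treatments and replicates against the per-sample total
#' mRNA signal, with BH-FDR adjustment over the single family of all
#' non-constant genes.  Genes with constant expression (including all-zero
#' rows) get `rho = NA` and are excluded from the FDR family.
#'
#' By default each gene is correlated against the totals minus its own
#' contribution (`leave_self_out = TRUE`).  Correlating a gene against a
#' sum that contains it makes highly expressed genes correlate with their
#' own noise, so a gene carrying a large share of the total mRNA shows a
#' strong "activity" correlation even in the complete absence of
#' coordinated expression; leaving the gene out restores validity of the
#' null p values while changing rho negligibly for all ordinary genes.
#'
#' @param fpkm Expression tibble (`gene_id` + sample columns).
#' @param totals Named per-sample totals ([total_mrna()]) over the same
#'   expression table and samples.
#' @param catalog Gene catalog carrying `category` labels.
#' @param alpha Significance level applied downstream (stored, default 0.05).
#' @param leave_self_out Subtract each gene's own row from the totals
#'   before correlating (default TRUE).
#' @return Object of class `zg_activity_screen`: list with `records`
#'   (tibble: gene_id, category, rho, p_raw, p_adj, n_pairs), `alpha`,
#'   `n_samples`.
#' @export
activity_correlations <- function(fpkm, totals, catalog, alpha = 0.05,
                                  leave_self_out = TRUE) {
  m <- counts_matrix(fpkm)
  zg_check(ncol(m) >= 3, "need at least 3 samples")
  zg_check(all(colnames(m) %in% names(totals)),
           "`totals` must name every sample")
  tot <- totals[colnames(m)]
  n <- ncol(m)

  constant <- apply(m, 1, function(r) length(unique(r)) == 1)
  rho <- rep(NA_real_, nrow(m))
  p_raw <- rep(NA_real_, nrow(m))
  live <- which(!constant)
  if (length(live)) {
    target <- function(i) if (leave_self_out) tot - m[i, ] else tot
    if (n >= 10) {
      ranks <- t(apply(m[live, , drop = FALSE], 1, rank))
      rs <- ranks - rowMeans(ranks)
      tmat <- t(vapply(live, function(i) rank(target(i)), numeric(n)))
      ts <- tmat - rowMeans(tmat)
      rho[live] <- rowSums(rs * ts) / sqrt(rowSums(rs^2) * rowSums(ts^2))
      p_raw[live] <- spearman_p_t(rho[live], n)
    } else {
      for (i in live) {
        res <- spearman_rho(m[i, ], target(i))
        rho[i] <- res$rho
        p_raw[i] <- res$p_raw
      }
    }
  }
  # a zero-variance leave-self-out target (gene identical to the totals)
  # leaves rho undefined
  undef <- !is.finite(rho)
  rho[undef] <- NA_real_
  p_raw[undef] <- NA_real_
  idx <- match(rownames(m), catalog$gene_id)
  records <- tibble(
    gene_id = rownames(m),
    category = if (anyNA(idx)) NA_character_ else catalog$category[idx],
    rho = rho,
    p_raw = p_raw,
    p_adj = benjamini_hochberg(p_raw),
    n_pairs = n
  )
  structure(
    list(records = records, alpha = alpha, n_samples = n),
    class = "zg_activity_screen"
  )
}

#' Functional-category correlation summaries
#'
#' Mean and SD of Spearman's rho per functional category, by default over
#' the genes significant after FDR adjustment (`p_adj < alpha`), matching
#' how category-level activity correlations are usually reported; set
#' `significant_only = FALSE` to average over all genes with a defined rho.
#'
#' @param screen A `zg_activity_screen` or its `records` tibble.
#' @param categories Categories to summarise (default: all present).
#' @param alpha Significance level, default taken from the screen.
#' @param significant_only Restrict the mean/SD to significant genes.
#' @return Tibble `(category, mean_rho, sd_rho, n_significant, n_total)`;
#'   the single-gene SD is 0 by convention.
#' @export
category_summary <- function(screen, categories = NULL, alpha = NULL,
                             significant_only = TRUE) {
  records <- if (inherits(screen, "zg_activity_screen")) screen$records else screen
  if (is.null(alpha)) {
    alpha <- if (inherits(screen, "zg_activity_screen")) screen$alpha else 0.05
  }
  zg_check(all(stats::na.omit(records$category) %in% gene_categories()),
           "unknown category label in records")
  if (is.null(categories)) {
    categories <- intersect(gene_categories(), unique(records$category))
  } else {
    zg_check(all(categories %in% gene_categories()), "unknown category label")
  }
  sd0 <- function(x) if (length(x) <= 1) 0 else sd(x)
  purrr::map_dfr(categories, function(catg) {
    rows <- records %>% filter(.data$category == catg)
    sig <- rows %>% filter(!is.na(.data$p_adj) & .data$p_adj < alpha)
    used <- if (significant_only) sig else filter(rows, !is.na(.data$rho))
    tibble(
      category = catg,
      mean_rho = if (nrow(used)) mean(used$rho) else NA_real_,
      sd_rho = if (nrow(used)) sd0(used$rho) else NA_real_,
      n_used = nrow(used),
      n_significant = nrow(sig),
      n_total = nrow(rows)
    )
  })
}

#' Classify the population state
#'
#' Combines three lines of evidence into one call:
#' \itemize{
#'   \item the trend of the qPCR population series: ordinary least squares
#'     on log10 copies versus day with a t-based 95 percent confidence
#'     interval on the slope;
#'   \item the activity fold change of total mRNA versus the control;
#'   \item the gap between the mean activity-category rho and the mean
#'     growth-category rho from the correlation screen.
#' }
#' The slope CI is converted to a CI on the total fold change over the
#' observed day span and compared against a minimal biologically meaningful
#' increase, `growth_fold_min` (default 2, a population doubling): the
#' population is called growing when the CI guarantees at least that
#' increase, and stable when the CI rules it out.  This equivalence-style
#' rule, rather than testing the point null slope = 0, keeps a genuinely
#' stable but noisily measured population from being misclassified as
#' growing on a statistically significant yet negligible drift (see the
#' methods vignette).  The state is `active_zero_growth` when the
#' population is stable while the activity fold is at least `fold_min` and
#' the rho gap at least `gap_min`; `growth` when the population grows;
#' otherwise `baseline`.
#'
#' @param population_series qPCR tibble with `day` and `copies_per_cm3`
#'   (>= 3 distinct days).
#' @param totals_fold Either the tibble from [fold_change_vs_control()] (its
#'   maximum fold is used) or a single fold value.
#' @param summaries Category summary tibble ([category_summary()]) covering
#'   at least one activity and one growth category; use
#'   `significant_only = FALSE` summaries so null categories keep a defined
#'   mean.
#' @param fold_min,gap_min Decision thresholds (defaults 10 and 0.2).
#' @param growth_fold_min Minimal population increase over the observed day
#'   span that counts as growth (default 2).
#' @param conf_level Confidence level of the slope CI.
#' @return Object of class `zg_population_state`: list with `state` and an
#'   `evidence` tibble (slope, CI, fold, rho gap, thresholds).
#' @export
classify_population_state <- function(population_series, totals_fold,
                                      summaries, fold_min = 10,
                                      gap_min = 0.2, growth_fold_min = 2,
                                      conf_level = 0.95) {
  zg_check(length(unique(population_series$day)) >= 3,
           "population series must span at least 3 time points")
  zg_check(growth_fold_min > 1, "`growth_fold_min` must exceed 1")
  fit <- lm(log10(copies_per_cm3) ~ day, data = population_series)
  slope <- unname(coef(fit)["day"])
  ci <- confint(fit, "day", level = conf_level)
  span <- diff(range(population_series$day))
  log_gmin <- log10(growth_fold_min)

  fold <- if (is.data.frame(totals_fold)) max(totals_fold$fold) else totals_fold
  zg_check(is.finite(fold) && fold > 0, "`totals_fold` must be positive")

  act <- summaries %>% filter(.data$category %in% activity_categories(),
                              !is.na(.data$mean_rho))
  grw <- summaries %>% filter(.data$category %in% growth_categories(),
                              !is.na(.data$mean_rho))
  zg_check(nrow(act) >= 1 && nrow(grw) >= 1,
           "summaries must cover at least one activity and one growth category")
  wmean <- function(d) stats::weighted.mean(d$mean_rho, pmax(d$n_used, 1))
  rho_gap <- wmean(act) - wmean(grw)

  growing <- ci[1] * span >= log_gmin
  stable <- ci[2] * span < log_gmin
  state <- if (growing) {
    "growth"
  } else if (stable && fold >= fold_min && rho_gap >= gap_min) {
    "active_zero_growth"
  } else {
    "baseline"
  }
  structure(
    list(
      state = state,
      evidence = tibble(
        population_trend_slope = slope,
        slope_ci_low = ci[1],
        slope_ci_high = ci[2],
        day_span = span,
        activity_fold = fold,
        rho_gap = rho_gap,
        fold_min = fold_min,
        gap_min = gap_min,
        growth_fold_min = growth_fold_min
      )
    ),
    class = "zg_population_state"
  )
}

#' @export
print.zg_activity_screen <- function(x, ...) {
  n_sig <- sum(x$records$p_adj < x$alpha, na.rm = TRUE)
  cat("Activity-correlation screen:", nrow(x$records), "genes,",
      x$n_samples, "samples;", n_sig, "significant at FDR", x$alpha, "\n")
  invisible(x)
}

#' @export
print.zg_population_state <- function(x, ...) {
  cat("Population state:", x$state, "\n")
  print(as.data.frame(x$evidence), row.names = FALSE)
  invisible(x)
}
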