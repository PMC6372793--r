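# Spearman screening, BH-FDR, category summaries and the population-state
# call.

test_that("spearman rho matches hand values and exact enumeration", {
  expect_equal(spearman_rho(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  r3 <- spearman_rho(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r3$rho, -1)
  expect_equal(r3$p_raw, 1 / 3)  # 2 of 3! permutations reach |rho| = 1

  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "3 pairs")
})

test_that("spearman agrees with cor / cor.test as independent oracles", {
  for (i in 1:10) {
    x <- withr::with_seed(i, rnorm(8))
    y <- withr::with_seed(100 + i, rnorm(8))
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-9)
  }
  # t-approximation branch against cor.test's asymptotic p
  for (i in 1:10) {
    x <- withr::with_seed(200 + i, rnorm(25))
    y <- withr::with_seed(300 + i, rnorm(25))
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_raw, ref$p.value, tolerance = 1e-9)
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  for (i in 1:10) {
    x <- withr::with_seed(400 + i, rnorm(15))
    y <- withr::with_seed(500 + i, rnorm(15))
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, base)
    expect_equal(spearman_rho(x, y^3)$rho, base)
    expect_equal(spearman_rho(rank(x), 2 + 5 * y)$rho, base)
  }
})

test_that("BH step-up matches hand computation and p.adjust", {
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  for (i in 1:10) {
    p <- withr::with_seed(600 + i, runif(50)^2)
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
    # adjusted values never fall below the raw ones (up to rounding)
    expect_true(all(benjamini_hochberg(p) >= p - 1e-12))
  }
  # NAs stay out of the family
  p <- c(0.01, NA, 0.02, 0.04)
  expect_equal(benjamini_hochberg(p), c(0.03, NA, 0.03, 0.04))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the screen handles self-rows, constant rows and tiny inputs", {
  catal <- toy_catalog(c(g1 = 1000L, g2 = 1000L, g3 = 1000L))
  m <- matrix(c(1, 2, 3, 4, 5,
                0, 0, 0, 0, 0,
                5, 1, 4, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:5)))
  tb <- counts_tbl(m)
  # a gene identical to the totals vector correlates perfectly when the
  # self-contribution is kept
  tot <- setNames(as.numeric(m[1, ]), colnames(m))
  scr <- activity_correlations(tb, tot, catal, leave_self_out = FALSE)
  expect_equal(scr$records$rho[scr$records$gene_id == "g1"], 1)
  # the all-zero gene is flagged NA and excluded from the family
  expect_true(is.na(scr$records$rho[scr$records$gene_id == "g2"]))
  expect_true(is.na(scr$records$p_adj[scr$records$gene_id == "g2"]))

  two <- tb[, 1:3]
  expect_error(activity_correlations(two, tot[1:2], catal), "3 samples")
})

test_that("category summaries average rho with the n = 1 sd convention", {
  rec <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    category = c("ribosomal", "ribosomal", "ribosomal", "growth_division"),
    rho = c(0.7, 0.8, 0.9, 0.5),
    p_raw = c(0.001, 0.001, 0.001, 0.01),
    p_adj = c(0.004, 0.004, 0.004, 0.04),
    n_pairs = 10
  )
  cs <- category_summary(rec, alpha = 0.05)
  rib <- cs[cs$category == "ribosomal", ]
  expect_equal(rib$mean_rho, 0.8)
  expect_equal(rib$sd_rho, 0.1)
  expect_equal(rib$n_significant, 3L)
  one <- cs[cs$category == "growth_division", ]
  expect_equal(one$mean_rho, 0.5)
  expect_equal(one$sd_rho, 0)  # single-gene convention

  # alpha gates the significant set
  cs2 <- category_summary(rec, alpha = 0.01)
  expect_equal(cs2$n_significant[cs2$category == "growth_division"], 0L)

  bad <- dplyr::mutate(rec, category = "mystery")
  expect_error(category_summary(bad), "unknown category")
})

test_that("population state distinguishes zero growth, growth and baseline", {
  summaries <- tibble::tibble(
    category = c("ribosomal", "growth_division"),
    mean_rho = c(0.79, 0.45),
    sd_rho = c(0.07, 0.13),
    n_used = c(72L, 40L),
    n_significant = c(72L, 40L),
    n_total = c(80L, 60L)
  )
  flat <- tidyr::expand_grid(day = c(0, 5, 8, 15, 26, 36, 50), replicate = 1:3) |>
    dplyr::mutate(copies_per_cm3 = 1.2e6 * withr::with_seed(
      7, rlnorm(dplyr::n(), 0, 0.2)
    ))

  # stable population + 80-fold activity + rho gap 0.34 -> zero growth
  st <- classify_population_state(flat, 80, summaries)
  expect_equal(st$state, "active_zero_growth")
  expect_equal(st$evidence$rho_gap, 0.34, tolerance = 1e-9)

  # a 13.6-fold rise by day 50 is growth
  rising <- dplyr::mutate(flat,
    copies_per_cm3 = copies_per_cm3 * 13.6^(day / 50))
  expect_equal(classify_population_state(rising, 80, summaries)$state,
               "growth")

  # no activity response -> baseline even with a stable population
  expect_equal(classify_population_state(flat, 1, summaries)$state,
               "baseline")

  short <- dplyr::filter(flat, day < 6)
  expect_error(classify_population_state(short, 80, summaries),
               "3 time points")
})

test_that("classification ignores gene order and replicate labels", {
  catal <- generate_gene_catalog(300, seed = 51)
  des <- default_design(days = c(8, 36), sulfate = "plusS")
  sim <- simulate_counts(catal, des, sim_params(), seed = 52)
  depths <- setNames(sim$design$library_depth, sim$design$sample_id)
  fpkm <- compute_fpkm(sim$counts, catal, "library", depths)
  scr1 <- activity_correlations(fpkm, total_mrna(fpkm), catal)

  perm <- withr::with_seed(1, sample(nrow(fpkm)))
  fpkm_p <- fpkm[perm, ]
  scr2 <- activity_correlations(fpkm_p, total_mrna(fpkm_p), catal)
  merged <- dplyr::left_join(scr1$records, scr2$records, by = "gene_id")
  expect_equal(merged$rho.x, merged$rho.y)
  expect_equal(merged$p_adj.x, merged$p_adj.y)
})
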