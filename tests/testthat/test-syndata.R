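# Synthetic-data generator: catalogs, negative-binomial counts with planted
# activity coupling, qPCR series.

test_that("gene catalog honours weights, layout invariants and the seed", {
  all_other <- c(other = 1)
  cat1 <- generate_gene_catalog(100, all_other, seed = 3)
  expect_equal(nrow(cat1), 100)
  expect_true(all(cat1$category == "other"))
  expect_silent(validate_catalog(cat1))
  expect_true(all(cat1$length_nt %% 3 == 0))

  # byte-identical under a fixed seed
  expect_identical(generate_gene_catalog(250, seed = 11),
                   generate_gene_catalog(250, seed = 11))
  expect_false(identical(generate_gene_catalog(250, seed = 11),
                         generate_gene_catalog(250, seed = 12)))

  expect_error(generate_gene_catalog(0), "positive")
  expect_error(generate_gene_catalog(10, c(other = 0.9)), "sum to 1")
  expect_error(generate_gene_catalog(10, length_range = c(10, 50)), "10000")
})

test_that("catalog category counts match the genome's COG D/L/M proportions", {
  n <- 6440
  w <- default_category_weights()
  catal <- generate_gene_catalog(n, w, seed = 42)
  counts <- table(catal$category)
  # expected 73 / 280 / 215 within 3 binomial SE
  for (spec in list(c("growth_division", 73), c("growth_replication", 280),
                    c("growth_envelope", 215))) {
    expected <- as.numeric(spec[2])
    se <- sqrt(n * (expected / n) * (1 - expected / n))
    expect_lt(abs(counts[[spec[1]]] - expected), 3 * se)
  }
})

test_that("dispersion-free counts are Poisson around the stated mean", {
  # fixed baselines and depth: all draws share mu = (999/1000) * depth * b
  catal <- generate_gene_catalog(200, c(other = 1), length_range = c(999, 1001),
                                 seed = 5)
  des <- default_design(sulfate = "minusS", days = c(0, 8, 36))
  p <- sim_params(dispersion = 0, baseline_log_mean = log(5e-6),
                  baseline_log_sd = 0, library_size_range = c(2e6, 2e6),
                  coupling_exponent = null_coupling(),
                  baseline_scale = flat_scale())
  sim <- simulate_counts(catal, des, p, seed = 9)
  draws <- as.matrix(sim$counts[-1])
  mu <- 0.999 * 2e6 * 5e-6
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / length(draws)))
  # Poisson: variance equals the mean (within Monte-Carlo error)
  expect_lt(abs(var(as.vector(draws)) / mu - 1), 0.05)
})

test_that("count variance follows Var = mu + phi mu^2", {
  catal <- generate_gene_catalog(300, c(other = 1), length_range = c(999, 1001),
                                 seed = 6)
  des <- default_design(sulfate = "minusS", days = c(0, 8, 36))
  phi <- 0.3
  p <- sim_params(dispersion = phi, baseline_log_mean = log(5e-6),
                  baseline_log_sd = 0, library_size_range = c(2e6, 2e6),
                  coupling_exponent = null_coupling(),
                  baseline_scale = flat_scale())
  sim <- simulate_counts(catal, des, p, seed = 10)
  draws <- as.vector(as.matrix(sim$counts[-1]))  # ~16k iid NB draws
  mu <- 0.999 * 2e6 * 5e-6
  expect_lt(abs(mean(draws) / mu - 1), 0.05)
  expect_lt(abs(var(draws) / (mu + phi * mu^2) - 1), 0.10)
})

test_that("counts are reproducible and reject inconsistent inputs", {
  catal <- generate_gene_catalog(50, seed = 2)
  des <- default_design(days = 36, sulfate = "plusS", replicates = 2)
  s1 <- simulate_counts(catal, des, sim_params(), seed = 4)
  s2 <- simulate_counts(catal, des, sim_params(), seed = 4)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$design$library_depth, s2$design$library_depth)

  # a design condition without an activity factor is an error
  bad <- sim_params()
  bad$activity_factors <- dplyr::filter(bad$activity_factors,
                                        substrate != "butyrate")
  expect_error(simulate_counts(catal, des, bad, seed = 1), "activity factor")
  expect_error(sim_params(dispersion = -1), ">= 0")
})

test_that("planted coupling is recovered by the correlation screen", {
  # gamma = 1 genes track the activity factor; gamma = 0 genes do not
  catal <- generate_gene_catalog(
    600, c(ribosomal = 0.5, growth_replication = 0.5), seed = 21
  )
  des <- default_design(days = c(8, 36), sulfate = "plusS")
  sim <- simulate_counts(catal, des, sim_params(), seed = 22)
  depths <- setNames(sim$design$library_depth, sim$design$sample_id)
  fpkm <- compute_fpkm(sim$counts, catal, "library", depths)
  scr <- activity_correlations(fpkm, total_mrna(fpkm), catal)
  cs <- category_summary(scr, significant_only = FALSE)
  rho_act <- cs$mean_rho[cs$category == "ribosomal"]
  rho_grw <- cs$mean_rho[cs$category == "growth_replication"]
  expect_gte(rho_act, 0.9)
  expect_lt(abs(rho_grw), 0.3)
  expect_gte(rho_act - rho_grw, 0.4)
})

test_that("qPCR series is stable, log-normal and condition-modulated", {
  des <- default_design(days = c(0, 8, 36))
  expect_equal(unique(simulate_qpcr(des, cv = 0)$copies_per_cm3), 1.2e6)

  # geometric mean of 1,000 draws within 2% of the target mean
  many <- tibble::tibble(
    sample_id = as.character(1:1000), substrate = "none",
    sulfate = "plusS", day = 0L, replicate = 1L
  )
  draws <- simulate_qpcr(many, mean_copies = 1.2e6, cv = 0.2, seed = 8)
  expect_lt(abs(exp(mean(log(draws$copies_per_cm3))) / 1.2e6 - 1), 0.02)

  # a 13.6-fold amendment response appears as a 13.6x series mean
  fm <- tibble::tibble(substrate = "butyrate", sulfate = "plusS",
                       day = 50L, fold = 13.6)
  des50 <- default_design(days = c(0, 50))
  q <- simulate_qpcr(des50, cv = 0, fold_map = fm, seed = 1)
  hit <- dplyr::filter(q, substrate == "butyrate",
                       sulfate == "plusS", day == 50)
  base <- dplyr::filter(q, day == 0, substrate == "none",
                        sulfate == "plusS")
  expect_equal(mean(hit$copies_per_cm3) / mean(base$copies_per_cm3), 13.6)

  expect_error(simulate_qpcr(des, mean_copies = -5), "> 0")
})
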