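#' Build a microcosm sample design
#'
#' Full-factorial sample sheet over carbon substrate, sulfate regime,
#' incubation day and replicate, mirroring anoxic peat microcosms amended
#' periodically with low-micromolar substrate doses with or without sulfate.
#' Day 0 denotes the initial soil.
#'
#' @param substrates Character subset of [substrate_levels()].
#' @param sulfate Character subset of [sulfate_levels()].
#' @param days Integer days sampled; the full incubation grid is
#'   `c(0, 5, 8, 15, 26, 36, 50)`.
#' @param replicates Number of replicate microcosms (1-3).
#' @return A tibble with columns `sample_id`, `substrate`, `sulfate`, `day`,
#'   `replicate`.
#' @export
#' @examples
#' default_design(days = c(8, 36), sulfate = "plusS")
default_design <- function(substrates = substrate_levels(),
                           sulfate = sulfate_levels(),
                           days = c(0, 8, 36),
                           replicates = 3L) {
  zg_check(all(substrates %in% substrate_levels()), "unknown substrate level")
  zg_check(all(sulfate %in% sulfate_levels()), "unknown sulfate level")
  zg_check(replicates >= 1 && replicates <= 3, "replicates must be in 1..3")
  design <- tidyr::expand_grid(
    substrate = substrates,
    sulfate = sulfate,
    day = as.integer(days),
    replicate = seq_len(replicates)
  )
  design %>%
    mutate(sample_id = sprintf("%s_%s_d%02d_r%d", .data$substrate,
                               .data$sulfate, .data$day, .data$replicate)) %>%
    select("sample_id", "substrate", "sulfate", "day", "replicate")
}

#' Default per-condition activity factors
#'
#' Multiplicative activity factors a > 0 for each (substrate, sulfate, day)
#' condition.  Defaults encode the observed response: by day 36, focal mRNA
#' totals in sulfate-reducing microcosms were 56-, 80-, 62- and 188-fold
#' higher with acetate, propionate, lactate and butyrate respectively than
#' the no-substrate control, while formate, the no-substrate control and all
#' methanogenic (minusS) incubations stayed at baseline.  Day-8 factors are
#' the geometric midpoint of baseline and the day-36 factor (steady rise).
#'
#' @param day36_folds Named vector of day-36 activity factors for the
#'   sulfate-amended treatments.
#' @return A tibble `(substrate, sulfate, day, activity)`.
#' @export
default_activity_factors <- function(day36_folds = c(
                                       none = 1, formate = 1, acetate = 56,
                                       propionate = 80, lactate = 62,
                                       butyrate = 188
                                     )) {
  grid <- tidyr::expand_grid(
    substrate = substrate_levels(),
    sulfate = sulfate_levels(),
    day = c(0L, 5L, 8L, 15L, 26L, 36L, 50L)
  )
  grid %>%
    mutate(
      a36 = unname(day36_folds[.data$substrate]),
      # geometric interpolation in day toward the day-36 plateau
      activity = dplyr::case_when(
        .data$sulfate == "minusS" ~ 1,
        .data$day == 0L ~ 1,
        .data$day >= 36L ~ .data$a36,
        TRUE ~ .data$a36^(.data$day / 36)
      )
    ) %>%
    select("substrate", "sulfate", "day", "activity")
}

#' Simulation parameters for the count generator
#'
#' Bundles the negative-binomial generator settings.  Counts are drawn as
#' K_ij ~ NB(mu_ij, dispersion phi) with
#' `mu_ij = (length_nt_i/1000) * depth_j * b_i * a_j^gamma(cat_i)`,
#' where `b_i` is a log-normal per-gene baseline (scaled per category so
#' ribosomal and energy-metabolism transcripts dominate the active mRNA
#' pool, as in real transcriptomes), `depth_j` a log-uniform library depth,
#' `a_j` the per-sample activity factor and `gamma` the per-category
#' activity-coupling exponent (1 = fully activity-coupled, 0 = flat).
#'
#' @param dispersion NB dispersion phi >= 0 (Var = mu + phi mu^2);
#'   phi = 0 gives Poisson counts.
#' @param baseline_log_mean,baseline_log_sd Meanlog / sdlog of the
#'   log-normal gene baselines b_i.
#' @param library_size_range Range of per-sample library depths (total
#'   fragments of the whole metatranscriptome), drawn log-uniformly.
#' @param activity_factors Condition-to-activity map as returned by
#'   [default_activity_factors()].
#' @param coupling_exponent Named vector gamma per category, each in \[0, 1\].
#' @param baseline_scale Named per-category multiplier on b_i.
#' @return A list of class `zg_sim_params`.
#' @export
sim_params <- function(dispersion = 0.1,
                       baseline_log_mean = log(5e-7),
                       baseline_log_sd = 1,
                       library_size_range = c(1e6, 1e7),
                       activity_factors = default_activity_factors(),
                       coupling_exponent = default_coupling(),
                       baseline_scale = default_baseline_scale()) {
  zg_check(dispersion >= 0, "`dispersion` must be >= 0")
  zg_check(all(library_size_range > 0) &&
             library_size_range[1] <= library_size_range[2],
           "`library_size_range` must be a positive increasing range")
  zg_check(all(activity_factors$activity > 0), "activity factors must be > 0")
  zg_check(all(coupling_exponent >= 0 & coupling_exponent <= 1),
           "coupling exponents must lie in [0, 1]")
  zg_check(all(coupling_exponent[growth_categories()] <=
                 min(coupling_exponent[c("ribosomal", "central_energy")])),
           "growth categories may not be more activity-coupled than ribosomal/energy")
  structure(
    list(
      dispersion = dispersion,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      library_size_range = library_size_range,
      activity_factors = activity_factors,
      coupling_exponent = coupling_exponent,
      baseline_scale = baseline_scale
    ),
    class = "zg_sim_params"
  )
}

#' @rdname sim_params
#' @details `default_coupling()` couples sulfate-reduction, ribosomal,
#'   central-energy and stress genes fully to activity (gamma = 1) and
#'   leaves growth (COG D/L/M), sporulation, phage-response and `other`
#'   genes flat (gamma = 0): transcriptional activity without growth.
#' @export
default_coupling <- function() {
  g <- setNames(rep(0, length(gene_categories())), gene_categories())
  g[activity_categories()] <- 1
  g
}

#' @rdname sim_params
#' @export
default_baseline_scale <- function() {
  s <- setNames(rep(1, length(gene_categories())), gene_categories())
  s[["ribosomal"]] <- 30
  s[["sulfate_reduction"]] <- 20
  s[["central_energy"]] <- 10
  s[["stress"]] <- 5
  s
}

#' Simulate a gene-by-sample count matrix
#'
#' Draws negative-binomial fragment counts for every catalog gene in every
#' design sample under [sim_params()].  Genes in activity-coupled categories
#' covary with the per-sample activity factor; growth-category genes do not.
#'
#' @param catalog Gene catalog ([generate_gene_catalog()]).
#' @param design Sample design ([default_design()]).
#' @param params A [sim_params()] object.
#' @param seed Integer seed; one RNG stream per call.
#' @return A list of class `zg_sim` with elements `counts` (tibble:
#'   `gene_id` + one integer column per sample), `design` (the design with a
#'   `library_depth` column appended), `catalog`, and `params`.
#' @export
#' @examples
#' cat <- generate_gene_catalog(50, seed = 1)
#' des <- default_design(days = 36, sulfate = "plusS", replicates = 2)
#' sim <- simulate_counts(cat, des, sim_params(), seed = 7)
#' sim$counts[1:3, 1:4]
simulate_counts <- function(catalog, design, params = sim_params(), seed = 1L) {
  validate_catalog(catalog)
  zg_check(nrow(catalog) > 0, "catalog must be non-empty")
  zg_check(inherits(params, "zg_sim_params"), "`params` must come from sim_params()")

  af <- design %>%
    left_join(params$activity_factors, by = c("substrate", "sulfate", "day"))
  zg_check(!anyNA(af$activity),
           "missing activity factor for at least one design condition")

  gamma <- params$coupling_exponent[catalog$category]
  bscale <- params$baseline_scale[catalog$category]
  n_g <- nrow(catalog)
  n_s <- nrow(design)

  withr::with_seed(seed, {
    b <- rlnorm(n_g, params$baseline_log_mean, params$baseline_log_sd) * bscale
    depth <- exp(runif(n_s, log(params$library_size_range[1]),
                       log(params$library_size_range[2])))
    mu <- outer(catalog$length_nt / 1000 * b, depth) *
      outer(gamma, log(af$activity), function(g, la) exp(g * la))
    counts <- if (params$dispersion == 0) {
      matrix(rpois(n_g * n_s, mu), n_g, n_s)
    } else {
      matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / params$dispersion), n_g, n_s)
    }
  })
  colnames(counts) <- design$sample_id
  counts_tbl <- bind_cols(tibble(gene_id = catalog$gene_id), as_tibble(counts))

  structure(
    list(
      counts = counts_tbl,
      design = mutate(design, library_depth = depth),
      catalog = catalog,
      params = params,
      seed = seed
    ),
    class = "zg_sim"
  )
}

#' Simulate a qPCR population series
#'
#' Log-normal 16S rRNA gene copy numbers around a stable mean, optionally
#' modulated per condition/day through `fold_map`.  The default emulates the
#' focal population's stable abundance of 1.2e6 16S rRNA gene copies per
#' cm^3 of soil across all microcosms.
#'
#' @param design Sample design tibble.
#' @param mean_copies Baseline copies per cm^3 (default 1.2e6).
#' @param cv Coefficient of variation of the log-normal noise (sdlog =
#'   `sqrt(log(1 + cv^2))`; the geometric mean equals the target mean).
#' @param fold_map Optional tibble `(substrate, sulfate, day, fold)`
#'   multiplying the baseline; conditions not listed default to fold 1.
#' @param seed Integer seed.
#' @param target `"focal_population"` or `"total_community"`.
#' @return Tibble `(sample_id, substrate, sulfate, day, replicate,
#'   copies_per_cm3, target)`.
#' @export
simulate_qpcr <- function(design, mean_copies = 1.2e6, cv = 0.2,
                          fold_map = NULL, seed = 1L,
                          target = "focal_population") {
  zg_check(mean_copies > 0, "`mean_copies` must be > 0")
  zg_check(cv >= 0, "`cv` must be >= 0")
  out <- design
  if (!is.null(fold_map)) {
    out <- left_join(out, fold_map, by = c("substrate", "sulfate", "day"))
    out$fold[is.na(out$fold)] <- 1
  } else {
    out$fold <- 1
  }
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    noise <- rlnorm(nrow(out), meanlog = 0, sdlog = sdlog)
  })
  out %>%
    mutate(
      copies_per_cm3 = mean_copies * .data$fold * noise,
      target = target
    ) %>%
    select(-"fold")
}

#' Simulate a two-sample scaffold coverage table
#'
#' Generates per-scaffold GC and mean coverage in two metagenomes (native
#' soil vs a 13C-labelled SIP fraction) with a planted low-abundance
#' population that is strongly enriched in the SIP sample — the situation
#' differential-coverage binning exploits.
#'
#' @param n_background,n_focal Scaffold counts for community background and
#'   the planted focal population.
#' @param focal_gc,focal_cov_a,focal_cov_b Mean GC (percent) and mean
#'   coverages of the focal population in samples A (native) and B (SIP);
#'   defaults 42.6 / 0.026 / 34 match a rare sulfate reducer enriched by SIP.
#' @param seed Integer seed.
#' @return Tibble `(scaffold_id, length_nt, gc_percent, coverage_a,
#'   coverage_b, population)`; `population` is the planted truth label.
#' @export
simulate_scaffolds <- function(n_background = 400, n_focal = 60,
                               focal_gc = 42.6, focal_cov_a = 0.026,
                               focal_cov_b = 34, seed = 1L) {
  withr::with_seed(seed, {
    bg <- tibble(
      scaffold_id = sprintf("bg_%04d", seq_len(n_background)),
      length_nt = round(rlnorm(n_background, log(8000), 0.8)),
      gc_percent = pmin(75, pmax(25, rnorm(n_background, 55, 6))),
      coverage_a = rlnorm(n_background, log(8), 0.7),
      coverage_b = rlnorm(n_background, log(3), 0.7),
      population = "background"
    )
    fc <- tibble(
      scaffold_id = sprintf("focal_%04d", seq_len(n_focal)),
      length_nt = round(rlnorm(n_focal, log(6000), 0.7)),
      gc_percent = pmin(60, pmax(30, rnorm(n_focal, focal_gc, 1.5))),
      coverage_a = rlnorm(n_focal, log(focal_cov_a), 0.25),
      coverage_b = rlnorm(n_focal, log(focal_cov_b), 0.25),
      population = "focal"
    )
  })
  bind_rows(fc, bg)
}
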