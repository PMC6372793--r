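# End-to-end orchestration: simulate -> normalize -> activity screen ->
# differential expression + response groups -> maintenance budget, with a
# consolidated report, optional on-disk outputs and a run manifest.

#' Pipeline configuration
#'
#' Declarative configuration of a full simulation-mode run.  Every source
#' of randomness derives from `seed`; re-running an identical config is
#' bit-reproducible.
#'
#' @param seed Master integer seed.
#' @param n_genes Catalog size.
#' @param category_weights Catalog category weights
#'   ([default_category_weights()]).
#' @param days,substrates,sulfate,replicates Design of the transcriptome
#'   samples ([default_design()]).
#' @param params [sim_params()] for the count generator.
#' @param alpha FDR level for the activity screen and DE (in (0,1)).
#' @param fold_min,gap_min Population-state thresholds
#'   ([classify_population_state()]).
#' @param de_day,de_sulfate Day and regime of the pairwise DE comparisons.
#' @param k_clusters Number of response groups cut from the dendrogram.
#' @param linkage Clustering linkage.
#' @param qpcr_mean,qpcr_cv,qpcr_days qPCR series settings (stable focal
#'   population around 1.2e6 copies cm^-3 over the incubation day grid).
#' @param energetics List: `model` ([maintenance_model()]),
#'   `carbon_per_cell`, `reaction` ([catabolic_reaction()]), optional
#'   `measured_rate`.
#' @param out_dir Optional output directory; when set, all stage tables,
#'   the JSON report and a manifest are written there.
#' @return List of class `zg_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_genes = 2000L,
                            category_weights = default_category_weights(),
                            days = c(8L, 36L),
                            substrates = substrate_levels(),
                            sulfate = "plusS",
                            replicates = 3L,
                            params = sim_params(),
                            alpha = 0.05,
                            fold_min = 10,
                            gap_min = 0.2,
                            de_day = 36L,
                            de_sulfate = "plusS",
                            k_clusters = 4L,
                            linkage = "average",
                            qpcr_mean = 1.2e6,
                            qpcr_cv = 0.2,
                            qpcr_days = c(0L, 5L, 8L, 15L, 26L, 36L, 50L),
                            energetics = list(),
                            out_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "zg_config")
  findings <- validate_config(cfg)
  if (nrow(findings) > 0) {
    abort(paste0(
      "invalid pipeline config:\n",
      paste0("  - ", findings$field, ": ", findings$reason, collapse = "\n")
    ))
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `zg_config` (or plain list with the same fields).
#' @return Tibble of findings `(field, reason)`; zero rows when valid.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(field, reason) f[[length(f) + 1]] <<- tibble(field = field, reason = reason)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  if (!num1(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    add("alpha", "must be a single number in (0, 1)")
  }
  if (!num1(config$fold_min) || config$fold_min <= 0) {
    add("fold_min", "threshold must be a single positive number")
  }
  if (!num1(config$gap_min) || config$gap_min < 0) {
    add("gap_min", "threshold must be a single non-negative number")
  }
  if (!num1(config$n_genes) || config$n_genes < 1) {
    add("n_genes", "must be a positive integer")
  }
  if (!num1(config$seed)) add("seed", "must be a single integer")
  if (!inherits(config$params, "zg_sim_params")) {
    add("params", "must come from sim_params()")
  }
  if (!is.null(config$out_dir) && !is.character(config$out_dir)) {
    add("out_dir", "must be a directory path or NULL")
  }
  if (!config$de_day %in% config$days) {
    add("de_day", "differential-expression day must be among the sampled days")
  }
  if (length(f) == 0) return(tibble(field = character(), reason = character()))
  bind_rows(f)
}

#' Run the full pipeline
#'
#' Simulation-mode end-to-end run: generate catalog + counts + qPCR series,
#' normalize (FPKM against whole-library depths, size factors, variance
#' stabilization), compute activity totals and fold changes versus the
#' no-substrate sulfate-amended control, run the Spearman activity screen
#' with category summaries and the population-state call, run the pairwise
#' DE comparisons at `de_day` and cut response groups from the
#' correlation-distance dendrogram of significant genes, and evaluate the
#' maintenance budget.  When `config$out_dir` is set, all stage tables
#' (TSV), the consolidated report (JSON), the gene dendrogram (Newick) and
#' a manifest are written there.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `zg_run_report`; a list with elements `catalog`,
#'   `design`, `counts`, `fpkm`, `totals`, `fold_changes`, `screen`,
#'   `category_summaries`, `state`, `qpcr`, `de`, `clusters`, `tree`,
#'   `maintenance`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  findings <- validate_config(config)
  zg_check(nrow(findings) == 0, "invalid config; see validate_config()")
  seed <- as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  catalog <- stage("simulate", generate_gene_catalog(
    config$n_genes, config$category_weights, seed = seed
  ))
  design <- default_design(config$substrates, config$sulfate, config$days,
                           config$replicates)
  sim <- stage("simulate", simulate_counts(catalog, design, config$params,
                                           seed = seed + 1L))
  qpcr_design <- default_design(config$substrates, config$sulfate,
                                config$qpcr_days, config$replicates)
  qpcr <- stage("simulate", simulate_qpcr(qpcr_design, config$qpcr_mean,
                                          config$qpcr_cv, seed = seed + 2L))

  depths <- setNames(sim$design$library_depth, sim$design$sample_id)
  fpkm <- stage("quantify", compute_fpkm(sim$counts, catalog,
                                         denominator = "library",
                                         depths = depths))
  totals <- stage("quantify", total_mrna(fpkm))
  folds <- stage("quantify", fold_change_vs_control(totals, sim$design,
                                                    day = config$de_day))

  screen <- stage("activity", activity_correlations(fpkm, totals, catalog,
                                                    alpha = config$alpha))
  summaries <- stage("activity", category_summary(screen))
  # the state call contrasts category means over all genes with a defined
  # rho; restricting to significant genes would bias null categories high
  summaries_all <- stage("activity", category_summary(screen,
                                                      significant_only = FALSE))
  state <- stage("activity", classify_population_state(
    qpcr, folds, summaries_all,
    fold_min = config$fold_min, gap_min = config$gap_min
  ))

  de <- stage("de", de_pairwise(sim$counts, sim$design, day = config$de_day,
                                sulfate = config$de_sulfate,
                                alpha = config$alpha))
  sig <- significant_genes(de, config$alpha)
  clusters <- NULL
  tree <- NULL
  if (length(sig) >= 2) {
    de_samples <- sim$design %>%
      filter(.data$day == config$de_day, .data$sulfate == config$de_sulfate) %>%
      pull("sample_id")
    vst <- stage("cluster", variance_stabilize(
      sim$counts[c("gene_id", de_samples)]
    ))
    vst_sig <- vst[vst$gene_id %in% sig, , drop = FALSE]
    nonconst <- apply(counts_matrix(vst_sig), 1, sd) > 0
    vst_sig <- vst_sig[nonconst, , drop = FALSE]
    if (nrow(vst_sig) >= 2) {
      dmat <- stage("cluster", pearson_distance(vst_sig))
      tree <- stage("cluster", hierarchical_cluster(dmat, config$linkage))
      k <- min(config$k_clusters, nrow(vst_sig))
      clusters <- stage("cluster", cut_clusters(tree, k = k))
    }
  }

  en <- config$energetics
  maintenance <- stage("maintenance", maintenance_budget(
    model = en$model %||% maintenance_model(),
    carbon_per_cell = en$carbon_per_cell %||% 6.5e-15,
    reaction = en$reaction %||% catabolic_reaction(),
    measured_rate = en$measured_rate
  ))

  manifest <- list(
    package_version = as.character(utils::packageVersion("zerogrowth")),
    seed = seed,
    n_genes = config$n_genes,
    n_samples = nrow(design),
    alpha = config$alpha,
    thresholds = list(fold_min = config$fold_min, gap_min = config$gap_min),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )

  report <- structure(
    list(
      catalog = catalog, design = sim$design, counts = sim$counts,
      fpkm = fpkm, totals = totals, fold_changes = folds, screen = screen,
      category_summaries = summaries, state = state, qpcr = qpcr, de = de,
      clusters = clusters, tree = tree, maintenance = maintenance,
      manifest = manifest
    ),
    class = "zg_run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Serialize the numeric content of a run report
#'
#' Stable JSON digest of every numeric result in the report (used for
#' reproducibility checks and the on-disk report).
#'
#' @param report A `zg_run_report`.
#' @return JSON string.
#' @export
report_json <- function(report) {
  payload <- list(
    totals = as.list(report$totals),
    fold_changes = report$fold_changes,
    correlations = report$screen$records,
    category_summaries = report$category_summaries,
    state = report$state$state,
    state_evidence = report$state$evidence,
    clusters = report$clusters,
    maintenance = list(
      m_G_T = report$maintenance$m_G_T,
      demand_fmol_per_cell_day = report$maintenance$demand_fmol_per_cell_day
    ),
    manifest = report$manifest
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write a run report to a directory
#'
#' @param report A `zg_run_report`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(report$counts, "counts.tsv")
  w(report$design, "design.tsv")
  w(as_tibble(report$catalog), "catalog.tsv")
  w(report$fpkm, "fpkm.tsv")
  w(report$fold_changes, "fold_changes.tsv")
  w(report$screen$records, "activity_correlations.tsv")
  w(report$category_summaries, "category_summaries.tsv")
  w(report$qpcr, "qpcr.tsv")
  w(report$de, "de_results.tsv")
  if (!is.null(report$clusters)) w(report$clusters, "response_groups.tsv")
  if (!is.null(report$tree) && requireNamespace("ape", quietly = TRUE)) {
    write_dendrogram_newick(report$tree, file.path(out_dir, "dendrogram.nwk"))
  }
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  writeLines(jsonlite::toJSON(report$manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.zg_run_report <- function(x, ...) {
  cat("zerogrowth run report\n")
  cat("  genes:", nrow(x$catalog), " samples:", nrow(x$design), "\n")
  cat("  state:", x$state$state, "\n")
  cat("  max activity fold:", signif(max(x$fold_changes$fold), 4), "\n")
  cat("  significant DE genes:", length(significant_genes(x$de)), "\n")
  cat("  maintenance demand:",
      signif(x$maintenance$demand_fmol_per_cell_day, 3),
      "fmol cell^-1 day^-1\n")
  invisible(x)
}
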