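# broom-style tidiers: tidy() returns the per-unit table of a result,
# glance() the one-row model-level summary.

#' Tidy an activity screen
#'
#' @param x A `zg_activity_screen`.
#' @param ... Unused.
#' @return The per-gene correlation records tibble.
#' @export
tidy.zg_activity_screen <- function(x, ...) x$records

#' @rdname tidy.zg_activity_screen
#' @export
glance.zg_activity_screen <- function(x, ...) {
  tibble(
    n_genes = nrow(x$records),
    n_tested = sum(!is.na(x$records$rho)),
    n_significant = sum(x$records$p_adj < x$alpha, na.rm = TRUE),
    n_samples = x$n_samples,
    alpha = x$alpha
  )
}

#' Tidy a population-state call
#'
#' @param x A `zg_population_state`.
#' @param ... Unused.
#' @return One-row evidence tibble with the state attached.
#' @export
tidy.zg_population_state <- function(x, ...) {
  bind_cols(tibble(state = x$state), x$evidence)
}

#' @rdname tidy.zg_population_state
#' @export
glance.zg_population_state <- function(x, ...) tidy(x)

#' Tidy a maintenance budget
#'
#' @param x A `zg_maintenance_budget`.
#' @param ... Unused.
#' @return Long tibble `(quantity, value, unit)` of every parameter and
#'   derived quantity, units explicit.
#' @export
tidy.zg_maintenance_budget <- function(x, ...) {
  rows <- tibble(
    quantity = c("m_ref", "T_ref", "Ea", "T", "m_G_T", "carbon_per_cell",
                 "delta_G", "demand"),
    value = c(x$model$m_ref, x$model$T_ref, x$model$Ea, x$model$T, x$m_G_T,
              x$carbon_per_cell, x$reaction$delta_G,
              x$demand_fmol_per_cell_day),
    unit = c("kJ C-mol^-1 h^-1", "K", "kJ mol^-1", "K", "kJ C-mol^-1 h^-1",
             "C-mol cell^-1", paste0("kJ (mol ", x$reaction$acceptor, ")^-1"),
             paste0("fmol ", x$reaction$acceptor, " cell^-1 day^-1"))
  )
  if (!is.null(x$ratio)) {
    rows <- bind_rows(rows, tibble(
      quantity = c("measured_rate", "measured_over_demand"),
      value = c(x$measured_rate, x$ratio),
      unit = c(paste0("fmol ", x$reaction$acceptor, " cell^-1 day^-1"),
               "dimensionless")
    ))
  }
  rows
}

#' @rdname tidy.zg_maintenance_budget
#' @export
glance.zg_maintenance_budget <- function(x, ...) {
  tibble(
    m_G_T = x$m_G_T,
    demand_fmol_per_cell_day = x$demand_fmol_per_cell_day,
    ratio = x$ratio %||% NA_real_,
    classification = x$classification %||% NA_character_
  )
}

#' Tidy a bin selection
#'
#' @param x A `zg_bin`.
#' @param ... Unused.
#' @return The selected scaffold tibble.
#' @export
tidy.zg_bin <- function(x, ...) x$scaffolds

#' @rdname tidy.zg_bin
#' @export
glance.zg_bin <- function(x, ...) x$summary

#' Tidy a run report
#'
#' @param x A `zg_run_report`.
#' @param ... Unused.
#' @return The per-gene correlation table joined with DE significance and
#'   response-group membership.
#' @export
tidy.zg_run_report <- function(x, ...) {
  out <- x$screen$records
  sig <- significant_genes(x$de)
  out <- mutate(out, de_significant = .data$gene_id %in% sig)
  if (!is.null(x$clusters)) {
    out <- left_join(out, select(x$clusters, "gene_id", "cluster_id"),
                     by = "gene_id")
  }
  out
}

#' @rdname tidy.zg_run_report
#' @export
glance.zg_run_report <- function(x, ...) {
  tibble(
    n_genes = nrow(x$catalog),
    n_samples = nrow(x$design),
    max_fold = max(x$fold_changes$fold),
    n_de_significant = length(significant_genes(x$de)),
    state = x$state$state,
    maintenance_demand = x$maintenance$demand_fmol_per_cell_day
  )
}
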