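# Thermodynamic maintenance-energy budget: temperature-corrected
# species-independent maintenance Gibbs energy, the Herbert-Pirt substrate
# partition q_s = m_s + mu/Y_max, and the per-cell electron-acceptor demand
# it implies at zero growth.

#' Maintenance model
#'
#' Bundles the species-independent maintenance Gibbs energy requirement and
#' its Arrhenius-type temperature correction.  Defaults: a maintenance rate
#' of 4.5 kJ per C-mol biomass per hour at 298.15 K with a temperature
#' coefficient of 69 kJ/mol, evaluated at 287.15 K (14 degC incubations).
#'
#' @param m_ref Maintenance Gibbs energy at `T_ref`, kJ (C-mol biomass)^-1 h^-1.
#' @param T_ref Reference temperature, K.
#' @param Ea Activation-energy-like temperature coefficient, kJ/mol.
#' @param T Incubation temperature, K.
#' @return List of class `zg_maintenance_model`.
#' @export
maintenance_model <- function(m_ref = 4.5, T_ref = 298.15, Ea = 69,
                              T = 287.15) {
  zg_check(m_ref > 0, "`m_ref` must be > 0")
  zg_check(T > 250 && T < 350 && T_ref > 250 && T_ref < 350,
           "temperatures must lie in (250, 350) K")
  structure(list(m_ref = m_ref, T_ref = T_ref, Ea = Ea, T = T),
            class = "zg_maintenance_model")
}

#' Temperature-corrected maintenance Gibbs energy
#'
#' `m_G(T) = m_ref * exp(-(Ea*1000/R) * (1/T - 1/T_ref))` with
#' R = 8.314 J mol^-1 K^-1: maintenance energy demand falls with
#' temperature along an Arrhenius-type curve.
#'
#' @param model A [maintenance_model()].
#' @return Maintenance Gibbs energy at `model$T`, kJ (C-mol)^-1 h^-1.
#' @export
#' @examples
#' temperature_corrected_maintenance(maintenance_model())  # ~1.55
temperature_corrected_maintenance <- function(model = maintenance_model()) {
  zg_check(inherits(model, "zg_maintenance_model"),
           "`model` must come from maintenance_model()")
  R <- 8.314  # J mol^-1 K^-1
  model$m_ref * exp(-(model$Ea * 1000 / R) * (1 / model$T - 1 / model$T_ref))
}

#' Herbert-Pirt substrate partition
#'
#' `q_s = m_s + mu / Y_max`: the biomass-specific substrate consumption
#' rate splits into a maintenance coefficient and a growth term.  At zero
#' growth (mu = 0) all consumption is maintenance.
#'
#' @param m_s Maintenance coefficient (substrate per biomass per time).
#' @param mu Specific growth rate, h^-1 (>= 0).
#' @param Y_max Maximum growth yield, biomass per substrate (> 0).
#' @return q_s in the units of `m_s`.
#' @export
herbert_pirt_qs <- function(m_s, mu, Y_max) {
  zg_check(Y_max > 0, "`Y_max` must be > 0")
  zg_check(mu >= 0, "`mu` must be >= 0")
  m_s + mu / Y_max
}

#' Catabolic reaction description
#'
#' @param name Reaction label.
#' @param delta_G Gibbs energy yield, kJ per mol electron acceptor
#'   (negative for an exergonic, usable reaction).
#' @param acceptor,donor Electron acceptor / donor names.
#' @return List of class `zg_reaction`.  The default describes incomplete
#'   lactate oxidation to acetate with sulfate as acceptor at -160 kJ per
#'   mol sulfate.
#' @export
catabolic_reaction <- function(name = "lactate_incomplete_oxidation",
                               delta_G = -160, acceptor = "sulfate",
                               donor = "lactate") {
  zg_check(delta_G < 0, "`delta_G` must be negative (exergonic)")
  structure(list(name = name, delta_G = delta_G, acceptor = acceptor,
                 donor = donor), class = "zg_reaction")
}

#' Per-cell electron-acceptor demand at zero growth
#'
#' Converts the maintenance power of a single cell into electron-acceptor
#' turnover: `demand = m_G * 24 * carbon_per_cell / |delta_G|`, returned in
#' fmol acceptor per cell per day.
#'
#' @param m_G Maintenance Gibbs energy, kJ (C-mol)^-1 h^-1.
#' @param carbon_per_cell Cell carbon content, C-mol per cell
#'   (default 6.5e-15 C-mol, about 0.16 pg C, a typical soil bacterium).
#' @param reaction A [catabolic_reaction()].
#' @return Demand, fmol acceptor cell^-1 day^-1.
#' @export
#' @examples
#' per_cell_acceptor_demand(1.55)  # ~1.5 fmol sulfate / cell / day
per_cell_acceptor_demand <- function(m_G, carbon_per_cell = 6.5e-15,
                                     reaction = catabolic_reaction()) {
  zg_check(carbon_per_cell > 0, "`carbon_per_cell` must be > 0")
  zg_check(reaction$delta_G < 0, "reaction must be exergonic")
  mol_per_day <- m_G * 24 * carbon_per_cell / abs(reaction$delta_G)
  mol_per_day * 1e15
}

#' Compare maintenance demand with a measured rate
#'
#' @param demand Predicted maintenance demand (> 0).
#' @param measured_rate Measured cell-specific rate, same units (> 0).
#' @param consistent_range Ratio window called "maintenance-consistent".
#' @return List with `ratio` (= measured / demand) and `classification`.
#' @export
demand_vs_measured_ratio <- function(demand, measured_rate,
                                     consistent_range = c(0.1, 10)) {
  zg_check(demand > 0 && measured_rate > 0, "inputs must be positive")
  ratio <- measured_rate / demand
  # boundary-inclusive up to floating rounding
  eps <- 1e-12
  cls <- if (ratio >= consistent_range[1] * (1 - eps) &&
             ratio <= consistent_range[2] * (1 + eps)) {
    "maintenance-consistent"
  } else if (ratio > consistent_range[2]) {
    "above-maintenance"
  } else {
    "below-maintenance"
  }
  list(ratio = ratio, classification = cls)
}

#' Full maintenance budget
#'
#' Chains temperature correction, cell carbon and catabolic energy yield
#' into the per-cell acceptor demand, optionally comparing it to a measured
#' cell-specific rate.
#'
#' @param model A [maintenance_model()].
#' @param carbon_per_cell C-mol per cell.
#' @param reaction A [catabolic_reaction()].
#' @param measured_rate Optional measured rate, fmol cell^-1 day^-1.
#' @return Object of class `zg_maintenance_budget`: parameters, `m_G_T`
#'   (kJ C-mol^-1 h^-1), `demand_fmol_per_cell_day`, and when a measured
#'   rate is given, `ratio` and `classification`.
#' @export
#' @examples
#' maintenance_budget()
maintenance_budget <- function(model = maintenance_model(),
                               carbon_per_cell = 6.5e-15,
                               reaction = catabolic_reaction(),
                               measured_rate = NULL) {
  m_G <- temperature_corrected_maintenance(model)
  demand <- per_cell_acceptor_demand(m_G, carbon_per_cell, reaction)
  out <- list(
    model = model,
    carbon_per_cell = carbon_per_cell,
    reaction = reaction,
    m_G_T = m_G,
    demand_fmol_per_cell_day = demand
  )
  if (!is.null(measured_rate)) {
    cmp <- demand_vs_measured_ratio(demand, measured_rate)
    out$measured_rate <- measured_rate
    out$ratio <- cmp$ratio
    out$classification <- cmp$classification
  }
  structure(out, class = "zg_maintenance_budget")
}

#' @export
print.zg_maintenance_budget <- function(x, ...) {
  cat("Maintenance budget\n")
  cat(sprintf("  m_G(%.2f K) = %.4g kJ C-mol^-1 h^-1\n", x$model$T, x$m_G_T))
  cat(sprintf("  cell carbon = %.3g C-mol; reaction %s (dG = %g kJ/mol %s)\n",
              x$carbon_per_cell, x$reaction$name, x$reaction$delta_G,
              x$reaction$acceptor))
  cat(sprintf("  demand = %.3g fmol %s cell^-1 day^-1\n",
              x$demand_fmol_per_cell_day, x$reaction$acceptor))
  if (!is.null(x$ratio)) {
    cat(sprintf("  measured/demand = %.3g (%s)\n", x$ratio, x$classification))
  }
  invisible(x)
}
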