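#' Solver control parameters
#'
#' @param cfl Courant number used to pick the time step from the fastest
#'   wave speed in the tree (evaluated at 250 mmHg for safety); must be in
#'   (0, 0.95].
#' @param max_cycles maximum number of cardiac cycles to run.
#' @param tol cycle-to-cycle periodicity tolerance: the run is converged
#'   when the maximum relative change of the root pressure waveform between
#'   consecutive cycles falls below `tol`.
#' @param friction_coeff Poiseuille-type friction coefficient `k_f` in the
#'   momentum source `-k_f * pi * (mu / rho) * Q / A`; 22 is a common 1-D
#'   velocity-profile value, 8 recovers the parabolic (Poiseuille) profile,
#'   0 disables friction.
#' @param init_pressure_mmhg initial uniform pressure; `NULL` uses the
#'   Ohmic estimate mean inflow x TPR.
#' @return a list of class `solver_control`.
#' @export
solver_control <- function(cfl = 0.8, max_cycles = 15, tol = 1e-3,
                           friction_coeff = 22, init_pressure_mmhg = NULL) {
  if (!is.finite(cfl) || cfl <= 0 || cfl > 0.95) abort("`cfl` must be in (0, 0.95]")
  if (!is.finite(tol) || tol <= 0) abort("`tol` must be > 0")
  if (max_cycles < 1) abort("`max_cycles` must be at least 1")
  if (friction_coeff < 0) abort("`friction_coeff` must be >= 0")
  structure(
    list(cfl = cfl, max_cycles = as.integer(max_cycles), tol = tol,
         friction_coeff = friction_coeff,
         init_pressure_mmhg = init_pressure_mmhg),
    class = "solver_control"
  )
}

#' Simulate pulse-wave propagation through an arterial tree
#'
#' Integrates the 1-D continuity and momentum equations (MacCormack
#' predictor-corrector) over the network with the prescribed inflow at the
#' aortic root, static-pressure continuity and mass conservation at
#' junctions, and three-element Windkessel boundaries at every leaf. Cycles
#' are repeated until the root pressure waveform is periodic to within
#' `control$tol` or `control$max_cycles` is reached; the final cycle's
#' pressure and flow at every named site are returned.
#'
#' @param tree an `arterial_tree`.
#' @param inflow an `inflow_wave`.
#' @param blood a `blood_properties` object.
#' @param control a `solver_control` object.
#' @return an object of class `sv_simulation`: `waveforms` (tibble `site`,
#'   `time_s`, `pressure_mmhg`, `flow_ml_s` over the final cycle),
#'   `converged`, `cycles_used`, `dt_s`, `period_s`, `mass` (cycle volume
#'   ledger, mL), `junction_imbalance_ml_s` and `terminal_flows`.
#'   Non-convergence is flagged, never silently dropped.
#' @export
simulate_pulse <- function(tree, inflow, blood = blood_properties(),
                           control = solver_control()) {
  stopifnot(inherits(tree, "arterial_tree"), inherits(inflow, "inflow_wave"))
  segs <- tree$segments
  ns <- nrow(segs)
  rho <- blood$density_kg_m3
  mu <- blood$viscosity_pa_s

  # SI per-segment quantities
  d_si <- segs$distensibility * 1e-3 / MMHG_PA       # Pa^-1
  pref_si <- rep(tree$reference$pressure_mmhg * MMHG_PA, ns)
  seg_aref <- lapply(seq_len(ns), function(i) {
    n <- segs$n_grid[i]
    d <- seq(segs$din_cm[i], segs$dout_cm[i], length.out = n) / 100
    pi * d^2 / 4
  })
  seg_dx <- segs$length_cm / 100 / (segs$n_grid - 1)

  parent_idx <- match(segs$parent, segs$id) - 1L
  parent_idx[is.na(parent_idx)] <- -1L
  term_idx <- match(segs$id, tree$terminals$segment) - 1L
  term_idx[is.na(term_idx)] <- -1L

  r_si <- MMHG_PA / 1e-6   # mmHg s/mL -> Pa s/m^3
  c_si <- 1e-6 / MMHG_PA   # mL/mmHg -> m^3/Pa

  # CFL time step from the fastest wave speed, evaluated at 250 mmHg
  p_hi <- 250 * MMHG_PA
  cmax <- vapply(seq_len(ns), function(i) {
    b <- segs$nonlinearity[i]
    if (b == 0) {
      a <- 1 + d_si[i] * (p_hi - pref_si[i])
      sqrt(a / (rho * d_si[i]))
    } else {
      a <- 1 + log(1 + d_si[i] * b * (p_hi - pref_si[i])) / b
      sqrt(a * exp(b * (a - 1)) / (rho * d_si[i]))
    }
  }, numeric(1))
  dt_raw <- control$cfl * min(seg_dx / (cmax + 2))
  period <- inflow$period_s
  nstep <- as.integer(ceiling(period / dt_raw))
  dt <- period / nstep

  qin <- inflow$fun(seq_len(nstep) * dt) * 1e-6  # m^3/s

  p_init <- control$init_pressure_mmhg
  if (is.null(p_init)) {
    p_init <- max(40, min(150, mean(qin) * 1e6 * tree_tpr(tree) +
                            mean(tree$terminals$pout)))
  }

  site_seg <- match(tree$sites$segment, segs$id) - 1L
  site_node <- as.integer(round(tree$sites$position * (segs$n_grid[site_seg + 1L] - 1L)))

  res <- solve_network_cpp(
    seg_n = segs$n_grid, seg_dx = seg_dx, seg_Aref = seg_aref,
    seg_D = d_si, seg_b = segs$nonlinearity, seg_Pref = pref_si,
    parent = parent_idx, term_of_seg = term_idx,
    term_R1 = tree$terminals$r1 * r_si, term_R2 = tree$terminals$r2 * r_si,
    term_C = tree$terminals$c * c_si, term_Pout = tree$terminals$pout * MMHG_PA,
    inflow = qin, dt = dt, max_cycles = control$max_cycles, tol = control$tol,
    rho = rho, fric_coef = control$friction_coeff * pi * mu / rho,
    site_seg = site_seg, site_node = site_node, P_init = p_init * MMHG_PA
  )

  ts <- seq_len(nstep) * dt
  wf <- purrr::map_dfr(seq_along(tree$sites$site), function(k) {
    tibble(
      site = tree$sites$site[k], time_s = ts,
      pressure_mmhg = res$site_P[, k] / MMHG_PA,
      flow_ml_s = res$site_Q[, k] * 1e6
    )
  })
  tf <- purrr::map_dfr(seq_along(tree$terminals$segment), function(k) {
    tibble(terminal = tree$terminals$segment[k], time_s = ts,
           flow_ml_s = res$term_Q[, k] * 1e6)
  })
  structure(
    list(
      waveforms = wf,
      terminal_flows = tf,
      converged = res$converged,
      cycles_used = res$cycles_used,
      dt_s = dt, period_s = period,
      mass = list(
        root_volume_ml = res$root_volume * 1e6,
        terminal_volume_ml = stats::setNames(res$term_volumes * 1e6,
                                             tree$terminals$segment),
        storage_change_ml = res$storage_change * 1e6
      ),
      junction_imbalance_ml_s = res$junction_imbalance * 1e6,
      inflow = inflow, control = control
    ),
    class = "sv_simulation"
  )
}

#' @export
print.sv_simulation <- function(x, ...) {
  cat("<sv_simulation>", if (x$converged) "converged" else "NOT converged",
      "in", x$cycles_used, "cycles | dt", signif(x$dt_s * 1e3, 3), "ms\n")
  rng <- x$waveforms |>
    group_by(.data$site) |>
    summarise(sbp = max(.data$pressure_mmhg), dbp = min(.data$pressure_mmhg))
  for (i in seq_len(nrow(rng))) {
    cat(sprintf("  %-14s %5.1f / %5.1f mmHg\n", rng$site[i], rng$sbp[i], rng$dbp[i]))
  }
  invisible(x)
}

#' Write simulated waveforms to CSV
#'
#' Columns `time_s`, `site`, `pressure_mmhg`, `flow_ml_s`.
#'
#' @param sim an `sv_simulation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(sim, path) {
  stopifnot(inherits(sim, "sv_simulation"))
  readr::write_csv(sim$waveforms[, c("time_s", "site", "pressure_mmhg", "flow_ml_s")],
                   path)
  invisible(path)
}
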