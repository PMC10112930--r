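#' Specification of a (k, mu) insulation sweep
#'
#' Bundles the tissue layout, the shared mechanics and solver controls,
#' and the grids of bending coefficients and cable stiffnesses for the
#' insulation experiment. The same active forcing and controls are used
#' for every sweep cell and for the baseline, so the normalization
#' isolates the barrier properties.
#'
#' @param k_values Bending coefficients to sweep (default `c(1, 10,
#'   100)`).
#' @param mu_values Strictly increasing cable stiffnesses (default
#'   `c(1, 3, 10, 30, 100)`, a log-spaced grid bracketing the two
#'   headline values 1 and 100).
#' @param f_active Contractile tension on the core edges (default 0.4,
#'   which constricts the core to half its apical area in the no-barrier
#'   tissue).
#' @param params Base [mechanics_params()]; its `mu_cable`/`k_bend` are
#'   overridden per sweep cell and its `f_active` by the `f_active`
#'   argument.
#' @param controls [solver_controls()] shared by all runs. The default
#'   relaxes to a maximum residual force of `1e-7`, ample for the
#'   order-0.1 radial displacements being compared.
#' @param mesh A tagged `tissue_mesh` with an active core (default
#'   [placode_mesh()]).
#' @param out_dir Optional directory: per-run mesh JSONs, `summary.csv`
#'   and a run log are written there.
#' @param peripheral Outside-node convention for the readout (see
#'   [insulation_index()]).
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(k_values = c(1, 10, 100),
                       mu_values = c(1, 3, 10, 30, 100),
                       f_active = 0.4,
                       params = mechanics_params(),
                       controls = solver_controls(force_tol = 1e-7),
                       mesh = placode_mesh(),
                       out_dir = NULL,
                       peripheral = c("outside", "rim")) {
  stopifnot(length(k_values) >= 1, all(k_values >= 0),
            length(mu_values) >= 1, all(mu_values > 0))
  if (is.unsorted(mu_values, strictly = TRUE))
    stop("`mu_values` must be strictly increasing")
  structure(list(k_values = k_values, mu_values = mu_values,
                 f_active = f_active, params = params, controls = controls,
                 mesh = mesh, out_dir = out_dir,
                 peripheral = match.arg(peripheral)),
            class = "sweep_spec")
}

cell_params <- function(spec, k_bend, mu_cable) {
  mechanics_params(mu_default = spec$params$mu_default,
                   mu_cable = mu_cable, k_bend = k_bend,
                   f_active = spec$f_active, eta = spec$params$eta)
}

#' Run one sweep cell: calibrate, then contract
#'
#' Calibrates the ground state of the spec's mesh at the given
#' `(k_bend, mu_cable)` and runs the active contraction from it.
#'
#' @param k_bend Bending coefficient of the cable.
#' @param mu_cable Cable spring constant.
#' @param spec A [sweep_spec()].
#' @return List with `result` (a `simulation_result`) and `mesh` (the
#'   calibrated mesh).
#' @export
run_single <- function(k_bend, mu_cable, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  p <- cell_params(spec, k_bend, mu_cable)
  mesh <- tryCatch(calibrate_ground_state(spec$mesh, p, spec$controls),
                   error = function(e) stop("sweep cell (k=", k_bend,
                                            ", mu=", mu_cable, "): ",
                                            conditionMessage(e)))
  res <- run_contraction(mesh, p, spec$controls)
  list(result = res, mesh = mesh)
}

#' Run the full (k, mu) insulation sweep
#'
#' Runs one baseline contraction (no barrier: `mu_cable = mu_default`,
#' `k_bend = 0`) plus one calibrated contraction per `(k_bend, mu_cable)`
#' pair, and summarises the mean radial movement of nodes on either side
#' of the cable, normalised against the baseline.
#'
#' @param spec A [sweep_spec()].
#' @param progress Print one line per run?
#' @return An `insulation_summary` data frame with columns `k_bend`,
#'   `mu_cable`, `mean_radial_outside`, `mean_radial_inside`,
#'   `n_outside`, `n_inside`, `normalized_movement`, `decrease`. The
#'   baseline result is stored in attribute `"baseline"`.
#' @export
run_sweep <- function(spec = sweep_spec(), progress = interactive()) {
  stopifnot(inherits(spec, "sweep_spec"))
  mesh <- spec$mesh
  out_dir <- spec$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (progress) message(msg)
  }

  base_params <- cell_params(spec, 0, spec$params$mu_default)
  say("baseline: k=0, mu=%g, f_active=%g", spec$params$mu_default,
      spec$f_active)
  baseline <- run_contraction(mesh, base_params, spec$controls)
  say("baseline: %d steps, max|F|=%.3g", baseline$steps_taken,
      baseline$final_max_force)

  inside_ids <- side_node_ids(mesh, "inside")
  outside_ids <- side_node_ids(mesh, "outside", spec$peripheral)
  # exclude vertices of the actively constricting core, as in the
  # live-imaging analysis: their movement reflects the constriction
  # itself, not transmitted deformation
  core_nodes <- unique(unlist(
    mesh$cells$boundary[mesh$cells$region == "core"]))
  inside_ids <- setdiff(inside_ids, core_nodes)

  rows <- vector("list", length(spec$k_values) * length(spec$mu_values))
  i <- 0L
  for (k in spec$k_values) {
    for (mu in spec$mu_values) {
      i <- i + 1L
      run <- tryCatch(run_single(k, mu, spec), error = identity)
      if (inherits(run, "error")) {
        say("FAILED (k=%g, mu=%g): %s", k, mu, conditionMessage(run))
        rows[[i]] <- data.frame(k_bend = k, mu_cable = mu,
                                mean_radial_outside = NA_real_,
                                mean_radial_inside = NA_real_,
                                n_outside = length(outside_ids),
                                n_inside = length(inside_ids),
                                normalized_movement = NA_real_,
                                decrease = NA_real_)
        next
      }
      idx <- insulation_index(run$result, baseline, mesh,
                              centre = mesh$centre,
                              peripheral = spec$peripheral)
      rows[[i]] <- data.frame(
        k_bend = k, mu_cable = mu,
        mean_radial_outside = idx$mean_radial_outside,
        mean_radial_inside = radial_displacement(run$result, inside_ids,
                                                 mesh$centre)$mean,
        n_outside = idx$n_outside,
        n_inside = length(inside_ids),
        normalized_movement = idx$normalized_movement,
        decrease = idx$decrease)
      say("k=%g mu=%g: %d steps, normalized_movement=%.4f", k, mu,
          run$result$steps_taken, idx$normalized_movement)
      if (!is.null(out_dir))
        write_mesh_json(set_mesh_positions(run$mesh,
                                           run$result$final_positions),
                        file.path(out_dir,
                                  sprintf("final_k%g_mu%g.json", k, mu)))
    }
  }
  summary <- do.call(rbind, rows)
  class(summary) <- c("insulation_summary", "data.frame")
  attr(summary, "baseline") <- baseline
  attr(summary, "f_active") <- spec$f_active
  if (!is.null(out_dir)) {
    write_insulation_csv(summary, file.path(out_dir, "summary.csv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  if (anyNA(summary$normalized_movement))
    warning("some sweep cells failed; see the run log")
  summary
}
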