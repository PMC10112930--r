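#' Solver controls for over-damped relaxation
#'
#' @param dt Euler time step. `NULL` (default) chooses
#'   `dt_safety * eta / S_max` per run, where `S_max` is a per-node upper
#'   bound on the local stiffness (sum of incident edge moduli, plus
#'   `12 * k_bend / l_min^2` at cable nodes); explicit Euler on a gradient
#'   flow is stable for `dt < 2 * eta / lambda_max` and `S_max` bounds
#'   `lambda_max` from above, so the default `dt_safety = 1` keeps a
#'   2-fold margin.
#' @param t_max Integration time budget per relaxation.
#' @param force_tol Equilibrium criterion: maximum per-node force
#'   magnitude.
#' @param calib_tol Ground-state calibration stop: maximum relative change
#'   of cable rest lengths between calibration rounds.
#' @param max_calib_rounds Calibration round budget.
#' @param snapshot_every Record a position snapshot every this many steps
#'   (0 = none).
#' @param dt_safety Stability factor used when `dt` is `NULL`.
#' @return A `solver_controls` object (named list).
#' @export
solver_controls <- function(dt = NULL, t_max = 5000, force_tol = 1e-8,
                            calib_tol = 1e-6, max_calib_rounds = 100L,
                            snapshot_every = 0L, dt_safety = 1) {
  if (!is.null(dt) && (length(dt) != 1L || !is.finite(dt) || dt <= 0))
    stop("`dt` must be NULL or a single positive number")
  stopifnot(t_max > 0, force_tol > 0, calib_tol > 0, max_calib_rounds >= 1,
            snapshot_every >= 0, dt_safety > 0)
  structure(list(dt = dt, t_max = t_max, force_tol = force_tol,
                 calib_tol = calib_tol,
                 max_calib_rounds = as.integer(max_calib_rounds),
                 snapshot_every = as.integer(snapshot_every),
                 dt_safety = dt_safety),
            class = "solver_controls")
}

#' Stable Euler time step for a mesh and parameter set
#'
#' Upper-bounds the local stiffness at each node by the sum of incident
#' effective edge moduli plus a bending term `12 * k_bend / l_min^2` at
#' cable nodes, and returns `safety * eta / max(S)`.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [mechanics_params()] object.
#' @param safety Stability factor (see [solver_controls()]).
#' @return A single positive time step.
#' @export
stable_dt <- function(mesh, params, safety = 1,
                      positions = mesh_positions(mesh)) {
  mod <- ifelse(mesh$edges$is_cable, params$mu_cable, params$mu_default)
  n <- nrow(mesh$nodes)
  S <- rowsum_by(mod, mesh$edges$from, n) + rowsum_by(mod, mesh$edges$to, n)
  if (params$k_bend > 0 && any(mesh$edges$is_cable)) {
    # bending stiffness scales with 1/length^2; guard against cable edges
    # currently shorter than their rest length
    cab <- mesh$edges$is_cable
    lmin <- min(mesh$edges$rest_length[cab],
                edge_lengths(mesh, positions)[cab])
    cn <- unique(c(mesh$edges$from[cab], mesh$edges$to[cab]))
    S[cn + 1L] <- S[cn + 1L] + 12 * params$k_bend / lmin^2
  }
  safety * params$eta / max(S)
}

rowsum_by <- function(v, idx0, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx0)
  out[as.integer(rownames(agg)) + 1L] <- agg
  out
}

#' Relax a tissue mesh to mechanical equilibrium
#'
#' Integrates the over-damped dynamics `eta * dx_i/dt = F_i` by explicit
#' Euler from the mesh's current positions until the maximum per-node
#' force magnitude drops below `force_tol` or the time budget `t_max` is
#' exhausted. The trajectory is a gradient flow of [total_energy()], so
#' energy is non-increasing for stable time steps. The mesh itself is not
#' modified.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [mechanics_params()] object.
#' @param controls A [solver_controls()] object.
#' @param with_active Apply active-edge tensions during the run?
#' @return A `simulation_result`: list with `initial_positions`,
#'   `final_positions`, `snapshots` (list of `n x 2` matrices),
#'   `snapshot_times`, `converged`, `final_max_force`, `steps_taken`,
#'   `dt`.
#' @export
relax <- function(mesh, params, controls = solver_controls(),
                  with_active = FALSE) {
  stopifnot(inherits(mesh, "tissue_mesh"),
            inherits(params, "mechanics_params"),
            inherits(controls, "solver_controls"))
  pos0 <- mesh_positions(mesh)
  co <- edge_coefficients(mesh, params, with_active)
  trip <- cable_triplets(mesh)
  fixed_dt <- !is.null(controls$dt)

  # with an automatic step the integration runs in chunks, re-deriving the
  # stable dt from the current geometry between chunks: cable edges that
  # shorten under strong bending raise the local stiffness, and a dt chosen
  # from the starting geometry alone can turn marginally unstable
  chunk_t <- if (fixed_dt) controls$t_max else 20 * params$eta
  pos <- pos0
  t_used <- 0
  steps <- 0L
  snaps <- list()
  stimes <- numeric(0)
  converged <- FALSE
  fmax <- NA_real_
  dt <- NA_real_
  repeat {
    dt <- if (fixed_dt) controls$dt
      else stable_dt(mesh, params, controls$dt_safety, pos)
    this_t <- min(chunk_t, controls$t_max - t_used)
    out <- cpp_relax(pos, mesh$edges$from, mesh$edges$to,
                     mesh$edges$rest_length, co$mod, co$tension,
                     trip, params$k_bend, params$eta, dt,
                     as.integer(ceiling(this_t / dt)), controls$force_tol,
                     controls$snapshot_every)
    pos <- out$positions
    steps <- steps + out$steps_taken
    if (length(out$snapshots)) {
      snaps <- c(snaps, out$snapshots)
      stimes <- c(stimes, t_used + out$snapshot_times)
    }
    t_used <- t_used + out$steps_taken * dt
    converged <- out$converged
    fmax <- out$final_max_force
    if (converged || t_used >= controls$t_max - dt / 2 ||
        out$steps_taken == 0L) break
  }

  structure(list(initial_positions = pos0,
                 final_positions = pos,
                 snapshots = snaps,
                 snapshot_times = stimes,
                 converged = converged,
                 final_max_force = fmax,
                 steps_taken = steps,
                 dt = dt),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d nodes, %d steps (dt=%.3g), %s, max|F|=%.3g\n",
    nrow(x$final_positions), x$steps_taken, x$dt,
    if (x$converged) "converged" else "NOT converged", x$final_max_force))
  invisible(x)
}

#' Calibrate the tension-free ground state of the cable
#'
#' With a bending penalty the initially zig-zag cable straightens and its
#' circumference shrinks, so the hexagonal lattice is no longer an
#' equilibrium. The ground state is restored by iteratively relaxing the
#' tissue (without active forces) and adopting the cable's equilibrium
#' length as its new rest length, until the rest lengths stop changing.
#'
#' Two reset conventions are provided. The default, `"uniform"`, adopts
#' one common rest length (the mean equilibrium cable-edge length) for
#' all cable edges each round; its fixed point is a ground state whose
#' cable carries zero mean tension, and the iteration is a stable,
#' one-dimensional fixed-point problem that the implementation solves by
#' a safeguarded secant method (each round's equilibrium found by direct
#' energy minimisation with a Newton polish), followed by the plain
#' relax-and-reset loop as verification against the over-damped
#' dynamics. The alternative `"per-edge"` convention adopts each edge's
#' own equilibrium length; linearising that map around its fixed point
#' shows eigenvalues above one for appreciable bending stiffness -- cable
#' nodes slide tangentially and bunch up, because a rest-length reset
#' erases the only elastic penalty on sliding while the bending energy,
#' which depends on angles alone, does not resist it -- so it is exposed
#' for small-`k_bend` experimentation but is not the default.
#'
#' @inheritParams relax
#' @param reset `"uniform"` (default) or `"per-edge"`; see Details.
#' @return The calibrated mesh: cable `rest_length` values replaced by
#'   their equilibrium value and node positions moved to the relaxed
#'   ground state. The attribute `"calibration"` holds a per-round log
#'   (stage, max relative rest-length change, cable circumference).
#' @export
calibrate_ground_state <- function(mesh, params, controls = solver_controls(),
                                   reset = c("uniform", "per-edge")) {
  stopifnot(inherits(mesh, "tissue_mesh"),
            inherits(params, "mechanics_params"))
  reset <- match.arg(reset)
  if (!any(mesh$edges$is_cable))
    stop("mesh has no tagged cable; call tag_regions() first")
  cable <- mesh$edges$is_cable
  log <- data.frame(stage = character(0), round = integer(0),
                    max_rel_change = numeric(0), circumference = numeric(0))

  adopt <- function(l) if (reset == "uniform") rep(mean(l), length(l)) else l

  reset_loop <- function(mesh, p, stage) {
    for (round in seq_len(controls$max_calib_rounds)) {
      res <- relax(mesh, p, controls, with_active = FALSE)
      mesh <- set_mesh_positions(mesh, res$final_positions)
      new_rest <- adopt(edge_lengths(mesh)[cable])
      rel_change <- max(abs(new_rest - mesh$edges$rest_length[cable]) /
                          mesh$edges$rest_length[cable])
      mesh$edges$rest_length[cable] <- new_rest
      log <<- rbind(log, data.frame(stage = stage, round = round,
                                    max_rel_change = rel_change,
                                    circumference = sum(new_rest)))
      if (rel_change <= controls$calib_tol) return(mesh)
    }
    stop(sprintf(
      paste0("ground-state calibration did not converge in %d rounds (last ",
             "max relative rest-length change %.3g > calib_tol %.3g)"),
      controls$max_calib_rounds, log$max_rel_change[nrow(log)],
      controls$calib_tol))
  }

  if (reset == "uniform" && params$k_bend > 0) {
    # secant acceleration of the one-dimensional fixed-point problem
    # lbar -> mean cable length at equilibrium(lbar)
    work <- mesh
    pos <- mesh_positions(work)
    lbar <- mean(work$edges$rest_length[cable])
    g_prev <- NULL
    lbar_prev <- NULL
    for (it in seq_len(controls$max_calib_rounds)) {
      work$edges$rest_length[cable] <- lbar
      work <- set_mesh_positions(work, pos)
      pos <- equilibrium_positions(work, params, controls)
      lmean <- mean(edge_lengths(work, pos)[cable])
      g <- lmean - lbar
      log <- rbind(log, data.frame(stage = "accelerated", round = it,
                                   max_rel_change = abs(g) / lbar,
                                   circumference = sum(cable) * lmean))
      if (abs(g) / lbar <= controls$calib_tol / 4) break
      step <- if (is.null(g_prev) || abs(g - g_prev) < 1e-14) g
        else -g * (lbar - lbar_prev) / (g - g_prev)
      lbar_prev <- lbar
      g_prev <- g
      # for a stiff cable the map is nearly flat, so the raw secant
      # extrapolation can be enormous; cap the relative step instead
      step <- sign(step) * min(abs(step), 0.05 * lbar)
      lbar <- max(lbar + step, 0.2 * mesh$edge_length)
    }
    mesh <- set_mesh_positions(mesh, pos)
    mesh$edges$rest_length[cable] <- lbar
  }
  mesh <- reset_loop(mesh, params, "verification")
  # leave the mesh at the relaxed ground state of its final rest lengths
  res <- relax(mesh, params, controls, with_active = FALSE)
  mesh <- set_mesh_positions(mesh, res$final_positions)
  attr(mesh, "calibration") <- log
  mesh
}

#' Run the active contraction from a calibrated ground state
#'
#' Relaxes the mesh with the active-edge tensions switched on: the core
#' constricts and deforms the surrounding tissue until a new equilibrium
#' is reached.
#'
#' @param calibrated_mesh A mesh returned by [calibrate_ground_state()]
#'   (or any mesh whose current state is the intended starting
#'   configuration).
#' @inheritParams relax
#' @return A `simulation_result` (see [relax()]).
#' @export
run_contraction <- function(calibrated_mesh, params,
                            controls = solver_controls()) {
  relax(calibrated_mesh, params, controls, with_active = TRUE)
}


# Mechanical equilibrium of a mesh under a parameter set, found by
# direct energy minimisation (L-BFGS with the analytic gradient)
# followed by a Newton polish using a finite-difference Hessian of the
# analytic forces (symmetrised; a small ridge bridges the rigid-motion
# nullspace). Falls back to over-damped relaxation if the polish cannot
# reach the force tolerance. Returns the equilibrium positions.
equilibrium_positions <- function(mesh, params, controls,
                                  with_active = FALSE) {
  co <- edge_coefficients(mesh, params, with_active)
  trip <- cable_triplets(mesh)
  n <- nrow(mesh$nodes)
  m <- 2L * n
  efrom <- mesh$edges$from
  eto <- mesh$edges$to
  rest <- mesh$edges$rest_length
  fvec <- function(x) as.vector(cpp_forces(matrix(x, n, 2L), efrom, eto,
                                           rest, co$mod, co$tension, trip,
                                           params$k_bend))
  opt <- stats::optim(as.vector(mesh_positions(mesh)),
                      fn = function(x) cpp_energy(matrix(x, n, 2L), efrom,
                                                  eto, rest, co$mod,
                                                  co$tension, trip,
                                                  params$k_bend),
                      gr = function(x) -fvec(x),
                      method = "L-BFGS-B",
                      control = list(maxit = 50000L, factr = 0,
                                     pgtol = 1e-6))
  x <- opt$par
  F0 <- fvec(x)
  if (max(abs(F0)) > controls$force_tol / 10) {
    h <- 1e-6
    J <- matrix(0, m, m)
    for (i in seq_len(m)) {
      xi <- x
      xi[i] <- xi[i] + h
      J[, i] <- (fvec(xi) - F0) / h
    }
    H <- -(J + t(J)) / 2
    diag(H) <- diag(H) + 1e-9
    for (np in seq_len(10L)) {
      if (max(abs(F0)) <= controls$force_tol / 10) break
      dx <- tryCatch(solve(H, F0), error = function(e) NULL)
      if (is.null(dx)) break
      Fn <- fvec(x + dx)
      if (max(abs(Fn)) >= max(abs(F0))) break
      x <- x + dx
      F0 <- Fn
    }
  }
  pos <- matrix(x, n, 2L)
  Fm <- matrix(F0, n, 2L)
  if (max(sqrt(rowSums(Fm^2))) > controls$force_tol) {
    mtmp <- set_mesh_positions(mesh, pos)
    pos <- relax(mtmp, params, controls, with_active)$final_positions
  }
  pos
}
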