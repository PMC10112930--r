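test_that("a zero-force configuration is a fixed point of relax", {
  mesh <- small_placode()
  res <- relax(mesh, mechanics_params(), solver_controls(t_max = 10))
  expect_true(res$converged)
  expect_equal(res$steps_taken, 0)
  expect_identical(res$final_positions, res$initial_positions)
})

test_that("isolated spring relaxes along the closed-form exponential", {
  # eta dl/dt = -2 mu (l - l0)  =>  l(t) = l0 + (l(0) - l0) exp(-2t)
  mesh <- two_node_mesh(separation = 2, rest_length = 1)
  ctl <- solver_controls(dt = 1e-3, t_max = 1, force_tol = 1e-15)
  res <- relax(mesh, mechanics_params(), ctl)
  l_end <- abs(diff(res$final_positions[, 1]))
  expect_equal(l_end, 1 + exp(-2), tolerance = 1e-3)
  expect_equal(res$steps_taken, 1000)
})

test_that("energy is non-increasing along the over-damped trajectory", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 20, k_bend = 10, f_active = 0.4)
  ctl <- solver_controls(t_max = 20, force_tol = 1e-10, snapshot_every = 500L)
  res <- relax(mesh, params, ctl, with_active = TRUE)
  energies <- c(total_energy(mesh, params, res$initial_positions),
                vapply(res$snapshots, function(p)
                  total_energy(mesh, params, p), numeric(1)),
                total_energy(mesh, params, res$final_positions))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("halving the time step barely changes the final state", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 10, k_bend = 5)
  dt0 <- stable_dt(mesh, params)
  ctl1 <- solver_controls(dt = dt0, t_max = 500, force_tol = 1e-8)
  ctl2 <- solver_controls(dt = dt0 / 2, t_max = 500, force_tol = 1e-8)
  r1 <- relax(mesh, params, ctl1)
  r2 <- relax(mesh, params, ctl2)
  expect_true(r1$converged && r2$converged)
  expect_lt(max(abs(r1$final_positions - r2$final_positions)), 10 * 1e-8 / 1e-2)
})

test_that("the pipeline is deterministic", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 10, k_bend = 5, f_active = 0.3)
  ctl <- solver_controls(force_tol = 1e-7, t_max = 500)
  r1 <- run_contraction(calibrate_ground_state(mesh, params, ctl), params, ctl)
  r2 <- run_contraction(calibrate_ground_state(mesh, params, ctl), params, ctl)
  expect_identical(r1$final_positions, r2$final_positions)
  expect_identical(r1$steps_taken, r2$steps_taken)
})

test_that("neutral-parameter calibration is a one-round no-op", {
  mesh <- small_placode()
  params <- mechanics_params()   # mu_cable = mu_default, k_bend = 0
  cal <- calibrate_ground_state(mesh, params, solver_controls(t_max = 10))
  log <- attr(cal, "calibration")
  expect_equal(nrow(log), 1)
  expect_lt(log$max_rel_change, 1e-12)
  expect_equal(cal$edges$rest_length, mesh$edges$rest_length,
               tolerance = 1e-12)
})

test_that("calibration shrinks the cable and is idempotent", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 10, k_bend = 20)
  ctl <- solver_controls(force_tol = 1e-8, t_max = 1000)
  cal <- calibrate_ground_state(mesh, params, ctl)
  expect_lt(cable_circumference(cal), cable_circumference(mesh))
  F <- total_force(cal, params, with_active = FALSE)
  expect_lt(max(sqrt(rowSums(F^2))), ctl$force_tol * 1.01)
  # re-running from the calibrated state changes rest lengths only within
  # the calibration tolerance
  cal2 <- calibrate_ground_state(cal, params, ctl)
  rel <- abs(cal2$edges$rest_length - cal$edges$rest_length) /
    cal$edges$rest_length
  expect_lt(max(rel), 5 * ctl$calib_tol)
})

test_that("no-barrier relaxation is identical with and without cable tags", {
  mesh <- small_placode()
  untagged <- mesh
  untagged$edges$is_cable <- FALSE
  untagged$cable_loop <- integer(0)
  params <- mechanics_params(f_active = 0.4)   # mu_cable = mu_default, k = 0
  ctl <- solver_controls(force_tol = 1e-8, t_max = 200)
  r1 <- relax(mesh, params, ctl, with_active = TRUE)
  r2 <- relax(untagged, params, ctl, with_active = TRUE)
  expect_identical(r1$final_positions, r2$final_positions)
})

test_that("contraction constricts the core and drags interior nodes inward", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 10, k_bend = 10, f_active = 0.4)
  ctl <- solver_controls(force_tol = 1e-7, t_max = 1000)
  cal <- calibrate_ground_state(mesh, params, ctl)
  res <- run_contraction(cal, params, ctl)
  core <- which(cal$cells$region == "core")
  expect_lt(sum(cell_areas(cal, res$final_positions)[core]),
            sum(cell_areas(cal, res$initial_positions)[core]))
  # interior (non-core) junctional nodes move toward the centre on average
  labels <- classify_nodes(cal)
  core_nodes <- unique(unlist(cal$cells$boundary[core]))
  ids <- setdiff(cal$nodes$id[labels == "inside" &
                                cal$nodes$kind == "junctional"], core_nodes)
  expect_gt(radial_displacement(res, ids, cal$centre)$mean, 0)
  # with no active force the ground state does not move
  still <- run_contraction(cal, mechanics_params(mu_cable = 10, k_bend = 10),
                           ctl)
  expect_lt(max(abs(still$final_positions - still$initial_positions)), 1e-5)
})
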