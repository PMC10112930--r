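test_that("spring force follows the linear law and action-reaction", {
  # at rest length: no force
  expect_equal(spring_force(c(0, 0), c(1, 0), 1), matrix(0, 2, 2))
  # stretched edge pulls the endpoints together with modulus * extension
  f <- spring_force(c(0, 0), c(2, 0), 1, modulus = 1)
  expect_equal(f[1, ], c(1, 0))
  expect_equal(f[2, ], c(-1, 0))
  # action-reaction for arbitrary geometry
  set.seed(1)
  for (i in 1:20) {
    f <- spring_force(rnorm(2), rnorm(2), runif(1, 0.5, 2), runif(1, 0.5, 5))
    expect_equal(f[1, ] + f[2, ], c(0, 0))
  }
  expect_error(spring_force(c(0, 0), c(0, 0), 1), "degenerate")
})

test_that("active force is a constant tension along the edge", {
  expect_equal(active_force(c(0, 0), c(1, 0), 0), matrix(0, 2, 2))
  f <- active_force(c(0, 0), c(1, 0), 0.5)
  expect_equal(f[1, ], c(0.5, 0))
  expect_equal(f[2, ], c(-0.5, 0))
  # magnitude independent of length
  f2 <- active_force(c(0, 0), c(10, 0), 0.5)
  expect_equal(f2[1, ], c(0.5, 0))
  expect_error(active_force(c(1, 1), c(1, 1), 1), "degenerate")
})

test_that("bending force is the exact gradient of the angle penalty", {
  # collinear triplet carries no force
  expect_equal(bending_force(c(-1, 0), c(0, 0), c(1, 0), 10),
               matrix(0, 3, 2), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    p <- list(rnorm(2), rnorm(2), rnorm(2))
    k <- runif(1, 0.5, 100)
    ana <- bending_force(p[[1]], p[[2]], p[[3]], k)
    num <- fd_bending_force(p[[1]], p[[2]], p[[3]], k)
    expect_equal(ana, num, tolerance = 1e-5)
    # forces sum to zero (translation invariance of the energy)
    expect_equal(colSums(ana), c(0, 0), tolerance = 1e-10)
    # zero net torque about the apex (rotation invariance)
    torque <- sum(vapply(1:3, function(j) {
      arm <- p[[j]] - p[[2]]
      arm[1] * ana[j, 2] - arm[2] * ana[j, 1]
    }, numeric(1)))
    expect_equal(torque, 0, tolerance = 1e-8)
  }
  expect_error(bending_force(c(0, 0), c(0, 0), c(1, 0), 1), "degenerate")
})

test_that("total force matches the element-by-element assembly", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 7, k_bend = 3, f_active = 0.25)
  set.seed(7)
  pos <- mesh_positions(mesh) + matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.05),
                                       ncol = 2)
  expect_equal(total_force(mesh, params, pos),
               assemble_total_force(mesh, params, pos), tolerance = 1e-12)
  # grand total vanishes for random parameter draws
  for (i in 1:5) {
    p <- mechanics_params(mu_cable = runif(1, 1, 100),
                          k_bend = runif(1, 0, 100),
                          f_active = runif(1, 0, 1))
    expect_equal(colSums(total_force(mesh, p, pos)), c(0, 0),
                 tolerance = 1e-10)
  }
})

test_that("constructed ground state carries no force and no energy", {
  mesh <- small_placode()
  params <- mechanics_params()   # no bending, no activity
  expect_lt(max(abs(total_force(mesh, params))), 1e-12)
  expect_equal(total_energy(mesh, params), 0)
  # a single hexagon at rest is force-free too
  single <- build_hex_tissue(0)
  expect_lt(max(abs(total_force(single, params))), 1e-12)
})

test_that("total force is minus the gradient of total energy", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 5, k_bend = 2, f_active = 0.3)
  set.seed(11)
  pos <- mesh_positions(mesh) + matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.03),
                                       ncol = 2)
  F <- total_force(mesh, params, pos)
  h <- 1e-6
  idx <- sample(nrow(pos), 12)
  for (i in idx) for (j in 1:2) {
    up <- pos; up[i, j] <- up[i, j] + h
    dn <- pos; dn[i, j] <- dn[i, j] - h
    num <- -(total_energy(mesh, params, up) -
               total_energy(mesh, params, dn)) / (2 * h)
    expect_equal(F[i, j], num, tolerance = 1e-5)
  }
  # stretching one edge of a fresh mesh from rest 1 to 2 adds 1/2 energy
  m2 <- two_node_mesh(separation = 2)
  expect_equal(total_energy(m2, mechanics_params()), 0.5)
})

test_that("force field is rotation-equivariant and translation-invariant", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 10, k_bend = 5, f_active = 0.2)
  set.seed(3)
  pos <- mesh_positions(mesh) + matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.05),
                                       ncol = 2)
  F <- total_force(mesh, params, pos)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(total_force(mesh, params, pos %*% t(R)), F %*% t(R),
               tolerance = 1e-9)
  shift <- matrix(c(2.5, -0.7), nrow(pos), 2, byrow = TRUE)
  expect_equal(total_force(mesh, params, pos + shift), F, tolerance = 1e-9)
})

test_that("a neutral cable is mechanically invisible", {
  mesh <- small_placode()
  neutral <- mechanics_params(mu_cable = 1, k_bend = 0)
  untagged <- mesh
  untagged$edges$is_cable <- FALSE
  untagged$cable_loop <- integer(0)
  set.seed(5)
  pos <- mesh_positions(mesh) + matrix(rnorm(2 * nrow(mesh$nodes), 0, 0.05),
                                       ncol = 2)
  expect_identical(total_force(mesh, neutral, pos),
                   total_force(untagged, neutral, pos))
})

test_that("parameter validation rejects nonphysical values", {
  expect_error(mechanics_params(mu_cable = -1), "positive")
  expect_error(mechanics_params(k_bend = -0.1), "non-negative")
  expect_error(mechanics_params(eta = 0), "positive")
  expect_error(mechanics_params(mu_default = NA), "non-finite")
})
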