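#' Mechanics parameter set
#'
#' Physical constants of the model, in model units (length unit = initial
#' junctional edge rest length; force unit = modulus x length).
#'
#' @param mu_default Spring constant of ordinary (non-cable) edges.
#' @param mu_cable Spring constant of cable edges; the swept stiffness.
#' @param k_bend Bending coefficient on the cable: penalty
#'   `(k_bend/2) * (theta - pi)^2` on the angle `theta` between adjacent
#'   cable edges, giving a restoring force of magnitude
#'   `k_bend * (theta - pi)`.
#' @param f_active Constant contractile tension on active edges.
#' @param eta Viscous friction factor of the over-damped dynamics
#'   `eta * dx/dt = F`.
#' @return A `mechanics_params` object (named list).
#' @export
mechanics_params <- function(mu_default = 1, mu_cable = 1, k_bend = 0,
                             f_active = 0, eta = 1) {
  p <- list(mu_default = mu_default, mu_cable = mu_cable, k_bend = k_bend,
            f_active = f_active, eta = eta)
  bad <- !vapply(p, function(v) length(v) == 1L && is.finite(v), logical(1))
  if (any(bad))
    stop("non-finite or non-scalar parameter: ",
         paste(names(p)[bad], collapse = ", "))
  if (mu_default <= 0 || mu_cable <= 0 || eta <= 0)
    stop("mu_default, mu_cable and eta must be positive")
  if (k_bend < 0 || f_active < 0)
    stop("k_bend and f_active must be non-negative")
  structure(p, class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat(sprintf(
    "<mechanics_params> mu_default=%g mu_cable=%g k_bend=%g f_active=%g eta=%g\n",
    x$mu_default, x$mu_cable, x$k_bend, x$f_active, x$eta))
  invisible(x)
}

#' Hookean spring force pair
#'
#' Linear restoring force of one elastic edge: each endpoint receives a
#' force of magnitude `modulus * |l - rest_length|` along the edge,
#' directed so as to restore the rest length. The two forces are equal and
#' opposite.
#'
#' @param p_a,p_b Endpoint positions (length-2 numeric vectors).
#' @param rest_length Edge rest length (positive).
#' @param modulus Spring constant.
#' @return A `2 x 2` matrix; row 1 the force on `p_a`, row 2 on `p_b`.
#' @export
spring_force <- function(p_a, p_b, rest_length, modulus = 1) {
  d <- p_b - p_a
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("degenerate geometry: coincident spring endpoints")
  f <- modulus * (len - rest_length) * d / len
  rbind(f, -f, deparse.level = 0)
}

#' Active contraction force pair
#'
#' Constant tension on an actively constricting edge: each endpoint is
#' pulled toward the other with force magnitude `f_active`, independent of
#' edge length.
#'
#' @inheritParams spring_force
#' @param f_active Contractile tension (non-negative).
#' @return A `2 x 2` matrix; row 1 the force on `p_a`, row 2 on `p_b`.
#' @export
active_force <- function(p_a, p_b, f_active) {
  d <- p_b - p_a
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("degenerate geometry: coincident active-edge endpoints")
  f <- f_active * d / len
  rbind(f, -f, deparse.level = 0)
}

#' Discrete bending force on a cable triplet
#'
#' Exact negative gradient, with respect to the three node positions, of
#' the bending energy `(k_bend/2) * (theta - pi)^2`, where `theta` is the
#' interior angle at `p_node` between the edges to `p_prev` and `p_next`.
#' The resulting force magnitude at straightening is `k_bend * (theta -
#' pi)`; collinear triplets carry no force. Because the energy is
#' invariant under translation and rotation, the three forces sum to zero
#' and carry zero net torque.
#'
#' @param p_prev,p_node,p_next Positions of the three consecutive cable
#'   nodes (length-2 numeric vectors).
#' @param k_bend Bending coefficient.
#' @return A `3 x 2` matrix of forces on `p_prev`, `p_node`, `p_next`.
#' @export
bending_force <- function(p_prev, p_node, p_next, k_bend) {
  a <- p_prev - p_node
  b <- p_next - p_node
  a2 <- sum(a^2)
  b2 <- sum(b^2)
  if (a2 < 1e-24 || b2 < 1e-24)
    stop("degenerate geometry: zero-length edge in bending triplet")
  crossz <- a[1] * b[2] - a[2] * b[1]
  theta <- atan2(abs(crossz), sum(a * b))
  sgn <- if (crossz >= 0) 1 else -1
  coef <- -k_bend * (theta - pi) * sgn
  g_prev <- c(a[2], -a[1]) / a2
  g_next <- c(-b[2], b[1]) / b2
  rbind(coef * g_prev,
        -coef * (g_prev + g_next),
        coef * g_next, deparse.level = 0)
}

# consecutive (prev, node, next) node-id triplets along the cable loop,
# as a 0-based integer matrix (one row per cable node)
cable_triplets <- function(mesh) {
  loop <- mesh$cable_loop
  n <- length(loop)
  if (n == 0L)
    return(matrix(integer(0), ncol = 3L))
  idx <- seq_len(n)
  cbind(loop[c(n, idx[-n])], loop, loop[c(idx[-1L], 1L)])
}

# per-edge effective moduli and tensions under a parameter set
edge_coefficients <- function(mesh, params, with_active = TRUE) {
  mod <- ifelse(mesh$edges$is_cable, params$mu_cable, params$mu_default)
  tension <- if (with_active && params$f_active > 0)
    ifelse(mesh$edges$is_active, params$f_active, 0) else
    numeric(nrow(mesh$edges))
  list(mod = mod, tension = tension)
}

#' Total force field on a tissue mesh
#'
#' Per node, the sum of spring forces from all incident edges (cable
#' edges use `mu_cable`, others `mu_default`), bending forces from every
#' cable triplet the node takes part in, and, when `with_active`, the
#' constant contractile tension of incident active edges. Because every
#' constituent is an internal action--reaction pair (or triplet), the
#' grand total over all nodes vanishes.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [mechanics_params()] object.
#' @param positions Optional `n x 2` position matrix (defaults to the
#'   mesh coordinates).
#' @param with_active Include active-edge tensions? Default `TRUE`.
#' @return An `n x 2` matrix of per-node forces.
#' @export
total_force <- function(mesh, params, positions = mesh_positions(mesh),
                        with_active = TRUE) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(params, "mechanics_params"))
  co <- edge_coefficients(mesh, params, with_active)
  cpp_forces(positions, mesh$edges$from, mesh$edges$to,
             mesh$edges$rest_length, co$mod, co$tension,
             cable_triplets(mesh), params$k_bend)
}

#' Total mechanical energy of a tissue mesh
#'
#' The scalar whose negative position-gradient is [total_force()]:
#' `sum (modulus/2)(l - l0)^2` over edges, plus
#' `sum (k_bend/2)(theta - pi)^2` over cable triplets, plus
#' `sum f_active * l` over active edges (when `with_active`).
#'
#' @inheritParams total_force
#' @return A single number.
#' @export
total_energy <- function(mesh, params, positions = mesh_positions(mesh),
                         with_active = TRUE) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(params, "mechanics_params"))
  co <- edge_coefficients(mesh, params, with_active)
  cpp_energy(positions, mesh$edges$from, mesh$edges$to,
             mesh$edges$rest_length, co$mod, co$tension,
             cable_triplets(mesh), params$k_bend)
}
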