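# Small meshes and hand-built fixtures shared across test files.

# compact tagged placode: 37 cells, cable between coronae 2 and 3,
# single-cell active core
small_placode <- function() placode_mesh(n_coronae = 3, cable_after_corona = 2,
                                         core_coronae = 0)

# a bare two-node, one-edge mesh for closed-form spring dynamics
two_node_mesh <- function(separation = 2, rest_length = 1) {
  nodes <- data.frame(id = 0:1, x = c(0, separation), y = c(0, 0),
                      kind = "junctional", region = NA_character_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = 0L, from = 0L, to = 1L, kind = "junction",
                      rest_length = rest_length, modulus = 1,
                      is_cable = FALSE, is_active = FALSE,
                      stringsAsFactors = FALSE)
  cells <- data.frame(id = integer(0), corona = integer(0),
                      centre_node = integer(0), region = character(0),
                      stringsAsFactors = FALSE)
  cells$boundary <- list()
  structure(list(nodes = nodes, edges = edges, cells = cells,
                 cable_loop = integer(0), centre = c(0, 0),
                 n_coronae = 0L, edge_length = 1,
                 cable_after_corona = NA_integer_,
                 core_coronae = NA_integer_),
            class = "tissue_mesh")
}

# independent brute-force count of hexagonal-lattice cells within n coronae
brute_force_cell_count <- function(n) {
  qr <- expand.grid(q = -n:n, r = -n:n)
  sum((abs(qr$q) + abs(qr$r) + abs(qr$q + qr$r)) / 2 <= n)
}

# independent finite-difference gradient of the bending energy
# (k/2) (theta - pi)^2 for a triplet, as a 3 x 2 matrix of forces
fd_bending_force <- function(p_prev, p_node, p_next, k, h = 1e-6) {
  energy <- function(pp, pn, px) {
    a <- pp - pn
    b <- px - pn
    theta <- atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b))
    0.5 * k * (theta - pi)^2
  }
  pts <- list(p_prev, p_node, p_next)
  out <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    up <- pts; up[[i]][j] <- up[[i]][j] + h
    dn <- pts; dn[[i]][j] <- dn[[i]][j] - h
    out[i, j] <- -(energy(up[[1]], up[[2]], up[[3]]) -
                     energy(dn[[1]], dn[[2]], dn[[3]])) / (2 * h)
  }
  out
}

# total force assembled edge-by-edge from the exported per-element
# operations; an independent route to the vectorised implementation
assemble_total_force <- function(mesh, params, positions = mesh_positions(mesh),
                                 with_active = TRUE) {
  F <- matrix(0, nrow(mesh$nodes), 2)
  for (i in seq_len(nrow(mesh$edges))) {
    e <- mesh$edges[i, ]
    mod <- if (e$is_cable) params$mu_cable else params$mu_default
    fp <- spring_force(positions[e$from + 1, ], positions[e$to + 1, ],
                       e$rest_length, mod)
    F[e$from + 1, ] <- F[e$from + 1, ] + fp[1, ]
    F[e$to + 1, ] <- F[e$to + 1, ] + fp[2, ]
    if (with_active && e$is_active && params$f_active > 0) {
      fa <- active_force(positions[e$from + 1, ], positions[e$to + 1, ],
                         params$f_active)
      F[e$from + 1, ] <- F[e$from + 1, ] + fa[1, ]
      F[e$to + 1, ] <- F[e$to + 1, ] + fa[2, ]
    }
  }
  loop <- mesh$cable_loop
  if (length(loop) && params$k_bend > 0) {
    n <- length(loop)
    for (j in seq_len(n)) {
      prev <- loop[if (j == 1) n else j - 1]
      node <- loop[j]
      nxt <- loop[if (j == n) 1 else j + 1]
      fb <- bending_force(positions[prev + 1, ], positions[node + 1, ],
                          positions[nxt + 1, ], params$k_bend)
      F[prev + 1, ] <- F[prev + 1, ] + fb[1, ]
      F[node + 1, ] <- F[node + 1, ] + fb[2, ]
      F[nxt + 1, ] <- F[nxt + 1, ] + fb[3, ]
    }
  }
  F
}
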