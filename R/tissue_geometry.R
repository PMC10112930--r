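#' Build a hexagonal tissue mesh
#'
#' Constructs the model substrate: a patch of regular hexagonal cells
#' arranged in concentric coronae around a single central cell (corona 0;
#' corona `c` holds `6*c` cells, so `n` coronae give `3*n*(n+1)+1` cells).
#' Each cell has six junctional corner nodes, shared with its neighbours,
#' and one central node joined to the corners by radial "spoke" edges.
#' All edges start at their rest length, so the freshly built mesh carries
#' no force. The model length unit is the initial junctional edge length.
#'
#' @param n_coronae Number of cell coronae around the central cell
#'   (default 6, giving the 127-cell tissue).
#' @param edge_length Initial (and rest) length of junctional edges.
#' @return A `tissue_mesh` object: a list with data frames `nodes`
#'   (`id`, `x`, `y`, `kind`, `region`), `edges` (`id`, `from`, `to`,
#'   `kind`, `rest_length`, `modulus`, `is_cable`, `is_active`), `cells`
#'   (`id`, `corona`, `centre_node`, `region`, and list column `boundary`
#'   of counter-clockwise corner node ids), the cyclic `cable_loop` node
#'   id vector (empty until [tag_regions()] is called) and the tissue
#'   `centre`. All ids are 0-based so that the JSON serialization
#'   ([write_mesh_json()]) is unambiguous.
#' @seealso [tag_regions()], [select_active_elements()]
#' @examples
#' mesh <- build_hex_tissue(2)
#' nrow(mesh$cells)  # 19
#' @export
build_hex_tissue <- function(n_coronae = 6L, edge_length = 1) {
  if (length(n_coronae) != 1L || is.na(n_coronae) || n_coronae < 0 ||
      n_coronae != round(n_coronae))
    stop("`n_coronae` must be a single non-negative integer")
  if (length(edge_length) != 1L || !is.finite(edge_length) || edge_length <= 0)
    stop("`edge_length` must be a single positive number")
  n_coronae <- as.integer(n_coronae)
  s <- edge_length

  # axial cell coordinates of all cells with hex distance <= n_coronae
  qr <- expand.grid(q = -n_coronae:n_coronae, r = -n_coronae:n_coronae)
  corona <- (abs(qr$q) + abs(qr$r) + abs(qr$q + qr$r)) / 2L
  keep <- corona <= n_coronae
  qr <- qr[keep, , drop = FALSE]
  corona <- as.integer(corona[keep])

  # pointy-top layout: neighbouring cell centres are sqrt(3)*s apart
  cx <- sqrt(3) * s * (qr$q + qr$r / 2)
  cy <- 1.5 * s * qr$r
  ord <- order(corona, round(atan2(cy, cx), 9), round(cx, 9))
  cx <- cx[ord]; cy <- cy[ord]; corona <- corona[ord]
  n_cells <- length(cx)

  # corner offsets, counter-clockwise starting at 30 degrees
  ang <- pi / 6 + (0:5) * pi / 3
  offx <- s * cos(ang)
  offy <- s * sin(ang)

  vx <- as.vector(outer(offx, cx, `+`))  # 6 corners per cell, cell-major
  vy <- as.vector(outer(offy, cy, `+`))
  # "+ 0" turns -0 into +0 so shared corners straddling an axis dedupe
  coord_key <- function(x, y)
    paste(sprintf("%.6f", round(x, 6) + 0), sprintf("%.6f", round(y, 6) + 0))
  key <- coord_key(vx, vy)
  ukey <- !duplicated(key)
  jx <- vx[ukey]; jy <- vy[ukey]
  jord <- order(round(jy, 6), round(jx, 6))
  jx <- jx[jord]; jy <- jy[jord]
  n_junc <- length(jx)
  # 0-based junctional node id for every cell corner
  corner_node <- match(key, coord_key(jx, jy)) - 1L
  corner_node <- matrix(corner_node, nrow = 6L)  # [corner, cell]

  centre_node <- n_junc + seq_len(n_cells) - 1L
  nodes <- data.frame(
    id = 0:(n_junc + n_cells - 1L),
    x = c(jx, cx), y = c(jy, cy),
    kind = rep(c("junctional", "cell-centre"), c(n_junc, n_cells)),
    region = NA_character_,
    stringsAsFactors = FALSE)

  # junction edges: consecutive corners of each cell, deduplicated
  from6 <- corner_node
  to6 <- corner_node[c(2:6, 1L), , drop = FALSE]
  jfrom <- pmin(from6, to6)
  jto <- pmax(from6, to6)
  jpair <- unique(data.frame(from = as.vector(jfrom), to = as.vector(jto)))
  jpair <- jpair[order(jpair$from, jpair$to), , drop = FALSE]

  # spokes: cell centre to each corner
  sfrom <- rep(centre_node, each = 6L)
  sto <- as.vector(corner_node)

  efrom <- c(jpair$from, sfrom)
  eto <- c(jpair$to, sto)
  # in a regular hexagon both the sides and the centre-to-corner spokes
  # have length s, so rest lengths are exact by construction
  edges <- data.frame(
    id = seq_along(efrom) - 1L,
    from = efrom, to = eto,
    kind = rep(c("junction", "spoke"), c(nrow(jpair), length(sfrom))),
    rest_length = s,
    modulus = 1,
    is_cable = FALSE,
    is_active = FALSE,
    stringsAsFactors = FALSE)

  cells <- data.frame(
    id = seq_len(n_cells) - 1L,
    corona = corona,
    centre_node = centre_node,
    region = NA_character_,
    stringsAsFactors = FALSE)
  cells$boundary <- lapply(seq_len(n_cells), function(i) corner_node[, i])

  mesh <- structure(list(
    nodes = nodes, edges = edges, cells = cells,
    cable_loop = integer(0),
    centre = c(0, 0),
    n_coronae = n_coronae,
    edge_length = edge_length,
    cable_after_corona = NA_integer_,
    core_coronae = NA_integer_), class = "tissue_mesh")
  mesh
}

#' Tag cable, interior and exterior regions of a tissue mesh
#'
#' Flags the closed loop of junctional edges separating the cell patch
#' `corona <= cable_after_corona` from the cells beyond it as the
#' supracellular cable, orders the loop counter-clockwise, and tags cells
#' and nodes by side. With the defaults (`n_coronae = 6`,
#' `cable_after_corona = 4`) the cable encloses 61 cells and leaves two
#' complete coronae (66 cells) outside it, representing the surrounding
#' epidermis.
#'
#' @param mesh A `tissue_mesh` from [build_hex_tissue()].
#' @param cable_after_corona Cable lies between this corona and the next
#'   (default 4). Must be smaller than the mesh's `n_coronae` so at least
#'   one corona lies outside the cable.
#' @return The mesh with `is_cable` flags, `cable_loop`, cell regions
#'   (`interior`/`exterior`) and node regions (`interior`/`exterior`/
#'   `cable`) filled in.
#' @export
tag_regions <- function(mesh, cable_after_corona = 4L) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (length(cable_after_corona) != 1L || is.na(cable_after_corona) ||
      cable_after_corona < 0 || cable_after_corona != round(cable_after_corona))
    stop("`cable_after_corona` must be a single non-negative integer")
  if (cable_after_corona >= mesh$n_coronae)
    stop("`cable_after_corona` must be < n_coronae (no corona would lie ",
         "outside the cable)")
  cable_after_corona <- as.integer(cable_after_corona)

  inside_cell <- mesh$cells$corona <= cable_after_corona
  mesh$cells$region <- ifelse(inside_cell, "interior", "exterior")

  # per-edge counts of incident inside/outside cells
  ec <- edge_cell_incidence(mesh)
  n_in <- tabulate(ec$edge[inside_cell[ec$cell + 1L]] + 1L,
                   nbins = nrow(mesh$edges))
  n_out <- tabulate(ec$edge[!inside_cell[ec$cell + 1L]] + 1L,
                    nbins = nrow(mesh$edges))
  is_cable <- mesh$edges$kind == "junction" & n_in == 1L & n_out == 1L
  mesh$edges$is_cable <- is_cable
  mesh$cable_loop <- order_cable_loop(mesh)

  # node tags: cable nodes first, the rest by the side of their cells
  reg <- rep(NA_character_, nrow(mesh$nodes))
  cable_nodes <- unique(c(mesh$edges$from[is_cable], mesh$edges$to[is_cable]))
  node_cell <- node_cell_incidence(mesh)
  node_inside <- tapply(inside_cell[node_cell$cell + 1L], node_cell$node, any)
  junc <- mesh$nodes$kind == "junctional"
  reg[junc] <- ifelse(node_inside[as.character(mesh$nodes$id[junc])],
                      "interior", "exterior")
  reg[mesh$nodes$kind == "cell-centre"] <-
    mesh$cells$region[match(mesh$nodes$id[mesh$nodes$kind == "cell-centre"],
                            mesh$cells$centre_node)]
  reg[cable_nodes + 1L] <- "cable"
  mesh$nodes$region <- reg
  mesh$cable_after_corona <- cable_after_corona
  mesh
}

#' Select the actively constricting core
#'
#' Tags the central cells (corona `<= core_coronae`, default the central
#' cell plus its first corona: seven cells) as the constricting core that
#' emulates the forming invagination pit. All junctional edges and spokes
#' of core cells are flagged active; during [run_contraction()] they carry
#' the constant contractile tension `f_active`. Additional edges can be
#' flagged through `extra_edges`.
#'
#' @param mesh A tagged `tissue_mesh` (see [tag_regions()]).
#' @param core_coronae Coronae included in the active core (default 1).
#' @param extra_edges Integer vector of extra edge ids to flag active.
#' @return The mesh with cell regions set to `"core"` and `is_active`
#'   flags filled in.
#' @export
select_active_elements <- function(mesh, core_coronae = 1L,
                                   extra_edges = integer(0)) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (is.na(mesh$cable_after_corona))
    stop("mesh has no tagged regions; call tag_regions() first")
  if (length(core_coronae) != 1L || is.na(core_coronae) || core_coronae < 0 ||
      core_coronae != round(core_coronae))
    stop("`core_coronae` must be a single non-negative integer")
  if (core_coronae > mesh$cable_after_corona)
    stop("`core_coronae` must not exceed `cable_after_corona`: the core ",
         "must lie inside the cable")
  core_coronae <- as.integer(core_coronae)
  if (length(extra_edges) > 0 &&
      (anyNA(extra_edges) || !all(extra_edges %in% mesh$edges$id)))
    stop("`extra_edges` contains edge ids not present in the mesh")

  core <- mesh$cells$corona <= core_coronae
  mesh$cells$region[core] <- "core"
  core_nodes <- c(unlist(mesh$cells$boundary[core]),
                  mesh$cells$centre_node[core])
  active <- (mesh$edges$from %in% core_nodes) &
    (mesh$edges$to %in% core_nodes)
  # spokes of non-core cells can share their junctional endpoint with the
  # core flower but never their centre node, so the filter above keeps
  # exactly the flower's own edges
  active[mesh$edges$id %in% extra_edges] <- TRUE
  mesh$edges$is_active <- active
  mesh$core_coronae <- core_coronae
  mesh
}

#' Default placode mesh
#'
#' Convenience wrapper chaining [build_hex_tissue()], [tag_regions()] and
#' [select_active_elements()] with the default study layout: 127 cells,
#' cable between coronae 4 and 5 (61 cells inside, 66 outside), and a
#' 7-cell active core.
#'
#' @inheritParams build_hex_tissue
#' @inheritParams tag_regions
#' @inheritParams select_active_elements
#' @return A fully tagged `tissue_mesh`.
#' @export
placode_mesh <- function(n_coronae = 6L, cable_after_corona = 4L,
                         core_coronae = 1L, edge_length = 1,
                         extra_edges = integer(0)) {
  mesh <- build_hex_tissue(n_coronae, edge_length)
  mesh <- tag_regions(mesh, cable_after_corona)
  select_active_elements(mesh, core_coronae, extra_edges)
}

# (edge id, cell id) incidence pairs for junction edges, both 0-based
edge_cell_incidence <- function(mesh) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  from6 <- do.call(cbind, mesh$cells$boundary)
  to6 <- from6[c(2:6, 1L), , drop = FALSE]
  jun <- mesh$edges$kind == "junction"
  eid <- mesh$edges$id[jun]
  emap <- structure(eid, names = pair_key(mesh$edges$from[jun],
                                          mesh$edges$to[jun]))
  data.frame(
    edge = as.integer(emap[pair_key(as.vector(from6), as.vector(to6))]),
    cell = rep(mesh$cells$id, each = 6L))
}

# (node id, cell id) incidence for junctional corner nodes, 0-based
node_cell_incidence <- function(mesh) {
  data.frame(node = unlist(mesh$cells$boundary),
             cell = rep(mesh$cells$id, lengths(mesh$cells$boundary)))
}

# order the flagged cable edges into one closed counter-clockwise loop
order_cable_loop <- function(mesh) {
  ce <- mesh$edges[mesh$edges$is_cable, , drop = FALSE]
  if (nrow(ce) == 0L) return(integer(0))
  nbr <- split(c(ce$to, ce$from), c(ce$from, ce$to))
  deg <- lengths(nbr)
  if (any(deg != 2L))
    stop("cable edges do not form a single closed loop ",
         "(a node has ", max(deg), " incident cable edges)")
  start <- min(as.integer(names(nbr)))
  loop <- integer(length(nbr))
  loop[1L] <- start
  prev <- -1L
  cur <- start
  for (i in seq_along(nbr)[-1L]) {
    nxt <- nbr[[as.character(cur)]]
    nxt <- nxt[nxt != prev][1L]
    loop[i] <- nxt
    prev <- cur
    cur <- nxt
  }
  last_nbrs <- nbr[[as.character(cur)]]
  if (!(start %in% last_nbrs))
    stop("cable edges do not close into a loop")
  # orient counter-clockwise (positive shoelace area)
  x <- mesh$nodes$x[loop + 1L]
  y <- mesh$nodes$y[loop + 1L]
  area2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
  if (area2 < 0) loop <- rev(loop)
  loop
}

#' Node positions of a mesh
#'
#' @param mesh A `tissue_mesh`.
#' @return An `n x 2` matrix of node positions ordered by node id.
#' @export
mesh_positions <- function(mesh) {
  cbind(x = mesh$nodes$x, y = mesh$nodes$y)
}

#' Replace node positions of a mesh
#'
#' @param mesh A `tissue_mesh`.
#' @param positions An `n x 2` matrix ordered by node id.
#' @return The mesh with updated node coordinates.
#' @export
set_mesh_positions <- function(mesh, positions) {
  stopifnot(is.matrix(positions), nrow(positions) == nrow(mesh$nodes),
            ncol(positions) == 2L, all(is.finite(positions)))
  mesh$nodes$x <- positions[, 1L]
  mesh$nodes$y <- positions[, 2L]
  mesh
}

#' Current edge lengths
#'
#' @param mesh A `tissue_mesh`.
#' @param positions Optional `n x 2` position matrix (defaults to the
#'   mesh's own coordinates).
#' @return Numeric vector of edge lengths ordered by edge id.
#' @export
edge_lengths <- function(mesh, positions = mesh_positions(mesh)) {
  dx <- positions[mesh$edges$to + 1L, 1L] - positions[mesh$edges$from + 1L, 1L]
  dy <- positions[mesh$edges$to + 1L, 2L] - positions[mesh$edges$from + 1L, 2L]
  sqrt(dx^2 + dy^2)
}

#' Cell apical areas
#'
#' Shoelace area of each cell's junctional polygon (positive for the
#' counter-clockwise boundaries the builder produces).
#'
#' @inheritParams edge_lengths
#' @return Numeric vector of polygon areas ordered by cell id.
#' @export
cell_areas <- function(mesh, positions = mesh_positions(mesh)) {
  vapply(mesh$cells$boundary, function(b) {
    x <- positions[b + 1L, 1L]
    y <- positions[b + 1L, 2L]
    sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
  }, numeric(1))
}

#' Total cable circumference
#'
#' @inheritParams edge_lengths
#' @return Sum of current cable edge lengths.
#' @export
cable_circumference <- function(mesh, positions = mesh_positions(mesh)) {
  sum(edge_lengths(mesh, positions)[mesh$edges$is_cable])
}

#' Outer rim junctional node ids
#'
#' Junction edges belonging to exactly one cell form the free outer rim of
#' the tissue; this returns the ids of their endpoint nodes.
#'
#' @param mesh A `tissue_mesh`.
#' @return Integer vector of 0-based node ids.
#' @export
rim_nodes <- function(mesh) {
  ec <- edge_cell_incidence(mesh)
  n_cells_per_edge <- tabulate(ec$edge + 1L, nbins = nrow(mesh$edges))
  rim <- mesh$edges$kind == "junction" & n_cells_per_edge == 1L
  sort(unique(c(mesh$edges$from[rim], mesh$edges$to[rim])))
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("<tissue_mesh> ", nrow(x$cells), " cells, ",
      sum(x$nodes$kind == "junctional"), " junctional nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (length(x$cable_loop)) {
    cat("  cable: ", sum(x$edges$is_cable), " edges after corona ",
        x$cable_after_corona, "; interior/exterior cells: ",
        sum(x$cells$region %in% c("interior", "core")), "/",
        sum(x$cells$region == "exterior"), "\n", sep = "")
  } else cat("  regions untagged\n")
  if (!is.na(x$core_coronae))
    cat("  active core: ", sum(x$cells$region == "core"), " cells, ",
        sum(x$edges$is_active), " active edges\n", sep = "")
  invisible(x)
}
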