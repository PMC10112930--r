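#' Classify mesh nodes by side of the cable
#'
#' Labels every node `"inside"`, `"outside"` or `"cable"`. Junctional
#' non-cable nodes are classified by point-in-polygon containment against
#' the cable loop (via [mgcv::in.out()]); cable nodes are labelled
#' `"cable"`; cell-centre nodes inherit their cell's side.
#'
#' @param mesh A tagged `tissue_mesh`.
#' @param positions Optional `n x 2` position matrix used for the
#'   containment test (defaults to the mesh coordinates; classification
#'   is normally done on the undeformed ground state).
#' @return Character vector, one label per node, ordered by node id.
#' @export
classify_nodes <- function(mesh, positions = mesh_positions(mesh)) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  if (length(mesh$cable_loop) == 0L)
    stop("mesh has no tagged cable loop; call tag_regions() first")
  loop_xy <- positions[mesh$cable_loop + 1L, , drop = FALSE]
  bnd <- rbind(loop_xy, loop_xy[1L, ])

  side <- rep(NA_character_, nrow(mesh$nodes))
  cable_nodes <- mesh$cable_loop
  side[cable_nodes + 1L] <- "cable"

  junc <- which(mesh$nodes$kind == "junctional" & is.na(side))
  if (length(junc)) {
    inside <- mgcv::in.out(bnd, positions[junc, , drop = FALSE])
    side[junc] <- ifelse(inside, "inside", "outside")
  }
  cen <- which(mesh$nodes$kind == "cell-centre")
  if (length(cen)) {
    inside <- mgcv::in.out(bnd, positions[cen, , drop = FALSE])
    side[cen] <- ifelse(inside, "inside", "outside")
  }
  side
}

#' Radial displacement of nodes toward the tissue centre
#'
#' For each requested node, `delta_r = |x_initial - centre| - |x_final -
#' centre|`: positive values mean the node moved toward the centre over
#' the simulation.
#'
#' @param result A `simulation_result` from [relax()] or
#'   [run_contraction()].
#' @param node_ids 0-based node ids to measure (non-empty).
#' @param centre Length-2 centre point (defaults to the origin).
#' @return List with `per_node` (named numeric vector) and `mean`.
#' @export
radial_displacement <- function(result, node_ids, centre = c(0, 0)) {
  stopifnot(inherits(result, "simulation_result"))
  if (length(node_ids) == 0L)
    stop("`node_ids` must be non-empty")
  i <- node_ids + 1L
  r0 <- sqrt((result$initial_positions[i, 1L] - centre[1L])^2 +
               (result$initial_positions[i, 2L] - centre[2L])^2)
  r1 <- sqrt((result$final_positions[i, 1L] - centre[1L])^2 +
               (result$final_positions[i, 2L] - centre[2L])^2)
  dr <- r0 - r1
  names(dr) <- node_ids
  list(per_node = dr, mean = mean(dr))
}

# junctional node ids on the requested side of the cable, with the
# "peripheral" convention selectable: all outside nodes, or only the
# outermost rim
side_node_ids <- function(mesh, side = c("outside", "inside"),
                          peripheral = c("outside", "rim")) {
  side <- match.arg(side)
  peripheral <- match.arg(peripheral)
  labels <- classify_nodes(mesh)
  ids <- mesh$nodes$id[labels == side & mesh$nodes$kind == "junctional"]
  if (side == "outside" && peripheral == "rim")
    ids <- intersect(ids, rim_nodes(mesh))
  ids
}

#' Mechanical insulation index
#'
#' Compares the mean radial movement (toward the tissue centre) of
#' junctional nodes outside the cable in a barrier simulation against the
#' same quantity in a baseline simulation run without the barrier
#' (`mu_cable = mu_default`, `k_bend = 0`), under identical active
#' forcing. `normalized_movement` is the ratio barrier/baseline and
#' `decrease = 1 - normalized_movement` is the fraction of outside-node
#' movement suppressed by the barrier.
#'
#' @param barrier_result `simulation_result` of the barrier run.
#' @param baseline_result `simulation_result` of the no-barrier run on
#'   the same mesh topology and active forcing.
#' @param mesh The tagged `tissue_mesh` both runs used.
#' @param centre Centre point for radial measurement.
#' @param peripheral `"outside"` (default) measures all junctional nodes
#'   outside the cable; `"rim"` restricts to the outermost tissue rim.
#' @return List with `normalized_movement`, `decrease`,
#'   `mean_radial_outside` (barrier run), `baseline_mean` and `n_outside`.
#' @export
insulation_index <- function(barrier_result, baseline_result, mesh,
                             centre = c(0, 0),
                             peripheral = c("outside", "rim")) {
  ids <- side_node_ids(mesh, "outside", match.arg(peripheral))
  barrier <- radial_displacement(barrier_result, ids, centre)$mean
  baseline <- radial_displacement(baseline_result, ids, centre)$mean
  if (abs(baseline) <= 1e-7)
    stop("undefined normalization: baseline mean radial movement is ",
         "indistinguishable from zero (", format(baseline), ")")
  nm <- barrier / baseline
  list(normalized_movement = nm, decrease = 1 - nm,
       mean_radial_outside = barrier, baseline_mean = baseline,
       n_outside = length(ids))
}

#' Write an insulation sweep summary as CSV
#'
#' @param summary A data frame as returned by [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_insulation_csv <- function(summary, path) {
  cols <- c("k_bend", "mu_cable", "mean_radial_outside", "mean_radial_inside",
            "n_outside", "n_inside", "normalized_movement", "decrease")
  stopifnot(all(cols %in% names(summary)))
  utils::write.csv(summary[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
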