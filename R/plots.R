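#' Plot a tissue mesh
#'
#' Draws the junctional edge network, highlighting the cable (thick dark
#' line) and the actively constricting edges (green).
#'
#' @param x A `tissue_mesh`.
#' @param positions Optional `n x 2` position matrix to draw instead of
#'   the mesh's own coordinates.
#' @param spokes Draw cell-centre spokes as well?
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tissue_mesh <- function(x, positions = mesh_positions(x),
                             spokes = FALSE, ...) {
  e <- x$edges
  if (!spokes) e <- e[e$kind == "junction", , drop = FALSE]
  graphics::plot(positions[, 1L], positions[, 2L], type = "n", asp = 1,
                 xlab = "x", ylab = "y", ...)
  seg <- function(sel, col, lwd) {
    if (!any(sel)) return(invisible())
    graphics::segments(positions[e$from[sel] + 1L, 1L],
                       positions[e$from[sel] + 1L, 2L],
                       positions[e$to[sel] + 1L, 1L],
                       positions[e$to[sel] + 1L, 2L], col = col, lwd = lwd)
  }
  seg(!e$is_cable & !e$is_active, "grey60", 1)
  seg(e$is_active & !e$is_cable, "forestgreen", 2)
  seg(e$is_cable, "black", 3)
  invisible(x)
}

#' Plot an insulation sweep summary
#'
#' Decrease in normalised outside-node radial movement against the cable
#' stiffness `mu_cable` (log axis), one curve per bending coefficient.
#'
#' @param x An `insulation_summary` from [run_sweep()].
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.insulation_summary <- function(x, ...) {
  ks <- sort(unique(x$k_bend))
  mus <- sort(unique(x$mu_cable))
  m <- sapply(ks, function(k)
    x$decrease[x$k_bend == k][order(x$mu_cable[x$k_bend == k])])
  graphics::matplot(mus, m, type = "b", log = "x", pch = 19, lty = 1,
                    xlab = expression(mu ~ "(cable stiffness)"),
                    ylab = "decrease in outside radial movement", ...)
  graphics::legend("topleft", legend = paste0("k = ", ks), col = seq_along(ks),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
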