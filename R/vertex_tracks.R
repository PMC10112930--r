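#' Specification of a synthetic vertex-track cohort
#'
#' Describes a cohort of tracked cell vertices emulating time-lapse
#' quantification around a forming invagination pit: vertices inside the
#' cable polygon drift toward the pit (about 2 um per ~10 min window in
#' the defaults), vertices outside barely move, and every observed
#' position carries isotropic Gaussian noise.
#'
#' @param n_inside,n_outside Number of tracks per side.
#' @param drift_inside,drift_outside Mean total drift toward the pit over
#'   one `window`, in um.
#' @param window Track duration in minutes (default 10.5, the interval
#'   between the two stills being compared).
#' @param sample_interval Minutes between samples (default 1.5).
#' @param noise_sd Positional noise s.d. per sample, um.
#' @param pit Pit position, um.
#' @param cable_polygon Closed polygon (matrix of x, y rows, um) marking
#'   the cable; sides are assigned by containment. Default: a regular
#'   24-gon of radius 15 um around the pit.
#' @param r_inside,r_outside Radial ranges (um, relative to the pit) from
#'   which starting positions are drawn for each side.
#' @param seed Integer seed; the generated cohort is a pure function of
#'   the spec.
#' @return A `track_cohort_spec` object.
#' @export
track_cohort_spec <- function(n_inside = 50L, n_outside = 50L,
                              drift_inside = 2, drift_outside = 0,
                              window = 10.5, sample_interval = 1.5,
                              noise_sd = 0.3, pit = c(0, 0),
                              cable_polygon = NULL,
                              r_inside = c(5, 13), r_outside = c(17, 25),
                              seed = 1L) {
  if (window <= 0) stop("`window` must be positive")
  stopifnot(n_inside >= 1, n_outside >= 1, noise_sd >= 0,
            sample_interval > 0, length(pit) == 2)
  if (is.null(cable_polygon)) {
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    cable_polygon <- cbind(pit[1L] + 15 * cos(ang), pit[2L] + 15 * sin(ang))
  }
  structure(list(n_inside = as.integer(n_inside),
                 n_outside = as.integer(n_outside),
                 drift_inside = drift_inside, drift_outside = drift_outside,
                 window = window, sample_interval = sample_interval,
                 noise_sd = noise_sd, pit = as.numeric(pit),
                 cable_polygon = cable_polygon,
                 r_inside = r_inside, r_outside = r_outside,
                 seed = as.integer(seed)),
            class = "track_cohort_spec")
}

new_vertex_track <- function(track_id, t_min, x_um, y_um, side) {
  structure(list(track_id = track_id,
                 samples = data.frame(t_min = t_min, x_um = x_um,
                                      y_um = y_um),
                 side = side),
            class = "vertex_track")
}

#' Generate a synthetic vertex-track cohort
#'
#' Inside tracks drift radially toward the pit with total noiseless drift
#' `drift_inside` over the window; outside tracks drift `drift_outside`;
#' independent isotropic Gaussian noise of s.d. `noise_sd` is added to
#' every observed sample. The cohort is fully determined by the spec's
#' seed, and side labels agree with containment of the noiseless start
#' position in the cable polygon.
#'
#' @param spec A [track_cohort_spec()].
#' @return List of `vertex_track` objects (fields `track_id`, `samples`
#'   data frame with `t_min`, `x_um`, `y_um`, and `side`).
#' @export
generate_synthetic_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_cohort_spec"))
  withr::with_seed(spec$seed, {
    times <- seq(0, spec$window, by = spec$sample_interval)
    if (max(times) < spec$window) times <- c(times, spec$window)
    one_side <- function(n, rrange, drift, side, id0) {
      lapply(seq_len(n), function(j) {
        r <- stats::runif(1, rrange[1L], rrange[2L])
        phi <- stats::runif(1, 0, 2 * pi)
        start <- spec$pit + r * c(cos(phi), sin(phi))
        # noiseless path: straight radial drift toward the pit,
        # proportional to elapsed time
        frac <- times / spec$window
        towards <- (spec$pit - start) / sqrt(sum((spec$pit - start)^2))
        x <- start[1L] + drift * frac * towards[1L] +
          stats::rnorm(length(times), 0, spec$noise_sd)
        y <- start[2L] + drift * frac * towards[2L] +
          stats::rnorm(length(times), 0, spec$noise_sd)
        # the side label always follows polygon containment; the default
        # radial ranges keep each cohort strictly on its own side
        lab <- classify_point(start, spec$cable_polygon)
        new_vertex_track(sprintf("%s_%03d", side, j + id0), times, x, y, lab)
      })
    }
    c(one_side(spec$n_inside, spec$r_inside, spec$drift_inside, "inside", 0L),
      one_side(spec$n_outside, spec$r_outside, spec$drift_outside,
               "outside", 0L))
  })
}

classify_point <- function(p, polygon) {
  bnd <- rbind(polygon, polygon[1L, ])
  if (mgcv::in.out(bnd, matrix(p, 1L))) "inside" else "outside"
}

#' Displacement of a tracked vertex toward a point
#'
#' `|x(t_start) - point| - |x(t_end) - point|`, where `t_start` is the
#' track's first sample time and `t_end` the last sample time not
#' exceeding `t_start + window`. Positive values mean net approach.
#'
#' @param track A `vertex_track`.
#' @param point Length-2 target point (the pit), um.
#' @param window Measurement window, minutes.
#' @return A single number, um.
#' @export
displacement_toward_point <- function(track, point, window = 10) {
  stopifnot(inherits(track, "vertex_track"))
  s <- track$samples
  t0 <- s$t_min[1L]
  if (max(s$t_min) - t0 < window)
    stop("insufficient span: track ", track$track_id, " covers ",
         format(max(s$t_min) - t0), " min < window ", format(window))
  iend <- max(which(s$t_min <= t0 + window))
  d0 <- sqrt((s$x_um[1L] - point[1L])^2 + (s$y_um[1L] - point[2L])^2)
  d1 <- sqrt((s$x_um[iend] - point[1L])^2 + (s$y_um[iend] - point[2L])^2)
  d0 - d1
}

#' Compare vertex displacement toward the pit by side of the cable
#'
#' Computes [displacement_toward_point()] for every usable track (tracks
#' labelled `"cable"` or `"excluded"` -- the vertices of actively
#' constricting cells -- contribute to neither side), averages per side,
#' and bootstraps a confidence interval for the inside-minus-outside
#' difference. The live-imaging analysis this mirrors was qualitative;
#' the bootstrap interval is this package's quantitative extension.
#'
#' @param tracks List of `vertex_track` objects.
#' @param pit Length-2 pit position, um.
#' @param window Measurement window, minutes (default 10).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return List with `mean_inside`, `mean_outside`, `difference`,
#'   `ci` (length-2), `n_inside`, `n_outside`.
#' @export
compare_sides <- function(tracks, pit, window = 10, n_boot = 2000L,
                          conf = 0.95, seed = 1L) {
  sides <- vapply(tracks, function(t) t$side, character(1))
  usable <- sides %in% c("inside", "outside")
  d <- vapply(tracks[usable], displacement_toward_point, numeric(1),
              point = pit, window = window)
  side <- sides[usable]
  n_in <- sum(side == "inside")
  n_out <- sum(side == "outside")
  if (n_in < 2L || n_out < 2L)
    stop("insufficient data: need at least 2 usable tracks per side ",
         "(have ", n_in, " inside, ", n_out, " outside)")
  di <- d[side == "inside"]
  do <- d[side == "outside"]
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      mean(sample(di, n_in, replace = TRUE)) -
        mean(sample(do, n_out, replace = TRUE)), numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(mean_inside = mean(di), mean_outside = mean(do),
       difference = mean(di) - mean(do),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n_inside = n_in, n_outside = n_out)
}

#' Write vertex tracks as CSV
#'
#' Long format with header `track_id,t_min,x_um,y_um,side`.
#'
#' @param tracks List of `vertex_track` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(t)
    data.frame(track_id = t$track_id, t_min = t$samples$t_min,
               x_um = t$samples$x_um, y_um = t$samples$y_um,
               side = t$side)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vertex tracks from CSV
#'
#' Expects the format of [write_tracks_csv()]; the `side` column is
#' optional and may instead be derived later from a cable polygon.
#'
#' @param path CSV file path.
#' @param cable_polygon Optional polygon (matrix of x, y rows) used to
#'   assign sides from each track's first position when the file carries
#'   no `side` column.
#' @return List of `vertex_track` objects.
#' @export
read_tracks_csv <- function(path, cable_polygon = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$track_id), function(s) {
    s <- s[order(s$t_min), ]
    side <- if ("side" %in% names(s)) s$side[1L]
      else if (!is.null(cable_polygon))
        classify_point(c(s$x_um[1L], s$y_um[1L]), cable_polygon)
      else NA_character_
    new_vertex_track(as.character(s$track_id[1L]), s$t_min, s$x_um, s$y_um,
                     side)
  })
}

#' Export a simulation result as vertex tracks
#'
#' Converts the initial and final junctional-node positions of a
#' `simulation_result` into two-sample `vertex_track` objects (one per
#' node), labelled by side of the cable, so simulation output can be fed
#' through the same displacement analysis as tracked imaging data.
#' Vertices of actively constricting core cells are labelled
#' `"excluded"`.
#'
#' @param result A `simulation_result`.
#' @param mesh The tagged `tissue_mesh` the simulation ran on.
#' @param duration Nominal track duration in minutes (default 10).
#' @return List of `vertex_track` objects.
#' @export
tracks_from_result <- function(result, mesh, duration = 10) {
  labels <- classify_nodes(mesh)
  core_nodes <- unique(unlist(
    mesh$cells$boundary[mesh$cells$region == "core"]))
  junc <- which(mesh$nodes$kind == "junctional")
  lapply(junc, function(i) {
    id <- mesh$nodes$id[i]
    side <- if (id %in% core_nodes) "excluded" else labels[i]
    new_vertex_track(sprintf("node_%04d", id), c(0, duration),
                     c(result$initial_positions[i, 1L],
                       result$final_positions[i, 1L]),
                     c(result$initial_positions[i, 2L],
                       result$final_positions[i, 2L]),
                     side)
  })
}
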