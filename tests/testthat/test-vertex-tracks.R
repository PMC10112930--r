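test_that("noiseless tracks drift straight toward the pit", {
  spec <- track_cohort_spec(n_inside = 3, n_outside = 2, noise_sd = 0,
                            drift_inside = 2, drift_outside = 0, seed = 4L)
  tracks <- generate_synthetic_tracks(spec)
  ins <- tracks[vapply(tracks, function(t) t$side, "") == "inside"]
  for (t in ins) {
    s <- t$samples
    start <- c(s$x_um[1], s$y_um[1])
    end <- c(s$x_um[nrow(s)], s$y_um[nrow(s)])
    d0 <- sqrt(sum((start - spec$pit)^2))
    d1 <- sqrt(sum((end - spec$pit)^2))
    expect_equal(d0 - d1, 2, tolerance = 1e-10)
    expect_equal(displacement_toward_point(t, spec$pit, spec$window), 2,
                 tolerance = 1e-10)
  }
  outs <- tracks[vapply(tracks, function(t) t$side, "") == "outside"]
  for (t in outs)
    expect_equal(displacement_toward_point(t, spec$pit, spec$window), 0,
                 tolerance = 1e-10)
})

test_that("seeding fully determines the cohort", {
  s1 <- generate_synthetic_tracks(track_cohort_spec(seed = 11L))
  s2 <- generate_synthetic_tracks(track_cohort_spec(seed = 11L))
  s3 <- generate_synthetic_tracks(track_cohort_spec(seed = 12L))
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]]$samples, s3[[1]]$samples))
  # generation does not disturb the session RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99); invisible(generate_synthetic_tracks(track_cohort_spec()))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("displacement respects the measurement window and geometry", {
  # tangential motion on a circle has zero displacement toward the centre
  th <- seq(0, pi / 3, length.out = 8)
  circ <- new_track <- structure(list(
    track_id = "circ",
    samples = data.frame(t_min = seq(0, 10.5, length.out = 8),
                         x_um = 7 * cos(th), y_um = 7 * sin(th)),
    side = "inside"), class = "vertex_track")
  expect_equal(displacement_toward_point(circ, c(0, 0), 10.5), 0,
               tolerance = 1e-10)
  # window shorter than the track picks the last sample inside it
  spec <- track_cohort_spec(n_inside = 1, n_outside = 1, noise_sd = 0,
                            sample_interval = 1.5, window = 10.5)
  tr <- generate_synthetic_tracks(spec)[[1]]
  d9 <- displacement_toward_point(tr, spec$pit, 10)   # last sample at 9 min
  expect_equal(d9, 2 * 9 / 10.5, tolerance = 1e-10)
  expect_error(displacement_toward_point(tr, spec$pit, 99),
               "insufficient span")
})

test_that("side labels agree with polygon containment", {
  spec <- track_cohort_spec(n_inside = 20, n_outside = 20, noise_sd = 0,
                            seed = 21L)
  tracks <- generate_synthetic_tracks(spec)
  sides <- vapply(tracks, function(t) t$side, "")
  expect_equal(sum(sides == "inside"), 20)
  expect_equal(sum(sides == "outside"), 20)
  for (t in tracks) {
    p <- c(t$samples$x_um[1], t$samples$y_um[1])
    expect_identical(cablesim:::classify_point(p, spec$cable_polygon), t$side)
  }
})

test_that("cohort analysis recovers the simulated drifts", {
  spec <- track_cohort_spec(n_inside = 50, n_outside = 50, noise_sd = 0.3,
                            drift_inside = 2, drift_outside = 0, seed = 7L)
  tracks <- generate_synthetic_tracks(spec)
  cmp <- compare_sides(tracks, spec$pit, window = spec$window, seed = 7L)
  # radial noise s.d. is ~ sqrt(2) * noise_sd (two noisy endpoints)
  se <- sqrt(2) * spec$noise_sd / sqrt(50)
  expect_lt(abs(cmp$mean_inside - 2), 3 * se)
  expect_lt(abs(cmp$mean_outside - 0), 3 * se)
  expect_lt(abs(cmp$difference - 2), 3 * sqrt(2) * se)
  expect_true(cmp$ci[1] > 0)   # interval excludes zero
  # identical cohorts give a difference straddling zero
  same <- track_cohort_spec(n_inside = 30, n_outside = 30, noise_sd = 0.3,
                            drift_inside = 1, drift_outside = 1, seed = 9L)
  cmp2 <- compare_sides(generate_synthetic_tracks(same), same$pit,
                        window = same$window, seed = 9L)
  expect_true(cmp2$ci[1] < 0 && cmp2$ci[2] > 0)
})

test_that("excluded and cable tracks contribute to neither side", {
  spec <- track_cohort_spec(n_inside = 5, n_outside = 5, noise_sd = 0,
                            seed = 3L)
  tracks <- generate_synthetic_tracks(spec)
  rogue <- tracks[[1]]
  rogue$track_id <- "rogue"
  rogue$side <- "excluded"
  rogue$samples$x_um <- rogue$samples$x_um + 500   # would wreck the means
  cmp_with <- compare_sides(c(tracks, list(rogue)), spec$pit,
                            window = spec$window, seed = 1L)
  cmp_without <- compare_sides(tracks, spec$pit, window = spec$window,
                               seed = 1L)
  expect_identical(cmp_with, cmp_without)
  few <- tracks[1:3]
  expect_error(compare_sides(few, spec$pit, window = spec$window),
               "insufficient data")
})

test_that("track CSV round-trips and classifies from a polygon", {
  spec <- track_cohort_spec(n_inside = 4, n_outside = 4, seed = 2L)
  tracks <- generate_synthetic_tracks(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tracks, path)
  back <- read_tracks_csv(path)
  expect_equal(length(back), length(tracks))
  orig <- tracks[order(vapply(tracks, function(t) t$track_id, ""))]
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$samples$x_um, orig[[i]]$samples$x_um,
                 tolerance = 1e-12)
    expect_identical(back[[i]]$side, orig[[i]]$side)
  }
  # side column dropped: recovered via the polygon
  df <- utils::read.csv(path)
  df$side <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  back2 <- read_tracks_csv(path2, cable_polygon = spec$cable_polygon)
  expect_identical(vapply(back2, function(t) t$side, ""),
                   vapply(back, function(t) t$side, ""))
})

test_that("simulation results flow through the track analysis unchanged", {
  mesh <- small_placode()
  params <- mechanics_params(mu_cable = 20, k_bend = 10, f_active = 0.4)
  ctl <- solver_controls(force_tol = 1e-6, t_max = 500)
  cal <- calibrate_ground_state(mesh, params, ctl)
  res <- run_contraction(cal, params, ctl)
  tracks <- tracks_from_result(res, cal)
  sides <- vapply(tracks, function(t) t$side, "")
  expect_setequal(unique(sides), c("inside", "outside", "cable", "excluded"))
  cmp <- compare_sides(tracks, cal$centre, window = 10, seed = 5L)
  expect_gt(cmp$difference, 0)   # inside moves more than outside
})
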