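test_that("basal plane fitting gives unit normals through the points", {
  pl <- fit_basal_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(plane_distance(c(0, 0, 0), pl), 0)

  # translation invariance of the normal
  sh <- c(5, -3, 11)
  pl2 <- fit_basal_plane(c(0, 0, 0) + sh, c(1, 0, 0) + sh, c(0, 1, 0) + sh)
  expect_equal(abs(pl2$normal), abs(pl$normal))

  # random triangles: all three points lie on the fitted plane
  set.seed(1)
  for (k in 1:25) {
    p <- matrix(rnorm(9, 0, 10), 3, 3)
    pl <- fit_basal_plane(p[1, ], p[2, ], p[3, ])
    expect_lt(max(abs(plane_distance(p, pl))), 1e-9)
    expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
  }

  expect_error(fit_basal_plane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("ring_area matches closed forms and the fan oracle", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(ring_area(sq), 1)

  hexa <- regular_polygon(6, 2)  # regular hexagon, side = circumradius = 2
  expect_equal(ring_area(hexa), 6 * sqrt(3), tolerance = 1e-12)

  # non-planar hexagon equals the independent fan-triangulation oracle
  lifted <- hexa
  lifted[3, 3] <- 1.7
  expect_equal(ring_area(lifted), fan_area_oracle(lifted), tolerance = 1e-12)

  expect_error(ring_area(hexa[1:2, ]), "at least 3")
})

test_that("ring_area is rigid-motion invariant and scales quadratically", {
  set.seed(42)
  for (k in 1:20) {
    v <- regular_polygon(6, runif(1, 1, 10))
    v[, 3] <- rnorm(6, 0, 0.5)  # lifted
    a0 <- ring_area(v)
    m <- rigid_motion()
    expect_equal(ring_area(apply_motion(v, m)), a0, tolerance = 1e-9)
    s <- runif(1, 0.5, 3)
    expect_equal(ring_area(v * s), a0 * s^2, tolerance = 1e-9)
  }
})

test_that("ring_footprint projects orthogonally onto the basal plane", {
  pl <- fit_basal_plane(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  ring <- regular_polygon(6, 3)

  fp <- ring_footprint(ring, pl)
  expect_equal(ring_area(cbind(fp, 0)), ring_area(ring), tolerance = 1e-12)

  # translating the ring along the normal leaves the footprint unchanged
  lifted <- sweep(ring, 2, c(0, 0, -10))
  expect_equal(ring_footprint(lifted, pl), fp)

  # a planar ring tilted by 30 degrees projects to area * cos(30 deg)
  tilt <- pi / 6
  rot_x <- rbind(c(1, 0, 0), c(0, cos(tilt), -sin(tilt)),
                 c(0, sin(tilt), cos(tilt)))
  tilted <- ring %*% t(rot_x)
  fp_t <- ring_footprint(tilted, pl)
  expect_equal(ring_area(cbind(fp_t, 0)), ring_area(ring) * cos(tilt),
               tolerance = 1e-12)
})

test_that("plane_distance is the signed orthogonal distance", {
  pl <- fit_basal_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                        apical_hint = c(0, 0, 1))
  expect_equal(plane_distance(c(0, 0, 5), pl), 5)
  expect_equal(plane_distance(c(3, -2, 0), pl), 0)

  # random cases match a least-squares oracle: distance = min over the plane
  set.seed(5)
  for (k in 1:10) {
    p <- matrix(rnorm(9, 0, 5), 3, 3)
    pl <- fit_basal_plane(p[1, ], p[2, ], p[3, ])
    q <- rnorm(3, 0, 5)
    # oracle: minimize |q - (p1 + a e1 + b e2)| over (a, b)
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    basis <- cbind(e1, e2)
    ab <- solve(crossprod(basis), crossprod(basis, q - p[1, ]))
    resid <- q - (p[1, ] + basis %*% ab)[, 1]
    expect_equal(abs(plane_distance(q, pl)), sqrt(sum(resid^2)),
                 tolerance = 1e-9)
  }
})

test_that("detect_pulses handles degenerate series", {
  t <- seq(0, 100, by = 10)
  p <- detect_pulses(t, 100 - t)          # strict linear decrease
  expect_equal(nrow(p), 1L)
  expect_equal(p$kind, "constriction")
  expect_equal(p$start_min, 0)
  expect_equal(p$end_min, 100)

  p2 <- detect_pulses(t, rep(50, length(t)))  # constant series
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$kind, "relaxation")

  expect_error(detect_pulses(t[1:2], c(1, 2)), "at least 3")
  expect_error(detect_pulses(t, 100 - t, window = 99), "window larger")
})

test_that("zero-noise ratchet schedules are recovered exactly with rates", {
  # frame-aligned schedule: 11 segments x 30 min at 7.5 min sampling
  cfg <- sim_config(rng_seed = 1, frame_interval_min = 7.5, n_frames = 70)
  ex <- generate_extrusion_event(cfg, 30, 330, 6)
  rs <- ring_series(ex$rings)
  p <- detect_pulses(rs$t_min, rs$area)
  expect_equal(sum(p$kind == "constriction"), 6L)
  expect_equal(p$kind, ex$truth$segments$kind)
  expect_lt(max(abs(p$mean_rate_um2_min - ex$truth$segments$rate_um2_min) /
                  abs(ex$truth$segments$rate_um2_min)), 0.05)

  # alternation and time conservation
  expect_true(all(p$kind[-1] != p$kind[-nrow(p)]))
  expect_equal(sum(p$end_min - p$start_min), max(rs$t_min) - min(rs$t_min))
  expect_equal(sum(p$area_change_um2), rs$area[length(rs$area)] - rs$area[1])
})

test_that("nuclear travel kinetics: onset, peak, duration, recoil", {
  # trajectory shaped like the observed single-enterocyte extrusion:
  # flat baseline, first apparent apical movement at t = 150 min, maximal
  # displacement at t = 263 min, recoil to a plateau -> duration 113 min
  t <- c(seq(0, 142.5, by = 7.5), 150, seq(158, 263, by = 7.5), 263,
         seq(270, 330, by = 7.5))
  t <- sort(unique(t))
  d <- numeric(length(t))
  rising <- t >= 150 & t <= 263
  d[rising] <- 18 * (t[rising] - 142.5) / (263 - 142.5)
  after <- t > 263
  d[after] <- pmax(18 - 0.2 * (t[after] - 263), 10)
  tv <- nuclear_travel(t, d)
  expect_true(tv$event)
  expect_equal(tv$start_min, 150)
  expect_equal(tv$peak_min, 263)
  expect_equal(tv$duration_min, 113)
  expect_gt(tv$recoil_um, 0)

  flat <- nuclear_travel(t, rep(0.1, length(t)))
  expect_false(flat$event)
})

test_that("synthetic extrusion round trip: travel onset and peak recovered", {
  cfg <- sim_config(rng_seed = 3, frame_interval_min = 7.5, n_frames = 70,
                    intensity_noise_sd = 0,
                    extrusions = list(list(start_min = 30, closure_min = 330,
                                           n_pulses = 6)))
  gen <- generate_tracks(cfg)
  tru <- gen$truth$events$extrusions[[1]]
  cell <- gen$tracks[gen$tracks$cell_id == tru$cell_id, ]
  pls <- gen$planes[gen$planes$frame == min(gen$planes$frame), ]
  pl <- fit_basal_plane(c(pls$x_um[1], pls$y_um[1], pls$z_um[1]),
                        c(pls$x_um[2], pls$y_um[2], pls$z_um[2]),
                        c(pls$x_um[3], pls$y_um[3], pls$z_um[3]))
  dist <- plane_distance(as.matrix(cell[, c("x_um", "y_um", "z_um")]), pl)
  if (median(tail(dist, 3)) < 0) dist <- -dist  # orient apical positive
  tv <- nuclear_travel(cell$t_min, dist)
  expect_true(tv$event)
  expect_lt(abs(tv$start_min - tru$travel$rise_min), 7.5 + 1e-9)
  expect_lt(abs(tv$peak_min - tru$travel$peak_min), 7.5 + 1e-9)
  expect_equal(tv$peak_um, tru$travel$peak_um, tolerance = 0.05)
  expect_equal(tv$recoil_um, tru$travel$recoil_um, tolerance = 0.1)
})
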