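test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(stem_fraction = 0.8, eb_fraction = 0.3), "sum")
  expect_error(sim_config(stem_fraction = -0.1), "fractions")
  expect_error(sim_config(n_frames = 1), "n_frames")
  expect_error(sim_config(ratio_modes = c(0.5, 0.2)), "increasing")
  expect_error(sim_config(frame_interval_min = 0), "frame_interval_min")
})

test_that("exact-quota typing yields the configured label counts", {
  gen <- generate_tracks(sim_config(rng_seed = 2, n_cells = 100,
                                    n_frames = 5))
  counts <- table(gen$truth$cells$label)
  expect_equal(unname(counts["stem"]), 20L)          # 0.20 x 100
  expect_equal(unname(counts["enteroblast"]), 15L)
  expect_equal(unname(counts["enteroendocrine"]), 10L)
  expect_equal(unname(counts["enterocyte"]), 55L)

  # binomial mode still respects the fractions on average (sanity only)
  genb <- generate_tracks(sim_config(rng_seed = 2, n_cells = 400,
                                     n_frames = 3, field_length_um = 1300,
                                     type_assignment = "binomial"))
  frac <- mean(genb$truth$cells$label == "stem")
  expect_gt(frac, 0.12); expect_lt(frac, 0.28)
})

test_that("identical seeds give identical movies; different seeds differ", {
  a <- generate_tracks(small_config(seed = 5))
  b <- generate_tracks(small_config(seed = 5))
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  c <- generate_tracks(small_config(seed = 6))
  expect_false(identical(a$tracks, c$tracks))
})

test_that("generated volumes respect the type-specific bounds", {
  gen <- generate_tracks(sim_config(rng_seed = 4, n_cells = 150,
                                    n_frames = 4, field_length_um = 600))
  cells <- gen$truth$cells
  mature_small <- cells$label == "enteroendocrine"
  expect_true(all(cells$volume_um3[mature_small] <= 113))
  expect_true(all(cells$volume_um3[cells$label == "enterocyte"] > 113))
  expect_true(all(cells$volume_um3[cells$label %in%
                                     c("stem", "enteroblast")] <= 113))
  expect_true(all(gen$tracks$volume_um3 > 0))
})

test_that("normalized ratios equal the scheduled ratios at zero noise", {
  cfg <- small_config(seed = 7, intensity_noise_sd = 0)
  gen <- generate_tracks(cfg)
  rs <- normalize_ratios(gen$tracks)
  m <- merge(rs, gen$truth$ratios, by = c("cell_id", "frame"))
  expect_gt(nrow(m), 100L)
  expect_lt(max(abs(m$ratio - m$ratio_true)), 1e-12)
})

test_that("one cell cannot be scheduled into two events", {
  expect_error(generate_tracks(sim_config(
    rng_seed = 1, n_cells = 60, n_frames = 40,
    mitoses = list(list(cell = 1, t_condense_min = 60, duration_min = 45)),
    transitions = list(list(cell = 1, t_start_min = 60)))),
    "more than one event")
})

test_that("extrusion events encode the scheduled pulse count and closure", {
  cfg <- sim_config(rng_seed = 1, frame_interval_min = 7.5, n_frames = 70)
  ex <- generate_extrusion_event(cfg, 30, 330, 6)
  expect_equal(sum(ex$truth$segments$kind == "constriction"), 6L)
  rs <- ring_series(ex$rings)
  expect_lt(rs$area[length(rs$area)], 0.05 * rs$area[1])
  expect_equal(nrow(ex$rings) %% 6, 0L)  # six vertices per frame
  # each constriction is faster than the adjacent relaxations (pulse
  # amplitudes ride the closing ladder, so only local comparisons hold)
  segs <- ex$truth$segments
  for (k in which(segs$kind == "relaxation")) {
    expect_gt(abs(segs$rate_um2_min[k - 1]), abs(segs$rate_um2_min[k]))
    expect_gt(abs(segs$rate_um2_min[k + 1]), abs(segs$rate_um2_min[k]))
  }
  expect_error(generate_extrusion_event(cfg, 30, 10, 6), "2 frames")
  expect_error(generate_extrusion_event(cfg, 30, 330, 0), "n_pulses")
})

test_that("mitosis frame flags and daughters follow the schedule", {
  cfg <- sim_config(rng_seed = 1, frame_interval_min = 7.5, n_frames = 40)
  rec <- generate_mitosis_event(cfg, 60, 45)
  expect_length(rec$frames, 7L)  # 45 / 7.5 + 1, endpoints inclusive
  expect_equal(rec$t_decondense_min, 105)
  expect_equal(rec$daughters$birth_frame, max(rec$frames) + 1L)
  expect_equal(dim(rec$daughters$positions), c(2L, 3L))
  expect_error(generate_mitosis_event(cfg, 60, 3), "duration")

  # all-zero schedule -> all-zero recovered hv angles
  sched <- cbind(hv = rep(0, 7), lc = rep(30, 7))
  rec0 <- generate_mitosis_event(cfg, 60, 45, angle_schedule = sched)
  pl <- fit_basal_plane(rec0$plane_points[1, ], rec0$plane_points[2, ],
                        rec0$plane_points[3, ])
  hv <- vapply(rec0$poles, function(p) angle_hv(p[1, ], p[2, ], pl),
               numeric(1))
  expect_lt(max(hv), 1e-9)
})

test_that("rendering handles empty input and out-of-field centroids", {
  cfg <- small_config()
  empty <- generate_tracks(cfg)$tracks[0, ]
  rv <- render_volume(empty, cfg)
  expect_true(all(rv$stack == 0))

  tr <- data.frame(movie_id = "m", cell_id = "far", frame = 0L, t_min = 0,
                   x_um = 500, y_um = 0, z_um = 0, volume_um3 = 100,
                   cfp_raw = 0, gfp_raw = 0, rfp_raw = 100,
                   label = "enterocyte", stringsAsFactors = FALSE)
  expect_error(render_volume(tr, cfg, origin_um = c(0, 0, 0),
                             dims_zyx = c(8, 16, 16)), "far")
})

test_that("rendered nuclei are recovered by segmentation", {
  cfg <- sim_config(rng_seed = 8, voxel_size_um = c(2, 1, 1))
  one <- data.frame(movie_id = "m", cell_id = "a", frame = 0L, t_min = 0,
                    x_um = 20, y_um = 22, z_um = 15, volume_um3 = 200,
                    cfp_raw = 0, gfp_raw = 0, rfp_raw = 1000,
                    label = "enterocyte", stringsAsFactors = FALSE)
  rv <- render_volume(one, cfg)
  seg <- segment_nuclei(rv$stack[1, 3, , , ], cfg$voxel_size_um,
                        typing_config(threshold_method = "fixed",
                                      fixed_thresholds = c(rfp = 500)),
                        origin_um = rv$origin_um)
  expect_equal(nrow(seg$components), 1L)
  # centroid within one voxel of the truth
  expect_lt(abs(seg$components$x_um - 20), 1)
  expect_lt(abs(seg$components$y_um - 22), 1)
  expect_lt(abs(seg$components$z_um - 15), 2)

  # two nuclei 30 um apart -> two components
  two <- rbind(one, within(one, {cell_id <- "b"; x_um <- 50}))
  rv2 <- render_volume(two, cfg)
  seg2 <- segment_nuclei(rv2$stack[1, 3, , , ], cfg$voxel_size_um,
                         typing_config(threshold_method = "fixed",
                                       fixed_thresholds = c(rfp = 500)),
                         origin_um = rv2$origin_um)
  expect_equal(nrow(seg2$components), 2L)
})
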