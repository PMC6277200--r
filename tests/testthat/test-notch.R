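make_ratio_df <- function(cell_id, t_min, ratio, movie = "m1") {
  data.frame(movie_id = movie, cell_id = cell_id,
             frame = seq_along(t_min) - 1L, t_min = t_min, ratio = ratio,
             valid = TRUE, stringsAsFactors = FALSE)
}

test_that("normalize_ratios divides by per-movie channel maxima", {
  tr <- data.frame(movie_id = "m1", cell_id = c("a", "b"), frame = 0L,
                   t_min = 0, gfp_raw = c(10, 20), rfp_raw = c(100, 50),
                   stringsAsFactors = FALSE)
  rs <- normalize_ratios(tr)
  # cell a: (10/20) / (100/100) = 0.5
  expect_equal(rs$ratio[rs$cell_id == "a"], 0.5)
  expect_equal(rs$ratio[rs$cell_id == "b"], (20 / 20) / (50 / 100))

  # per-movie multiplicative gain invariance (exact)
  tr3 <- tr
  tr3$gfp_raw <- tr3$gfp_raw * 3
  tr3$rfp_raw <- tr3$rfp_raw * 7
  expect_equal(normalize_ratios(tr3)$ratio, rs$ratio)

  # zero RFP is flagged invalid, not an infinity
  tr0 <- tr
  tr0$rfp_raw[1] <- 0
  rs0 <- normalize_ratios(tr0)
  expect_false(rs0$valid[rs0$cell_id == "a"])
  expect_true(is.na(rs0$ratio[rs0$cell_id == "a"]))
})

test_that("pooled distributions of two movies with different gains agree", {
  mk <- function(seed, id) {
    cfg <- sim_config(rng_seed = seed, movie_id = id, n_cells = 300L,
                      n_frames = 100L, field_length_um = 1000)
    generate_tracks(cfg)$tracks
  }
  rs <- normalize_ratios(rbind(mk(21, "mvA"), mk(22, "mvB")))
  a <- rs$ratio[rs$movie_id == "mvA" & rs$valid]
  b <- rs$ratio[rs$movie_id == "mvB" & rs$valid]
  expect_gte(min(length(a), length(b)), 1e4)
  ks <- suppressWarnings(stats::ks.test(a, b)$statistic)
  expect_lt(as.numeric(ks), 0.05)
})

test_that("threshold estimation finds the between-mode density minimum", {
  # two well-separated narrow Gaussians: the analytic mixture minimum sits
  # at the symmetry point 0.5 (grid-search oracle below)
  set.seed(31)
  x <- c(rnorm(2000, 0.1, 0.02), rnorm(2000, 0.9, 0.02))
  est <- estimate_threshold(x)
  grid <- seq(0.1, 0.9, by = 1e-4)
  mix <- dnorm(grid, 0.1, 0.02) + dnorm(grid, 0.9, 0.02)
  oracle <- grid[which.min(mix)]
  expect_lt(abs(est$threshold - oracle), 0.05)
  expect_equal(est$modes[1], 0.1, tolerance = 0.05)
  expect_equal(est$modes[2], 0.9, tolerance = 0.05)

  expect_error(estimate_threshold(rnorm(5000, 0.5, 0.05)), "unimodal")
  expect_error(estimate_threshold(runif(50)), "at least 100")
})

test_that("threshold recovery works across mode separations >= 4 sd", {
  set.seed(77)
  for (sep in c(4, 6, 10)) {
    sd0 <- 0.05
    m1 <- 0.2; m2 <- m1 + sep * sd0
    x <- c(rnorm(3000, m1, sd0), rnorm(3000, m2, sd0))
    est <- estimate_threshold(x)
    grid <- seq(m1, m2, by = 1e-4)
    oracle <- grid[which.min(dnorm(grid, m1, sd0) + dnorm(grid, m2, sd0))]
    expect_lt(abs(est$threshold - oracle), 0.05)
  }
})

test_that("pooled progenitor ratios from the generator are bimodal", {
  cfg <- sim_config(rng_seed = 5, n_cells = 251L, n_frames = 116L,
                    stem_fraction = 4 / 7, eb_fraction = 3 / 7,
                    ee_fraction = 0, field_length_um = 800)
  gen <- generate_tracks(cfg)
  rs <- normalize_ratios(gen$tracks)
  est <- estimate_threshold(rs$ratio[rs$valid])
  # local minimum strictly between the two modes
  expect_gt(est$threshold, est$modes[1])
  expect_lt(est$threshold, est$modes[2])
  # modes near the configured locations (0.015, 0.528)
  expect_lt(abs(est$modes[1] - 0.015), 0.05)
  expect_lt(abs(est$modes[2] - 0.528), 0.10)
})

test_that("benchmark stem-cell fraction below threshold", {
  rs <- make_ratio_df("a", c(0, 10, 20, 30), c(0.05, 0.05, 0.05, 0.9))
  mit <- data.frame(cell_id = "a", t_condense_min = 30)
  b <- benchmark_stem_fraction(rs, mit, 0.17)
  expect_equal(b$fraction_below, 1)
  expect_equal(b$n_values, 3L)  # frames strictly before condensation
  expect_equal(b$n_cells, 1L)

  rs2 <- make_ratio_df("a", c(0, 10), c(0.1, 0.2))
  mit2 <- data.frame(cell_id = "a", t_condense_min = 20)
  expect_equal(benchmark_stem_fraction(rs2, mit2, 0.17)$fraction_below, 0.5)
  expect_error(benchmark_stem_fraction(rs2,
                                       data.frame(cell_id = "zz",
                                                  t_condense_min = 5), 0.17),
               "no pre-mitotic")
})

test_that("transition calling reproduces the worked slow-activation example", {
  # flat baseline 0.049 until 3.5 h, linear rise reaching 0.17 at 10.4 h,
  # continuing to 0.364 -> transition duration 6.9 h
  t <- seq(0, 900, by = 6)
  r <- ifelse(t <= 210, 0.049,
              pmin(0.049 + (t - 210) * (0.17 - 0.049) / (624 - 210), 0.364))
  tr <- detect_transitions(make_ratio_df("cellA", t, r), threshold = 0.17)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$status, "transition")
  expect_equal(tr$baseline_ratio, 0.049)
  expect_equal(tr$baseline_min, 210)
  expect_equal(tr$crossing_min, 624)
  expect_equal(tr$duration_hr, 6.9)

  # constant low series: no event
  none <- detect_transitions(make_ratio_df("c", t, rep(0.05, length(t))))
  expect_equal(nrow(none), 0L)

  # entirely above threshold: flagged, not scored as a transition
  high <- detect_transitions(make_ratio_df("h", t, rep(0.5, length(t))))
  expect_equal(high$status, "already_enteroblast")

  # a persistent fall from above to below is a reversion candidate
  rev <- detect_transitions(make_ratio_df("r", t,
                                          ifelse(t < 300, 0.4, 0.05)))
  expect_equal(rev$status, "reversion_candidate")

  # single-frame noise spikes are rejected by the persistence rule
  spik <- rep(0.05, length(t))
  spik[50] <- 0.3
  expect_equal(nrow(detect_transitions(make_ratio_df("s", t, spik))), 0L)
})

test_that("scheduled ramp transitions are recovered within one frame", {
  cfg <- sim_config(rng_seed = 13, n_cells = 200L, n_frames = 96L,
                    field_length_um = 700, stem_fraction = 0.45,
                    eb_fraction = 0.15, ee_fraction = 0.1,
                    intensity_noise_sd = 0,
                    transitions = lapply(1:20, function(i)
                      list(t_start_min = 60 + 15 * i)))
  gen <- generate_tracks(cfg)
  rs <- normalize_ratios(gen$tracks)
  calls <- detect_transitions(rs, threshold = 0.17)
  calls <- calls[calls$status == "transition", ]
  for (tru in gen$truth$events$transitions) {
    got <- calls[calls$cell_id == tru$cell_id, ]
    expect_equal(nrow(got), 1L)
    expect_lt(abs(got$crossing_min - tru$t_cross_017_min),
              cfg$frame_interval_min + 1e-9)
    expect_lt(abs(got$baseline_min - tru$t_start_min),
              cfg$frame_interval_min + 1e-9)
  }
})

test_that("no false transitions on a pure stem-like cohort", {
  cfg <- sim_config(rng_seed = 17, n_cells = 125L, n_frames = 60L,
                    stem_fraction = 0.8, eb_fraction = 0.1,
                    ee_fraction = 0.05, field_length_um = 600)
  gen <- generate_tracks(cfg)
  stems <- gen$truth$cells$cell_id[gen$truth$cells$label == "stem"]
  expect_gte(length(stems), 100L)
  rs <- normalize_ratios(gen$tracks)
  calls <- detect_transitions(rs, threshold = 0.17)
  fp <- calls[calls$status == "transition" & calls$cell_id %in% stems, ]
  expect_equal(nrow(fp), 0L)
})

test_that("inter-nuclear distance and contact classification", {
  expect_equal(internuclear_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(internuclear_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(3)
  for (k in 1:20) {
    p <- rnorm(3, 0, 10); q <- rnorm(3, 0, 10)
    expect_equal(internuclear_distance(p, q), sqrt(sum((q - p)^2)))
  }

  # boundary values are indeterminate; the partition is exhaustive
  expect_equal(classify_contact(c(5.9, 6.0, 10, 15.5, 15.6, 20)),
               c("contact", "indeterminate", "indeterminate",
                 "indeterminate", "separated", "separated"))
  dists <- c(0, 10^seq(-3, 3, length.out = 200))
  states <- classify_contact(dists)
  expect_true(all(states %in% c("contact", "indeterminate", "separated")))
  expect_error(classify_contact(-1), "finite")
  expect_error(contact_thresholds(16, 15.5), "smaller")
})

test_that("sibling contact timelines summarize state sequences", {
  mk_track <- function(id, x) {
    data.frame(cell_id = id, frame = seq_along(x) - 1L,
               t_min = (seq_along(x) - 1L) * 30, x_um = x, y_um = 0, z_um = 0)
  }
  # constant 5 um apart: all contact
  tl <- sibling_contact_timeline(mk_track("a", rep(0, 10)),
                                 mk_track("b", rep(5, 10)))
  expect_true(all(tl$states$state == "contact"))
  expect_equal(tl$summary$n_alternations, 0L)
  expect_false(tl$summary$permanent_separation)

  # 5 -> 20 -> 5 um: one separation run, two alternations
  x2 <- c(rep(5, 3), rep(20, 4), rep(5, 3))
  tl2 <- sibling_contact_timeline(mk_track("a", rep(0, 10)),
                                  mk_track("b", x2))
  expect_equal(tl2$summary$n_alternations, 2L)
  expect_equal(tl2$summary$longest_separation_min, 3 * 30)
  expect_false(tl2$summary$permanent_separation)

  expect_error(sibling_contact_timeline(mk_track("a", rep(0, 3)),
                                        data.frame(cell_id = "b",
                                                   frame = 10:12,
                                                   t_min = 1:3, x_um = 0,
                                                   y_um = 0, z_um = 0)),
               "share no frames|birth frame")
})

test_that("a scheduled 18-pair cohort's summaries equal ground truth", {
  states_for <- function(i) {
    # deterministic variety: high-contact, alternating, permanent separation
    switch((i %% 3) + 1,
           rep("contact", 60),
           c(rep("contact", 15), rep("separated", 20), rep("contact", 25)),
           c(rep("contact", 5 + i), rep("separated", 60)))
  }
  cfg <- sim_config(rng_seed = 29, n_cells = 40L, n_frames = 60L,
                    sibling_pairs = lapply(1:18, function(i)
                      list(t_birth_min = 0, states = states_for(i))))
  gen <- generate_tracks(cfg)
  expect_length(gen$truth$events$sibling_pairs, 18L)
  n_sep_1h <- 0L
  for (sp in gen$truth$events$sibling_pairs) {
    t1 <- gen$tracks[gen$tracks$cell_id == sp$cell_id1, ]
    t2 <- gen$tracks[gen$tracks$cell_id == sp$cell_id2, ]
    tl <- sibling_contact_timeline(t1, t2)
    expect_equal(tl$states$state, sp$states)
    truth_rle <- rle(sp$states)
    ends <- cumsum(truth_rle$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    sep <- which(truth_rle$values == "separated")
    t_min <- t1$t_min
    want_longest <- if (length(sep))
      max(t_min[ends[sep]] - t_min[starts[sep]]) else 0
    expect_equal(tl$summary$longest_separation_min, want_longest)
    if (want_longest >= 60) n_sep_1h <- n_sep_1h + 1L
    want_perm <- truth_rle$values[length(truth_rle$values)] == "separated"
    expect_equal(tl$summary$permanent_separation, want_perm)
  }
  expect_equal(n_sep_1h, 12L)  # by construction of the schedule
})

test_that("bleed-over frames are flagged and excluded from validity", {
  # isolated cell: nothing flagged
  tr <- data.frame(movie_id = "m", cell_id = "a", frame = 0:4,
                   t_min = (0:4) * 10, x_um = 0, y_um = 0, z_um = 0,
                   gfp_raw = 1, rfp_raw = 10, stringsAsFactors = FALSE)
  rs <- normalize_ratios(tr)
  expect_true(all(flag_bleedover(tr, rs)$valid))

  # scheduled collision with a bright mature enteroblast
  cfg <- sim_config(rng_seed = 37, n_cells = 40L, n_frames = 40L,
                    intensity_noise_sd = 0,
                    collisions = list(list(t_start_min = 75,
                                           t_end_min = 150)))
  gen <- generate_tracks(cfg)
  tru <- gen$truth$events$collisions[[1]]
  rs <- normalize_ratios(gen$tracks)
  flagged <- flag_bleedover(gen$tracks, rs)
  got <- flagged[flagged$cell_id == tru$target_id & flagged$bleedover, ]
  expect_setequal(got$frame, tru$frames)
  expect_true(all(!got$valid))
})
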