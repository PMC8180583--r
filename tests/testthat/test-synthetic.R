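test_that("degenerate parameters produce constant gaze at the cell center", {
  wp <- world_params("VR", cells = list(
    corridor = cell_params(mu_x = 3, mu_y = -2, sigma_step = 0,
                           sacc_rate = 0),
    ascending = cell_params(), descending = cell_params()),
    valid_frac = 1)
  plan <- sector_map(0, 10, "corridor")
  ss <- simulate_session(wp, plan, seed = 1)
  expect_true(all(ss$rec$samples$x == 3))
  expect_true(all(ss$rec$samples$y == -2))
  expect_true(all(ss$rec$samples$valid))
})

test_that("VR sessions are sampled at nominal 120 Hz spacing", {
  p <- study_gen_params()
  ss <- simulate_session(p$VR, default_sector_plan("VR", scale = 0.1),
                         seed = 2)
  dts <- diff(ss$rec$samples$t)
  expect_equal(median(dts), 1 / 120, tolerance = 1e-12)
  expect_lt(max(abs(dts - 1 / 120)), 1e-9)
  expect_equal(ss$rec$nominal_rate, 120)
  expect_equal(ss$rec$tracking_range, c(100, 110))
})

test_that("ground-truth saccade count follows the renewal expectation", {
  wp <- world_params("VR", cells = list(
    corridor = cell_params(sacc_rate = 2), ascending = cell_params(),
    descending = cell_params()), valid_frac = 1)
  plan <- sector_map(0, 400, "corridor")
  ss <- simulate_session(wp, plan, seed = 3)
  expect_equal(ss$truth$n_saccades, nrow(ss$truth$saccades))
  # 2 /s over 400 s: count near 800 (renewal process, modest tolerance)
  expect_gt(ss$truth$n_saccades, 800 * 0.9)
  expect_lt(ss$truth$n_saccades, 800 * 1.1)
  # events are consistent with the emitted recording clock
  expect_true(all(ss$truth$saccades$onset >= 0))
  expect_true(all(ss$truth$saccades$offset <= 400 + 1e-9))
})

test_that("blinks zero the pupil, void gaze, and hit the target valid fraction", {
  p <- study_gen_params()
  ss <- simulate_session(p$RW, default_sector_plan("RW"), seed = 4)
  s <- ss$rec$samples
  expect_true(all(is.na(s$x[s$pupil == 0])))
  expect_true(all(s$valid == (s$pupil > 0 & is.finite(s$x))))
  # single-session check, 3-sigma tolerance around 85.5%
  expect_lt(abs(mean(s$valid) - 0.855), 0.03)
})

test_that("linear drift moves measured gaze away from the truth", {
  wp <- world_params("VR", cells = list(
    corridor = cell_params(mu_x = 0, mu_y = 0, sigma_step = 0,
                           sacc_rate = 0),
    ascending = cell_params(), descending = cell_params()),
    valid_frac = 1, drift_total = c(4, -2))
  ss <- simulate_session(wp, sector_map(0, 100, "corridor"), seed = 5)
  s <- ss$rec$samples
  n <- nrow(s)
  # truth is drift-free; measurement ends displaced by ~drift_total
  expect_equal(ss$truth$true_x[n], 0)
  expect_equal(s$x[n], 4 * s$t[n] / 100, tolerance = 1e-9)
  expect_equal(s$y[n], -2 * s$t[n] / 100, tolerance = 1e-9)
  expect_equal(s$x[1], 0)
})

test_that("cohorts are reproducible and respect injected cell shifts", {
  p <- study_gen_params()
  c1 <- simulate_cohort(n = 2, params = p, seed = 9, scale = 0.05)
  c2 <- simulate_cohort(n = 2, params = p, seed = 9, scale = 0.05)
  expect_identical(c1$S1$VR$rec$samples, c2$S1$VR$rec$samples)
  expect_identical(c1$S2$RW$rec$samples, c2$S2$RW$rec$samples)
  c3 <- simulate_cohort(n = 2, params = p, seed = 10, scale = 0.05)
  expect_false(identical(c1$S1$VR$rec$samples$x, c3$S1$VR$rec$samples$x))
  # shifting one cell's vertical center moves its true median accordingly
  shift <- matrix(0, 2, 3)
  shift[2, 3] <- 10  # (RW, descending)
  c4 <- simulate_cohort(n = 3, params = p, seed = 11, scale = 0.3,
                        mu_y_shift = shift)
  c5 <- simulate_cohort(n = 3, params = p, seed = 11, scale = 0.3)
  d <- sapply(1:3, function(i) {
    g <- function(co) {
      per <- co[[i]]$RW$truth$per_sector
      per$median_y[per$label == "descending"]
    }
    g(c4) - g(c5)
  })
  # short scaled-down segments leave a few fixations per cell, so individual
  # medians are noisy; the mean shift tracks the injected 10 degrees
  expect_lt(abs(mean(d) - 10), 2.5)
})

test_that("per-sector truth matches the emitted true stream", {
  p <- study_gen_params()
  ss <- simulate_session(p$VR, default_sector_plan("VR", scale = 0.25),
                         seed = 12)
  labs <- gaitgaze:::.label_at_times(ss$rec$samples$t, ss$plan)
  per <- ss$truth$per_sector
  i <- labs == "corridor"
  expect_equal(per$median_x[per$label == "corridor"],
               median(ss$truth$true_x[i]), tolerance = 1e-9)
  expect_equal(per$iqr_y[per$label == "corridor"],
               IQR(ss$truth$true_y[i], type = 7), tolerance = 1e-9)
})

test_that("validation grids embed the requested drift", {
  set.seed(13)
  g <- simulate_validation_grid(c(-2, 5), noise_sd = 0)
  d <- estimate_drift(g)
  expect_equal(unname(d$mean_offset), c(-2, 5), tolerance = 1e-9)
  expect_equal(d$mean_magnitude, sqrt(29), tolerance = 1e-9)
})

test_that("AOI tracks hit the controlled on-marker fraction by construction", {
  p <- study_gen_params()
  ss <- simulate_session(p$VR, default_sector_plan("VR", scale = 0.5),
                         seed = 14)
  aoi <- simulate_aoi_track(ss, seed = 15)
  ep <- aoi$truth$on_episodes
  corr <- ss$plan[ss$plan$label == "corridor", ]
  corr_dur <- sum(corr$t_end - corr$t_start)
  expect_equal(sum(ep$t1 - ep$t0) / corr_dur, aoi$truth$on_frac_target,
               tolerance = 1e-6)
  # confidence has a sub-threshold tail
  expect_gt(mean(aoi$track$confidence > 0.9), 0.9)
  expect_gt(sum(aoi$track$confidence <= 0.9), 0)
  # zero fraction: no gaze sample within 1 degree of any marker
  p0 <- p
  p0$VR$aoi$on_frac <- 0
  ss0 <- simulate_session(p0$VR, default_sector_plan("VR", scale = 0.25),
                          seed = 16)
  aoi0 <- simulate_aoi_track(ss0, seed = 17)
  rec0 <- mark_invalid_samples(ss0$rec)
  corr0 <- do.call(rbind, lapply(slice_by_sector(rec0, ss0$plan, "corridor"),
                                 function(s) s$samples))
  dw0 <- dwell_time(corr0, aoi0$track)
  expect_equal(dw0$dwell_frac, 0)
  expect_gt(dw0$mean_distance, 1)
})

test_that("horizon frame stacks translate a fixed texture", {
  # zero trace, zero noise: identical frames
  fs <- simulate_horizon_frames(5, rep(0, 5), noise_sd = 0, seed = 18)
  expect_equal(fs$frames[, , 3], fs$frames[, , 1])
  # integer step shift moves rows down
  fs2 <- simulate_horizon_frames(3, c(0, 0, 3), noise_sd = 0, seed = 19)
  expect_equal(fs2$frames[10 + 3, , 3], fs2$frames[10, , 1], tolerance = 1e-9)
})

test_that("horizon traces place gaze the configured distance below the horizon", {
  p <- study_gen_params()
  ss <- simulate_session(p$VR, default_sector_plan("VR", scale = 0.5),
                         seed = 20)
  tr <- simulate_horizon_trace(ss, noise_sd = 0)
  per <- ss$truth$per_sector
  expect_equal(unique(round(tr$y, 9)),
               round(per$median_y[per$label == "corridor"] - 2.2, 9))
})
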