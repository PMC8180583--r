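test_that("gaze summary matches a sort-based quantile oracle", {
  # constant gaze: degenerate case
  rec <- make_rec(rep(3, 20), rep(-2, 20))
  sm <- summarize_gaze(rec)
  expect_equal(sm$median_x, 3)
  expect_equal(sm$median_y, -2)
  expect_equal(sm$iqr_x, 0)
  expect_equal(sm$iqr_y, 0)
  # random samples vs oracle
  set.seed(21)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n, 0, 10)
    y <- rexp(n) - rnorm(n, 2)
    sm <- summarize_gaze(make_rec(x, y))
    expect_equal(sm$median_x, oracle_median(x), tolerance = 1e-12)
    expect_equal(sm$median_y, oracle_median(y), tolerance = 1e-12)
    expect_equal(sm$iqr_x, oracle_iqr(x), tolerance = 1e-12)
    expect_equal(sm$iqr_y, oracle_iqr(y), tolerance = 1e-12)
  }
})

test_that("uniform vertical gaze has IQR of half its range", {
  y <- seq(0, 10, length.out = 20001)  # dense deterministic grid
  sm <- summarize_gaze(make_rec(rep(0, length(y)), y))
  expect_equal(sm$iqr_y, 5, tolerance = 1e-3)
})

test_that("median shifts by a constant offset while IQR is unchanged", {
  set.seed(5)
  x <- rnorm(300); y <- rnorm(300)
  a <- 7.3; b <- -4.1
  s0 <- summarize_gaze(make_rec(x, y))
  s1 <- summarize_gaze(make_rec(x + a, y + b))
  expect_equal(s1$median_x - s0$median_x, a, tolerance = 1e-12)
  expect_equal(s1$median_y - s0$median_y, b, tolerance = 1e-12)
  expect_equal(s1$iqr_x, s0$iqr_x, tolerance = 1e-12)
  expect_equal(s1$iqr_y, s0$iqr_y, tolerance = 1e-12)
})

test_that("out-of-range fractions are directional and gate median reliability", {
  # RW range 60 x 46: half extents 30 / 23
  x <- c(rep(-40, 30), rep(0, 60), rep(35, 10))
  y <- rep(0, 100)
  sm <- summarize_gaze(make_rec(x, y, world = "RW"))
  expect_equal(sm$frac_out_left, 0.3)
  expect_equal(sm$frac_out_right, 0.1)
  expect_equal(sm$frac_out_up, 0)
  expect_true(sm$median_reliable)
  x2 <- c(rep(-40, 60), rep(0, 40))
  sm2 <- summarize_gaze(make_rec(x2, y, world = "RW"))
  expect_false(sm2$median_reliable)
})

test_that("T-shape ratio recovers engineered spread asymmetry", {
  # symmetric distribution: ratio 1
  gx <- rep(seq(-5, 5, by = 0.5), times = 40)
  gy <- rep(seq(-4.875, 4.875, length.out = 40), each = 21)
  expect_equal(tshape_ratio(make_rec(gx, gy)), 1, tolerance = 1e-10)
  # upper half twice as wide: ratio 2 (deterministic grids)
  up <- expand.grid(x = seq(-10, 10, by = 0.25), y = seq(-5, -1, by = 1))
  lo <- expand.grid(x = seq(-5, 5, by = 0.125), y = seq(1, 5, by = 1))
  d <- rbind(up, lo)
  expect_equal(tshape_ratio(make_rec(d$x, d$y)), 2, tolerance = 0.01)
  # degenerate lower half
  x <- c(rnorm(50), rep(0, 50))
  y <- c(rep(-1, 50), rep(1, 50))
  expect_warning(r <- tshape_ratio(make_rec(x, y)), "zero")
  expect_true(is.nan(r))
  expect_error(tshape_ratio(make_rec(rnorm(4), rnorm(4))), "at least")
})

test_that("direction histogram bins movements by screen-up convention", {
  # monotone rightward drift: all mass at 0 degrees
  h <- direction_histogram(make_rec(seq(0, 10, by = 0.1), rep(0, 101)))
  expect_equal(h$mass[1], 1)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  # pure 45-degree moves: x increasing, y decreasing (up on screen)
  h45 <- direction_histogram(make_rec(seq(0, 10, by = 0.1),
                                      seq(0, -10, by = -0.1)))
  expect_equal(h45$mass[2], 1)
  # moving down on screen (+y) is 270 degrees
  hdn <- direction_histogram(make_rec(rep(0, 50), seq(0, 4.9, by = 0.1)))
  expect_equal(hdn$mass[7], 1)
  # wedges are left-closed at their lower boundary: just past 22.5 degrees
  # belongs to the 45 bin, just below stays in the 0 bin
  for (eps in c(1e-6, -1e-6)) {
    ang <- (22.5 + eps) * pi / 180
    hb <- direction_histogram(make_rec(cumsum(rep(cos(ang), 10)),
                                       cumsum(rep(-sin(ang), 10))))
    expect_equal(hb$mass[if (eps > 0) 2 else 1], 1)
  }
  # zero-displacement pairs are excluded
  hz <- direction_histogram(make_rec(c(0, 0, 1), c(0, 0, 0)))
  expect_equal(hz$n_moves, 1L)
  expect_error(direction_histogram(make_rec(rep(1, 5), rep(2, 5))),
               "non-zero")
})

test_that("isotropic movements fill all direction bins evenly", {
  set.seed(123)
  n <- 1e5
  th <- runif(n, 0, 2 * pi)
  x <- cumsum(cos(th))
  y <- cumsum(-sin(th))  # screen-down storage
  h <- direction_histogram(make_rec(x, y, rate = 1000))
  se <- sqrt(0.125 * 0.875 / n)
  expect_true(all(abs(h$mass - 0.125) < 3 * se))
  expect_equal(cardinal_oblique_ratio(h), 1, tolerance = 0.05)
})

test_that("cardinal/oblique ratio handles uniform and degenerate histograms", {
  h <- structure(list(mass = rep(0.125, 8), centers = seq(0, 315, by = 45),
                      n_moves = 800L), class = "direction_histogram")
  expect_equal(cardinal_oblique_ratio(h), 1)
  h2 <- h
  h2$mass <- c(0.25, 0, 0.25, 0, 0.25, 0, 0.25, 0)
  expect_warning(r <- cardinal_oblique_ratio(h2), "oblique")
  expect_identical(r, Inf)
})

test_that("velocities use neighboring valid samples only", {
  # +1 degree per 0.1 s: 10 deg/s horizontal
  v <- sample_velocities(make_rec(seq(0, 5, by = 1), rep(2, 6), rate = 10))
  expect_equal(v$speed, rep(10, 5))
  expect_equal(v$speed_y, rep(0, 5))
  # stationary gaze
  v0 <- sample_velocities(make_rec(rep(1, 10), rep(1, 10)))
  expect_true(all(v0$speed == 0))
  # a blink between two valid samples: no velocity across the gap
  pupil <- rep(2, 10); pupil[5] <- 0
  x <- c(1:4, NA, 6:10)
  vb <- sample_velocities(mark_invalid_samples(make_rec(x, x, pupil = pupil)))
  expect_equal(nrow(vb), 7L)  # 9 pairs minus the two spanning sample 5
  expect_error(sample_velocities(data.frame(t = c(0, 0), x = c(1, 2),
                                            y = c(0, 0))),
               "non-positive")
})

test_that("velocity histogram uses left-closed octave bins", {
  vh <- velocity_histogram(c(10))
  expect_equal(which(vh$mass == 1), 5L)  # 8-16 bin
  expect_equal(which(velocity_histogram(600)$mass == 1), 11L)  # >512
  expect_equal(which(velocity_histogram(2)$mass == 1), 3L)     # 2-4
  expect_equal(which(velocity_histogram(0.99)$mass == 1), 1L)  # <1
  vh2 <- velocity_histogram(c(0.5, 3, 3, 700), normalize = TRUE)
  expect_equal(sum(vh2$mass), 1)
  expect_equal(vh2$mass[3], 0.5)
})

test_that("heatmap accumulates mass exactly, clamps to edge bins and smooths", {
  # all samples at the center
  hm <- gaze_heatmap(make_rec(rep(0, 50), rep(0, 50)), smooth_fwhm = 0)
  expect_equal(sum(hm$counts), 50)
  expect_equal(hm$counts["0", "0"], 50)
  # out-of-range sample lands in the outermost bin
  hm2 <- gaze_heatmap(make_rec(c(80, 0), c(0, -70)), smooth_fwhm = 0)
  expect_equal(hm2$counts["0", "50"], 1)
  expect_equal(hm2$counts["-50", "0"], 1)
  # smoothing preserves interior mass
  hm3 <- gaze_heatmap(make_rec(rep(0, 100), rep(0, 100)), smooth_fwhm = 1)
  expect_equal(sum(hm3$counts), 100, tolerance = 1e-9)
  expect_lt(max(hm3$counts), 100)
  expect_equal(hm3$n, 100)
  # normalization across a participant's maps: global max becomes 1
  maps <- normalize_heatmaps(list(
    gaze_heatmap(make_rec(rep(0, 200), rep(0, 200)), smooth_fwhm = 0),
    gaze_heatmap(make_rec(rep(10, 50), rep(5, 50)), smooth_fwhm = 0)))
  expect_equal(max(vapply(maps, function(m) max(m$counts), 0)), 1)
  expect_equal(max(maps[[2]]$counts), 0.25)
  # log display regularization keeps zero bins finite
  expect_true(all(is.finite(heatmap_log_display(maps[[1]]))))
})
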