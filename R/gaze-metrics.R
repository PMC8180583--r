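#' Robust positional summary of a gaze segment
#'
#' Characterizes the gaze distribution of a segment by its componentwise
#' median and inter-quartile range (IQR), computed over valid, non-excluded
#' samples. Samples outside the device tracking range are included: their
#' exact position is unreliable but the side on which they left the range is
#' not, and neither median nor IQR depends on exact positions in the tails as
#' long as fewer than half the data fall outside on one side (a quarter for
#' the IQR). Directional out-of-range fractions are reported so that this
#' condition can be checked; the median is flagged unreliable if any side
#' exceeds 50%.
#'
#' Quartiles use linear-interpolation sample quantiles (type 7).
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @param tracking_range full extents (width, height) in degrees; taken from
#'   the recording when present.
#' @return list with `median_x`, `median_y`, `iqr_x`, `iqr_y`, `n_valid`,
#'   `frac_out_left/right/up/down` and logical `median_reliable`.
#' @export
summarize_gaze <- function(seg, tracking_range = NULL) {
  s <- gaze_samples(seg, valid_only = TRUE)
  if (is.null(tracking_range)) tracking_range <- attr(s, "tracking_range")
  if (nrow(s) < 1) stop("no valid samples in segment")
  q <- function(v) unname(stats::quantile(v, c(.25, .5, .75), type = 7))
  qx <- q(s$x); qy <- q(s$y)
  out <- list(median_x = qx[2], median_y = qy[2],
              iqr_x = qx[3] - qx[1], iqr_y = qy[3] - qy[1],
              n_valid = nrow(s))
  if (!is.null(tracking_range)) {
    hw <- tracking_range[1] / 2; hh <- tracking_range[2] / 2
    out$frac_out_left <- mean(s$x < -hw)
    out$frac_out_right <- mean(s$x > hw)
    out$frac_out_up <- mean(s$y < -hh)
    out$frac_out_down <- mean(s$y > hh)
  } else {
    out[c("frac_out_left", "frac_out_right", "frac_out_up",
          "frac_out_down")] <- 0
  }
  out$median_reliable <- max(out$frac_out_left, out$frac_out_right,
                             out$frac_out_up, out$frac_out_down) <= 0.5
  out
}

#' T-shape ratio of a gaze distribution
#'
#' Natural gaze during locomotion often shows a "T" pattern: a horizontally
#' wide band above the vertical median (looking around / planning ahead) over
#' a narrow vertical trunk below it (terrain ahead). The segment's valid
#' samples are split at the vertical median into an upper half (gaze up,
#' `y < median`) and a lower half (`y > median`; stored y is positive
#' downward). The ratio is the horizontal IQR of the upper half divided by
#' that of the lower half; values above 1 indicate wider horizontal scanning
#' above the median. Samples tied with the median are excluded from both
#' halves.
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @param min_half minimum valid samples required per half.
#' @return the ratio (numeric scalar); `NaN` with a warning when the
#'   lower-half IQR is zero.
#' @export
tshape_ratio <- function(seg, min_half = 4) {
  s <- gaze_samples(seg, valid_only = TRUE)
  my <- stats::median(s$y)
  upper <- s$x[s$y < my]
  lower <- s$x[s$y > my]
  if (length(upper) < min_half || length(lower) < min_half) {
    stop("need at least ", min_half, " valid samples in each half")
  }
  iqr_u <- stats::IQR(upper, type = 7)
  iqr_l <- stats::IQR(lower, type = 7)
  if (iqr_l == 0) {
    warning("lower-half horizontal IQR is zero; T-shape ratio undefined")
    return(NaN)
  }
  iqr_u / iqr_l
}

.dir_centers <- seq(0, 315, by = 45)

#' Histogram of gaze-movement directions
#'
#' For every pair of consecutive valid samples, the displacement direction is
#' computed (0 deg = rightward, 90 deg = upward gaze movement; stored y is
#' positive-down, so the vertical displacement sign is flipped).
#' Zero-displacement pairs are dropped. Directions are accumulated in eight
#' 45-degree wedges centered on the cardinal and oblique axes, with bin
#' boundaries at +/-22.5 deg around each center (left-closed), and the
#' histogram is normalized to unit integral.
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @return object of class `direction_histogram`: list with `mass` (length 8,
#'   sums to 1), `centers` (0, 45, ..., 315) and `n_moves`.
#' @export
direction_histogram <- function(seg) {
  s <- gaze_samples(seg)
  ok <- s$valid & !s$excluded
  pair <- ok[-nrow(s)] & ok[-1]
  dx <- diff(s$x)[pair]
  dy <- -diff(s$y)[pair]  # flip to positive-up for direction convention
  nz <- dx != 0 | dy != 0
  dx <- dx[nz]; dy <- dy[nz]
  if (!length(dx)) stop("no non-zero gaze movements in segment")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  bin <- floor(((ang + 22.5) %% 360) / 45) + 1L
  mass <- tabulate(bin, nbins = 8L) / length(bin)
  structure(list(mass = mass, centers = .dir_centers, n_moves = length(bin)),
            class = "direction_histogram")
}

#' Cardinal-to-oblique movement ratio
#'
#' Ratio of the summed histogram mass in the cardinal wedges (centers 0, 90,
#' 180, 270 deg) to the mass in the oblique wedges (45, 135, 225, 315 deg).
#' Human gaze shifts are biased toward cardinal directions, giving ratios
#' above 1.
#'
#' @param h a [direction_histogram()].
#' @return the ratio; `Inf` with a warning when the oblique mass is zero.
#' @export
cardinal_oblique_ratio <- function(h) {
  stopifnot(inherits(h, "direction_histogram"))
  card <- sum(h$mass[h$centers %% 90 == 0])
  obl <- sum(h$mass[h$centers %% 90 != 0])
  if (obl == 0) {
    warning("zero oblique mass; cardinal/oblique ratio undefined (Inf)")
    return(Inf)
  }
  card / obl
}

#' Sample-to-sample gaze velocities
#'
#' Gaze speed is the Euclidean position difference between two neighboring
#' valid samples divided by their time difference; absolute horizontal and
#' vertical component speeds are returned alongside. Samples without a valid
#' neighbor (e.g. across blinks) contribute no velocity — velocities are
#' never interpolated across invalid gaps.
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @return data.frame with `t` (midpoint of the pair), `speed`, `speed_x`,
#'   `speed_y` in deg/s.
#' @export
sample_velocities <- function(seg) {
  s <- gaze_samples(seg)
  if (nrow(s) < 2) {
    return(data.frame(t = numeric(0), speed = numeric(0),
                      speed_x = numeric(0), speed_y = numeric(0)))
  }
  ok <- s$valid & !s$excluded
  pair <- ok[-nrow(s)] & ok[-1]
  dt <- diff(s$t)[pair]
  if (any(dt <= 0)) stop("non-positive sample time difference")
  dx <- diff(s$x)[pair]
  dy <- diff(s$y)[pair]
  data.frame(t = (s$t[-nrow(s)][pair] + s$t[-1][pair]) / 2,
             speed = sqrt(dx^2 + dy^2) / dt,
             speed_x = abs(dx) / dt,
             speed_y = abs(dy) / dt)
}

.vel_edges <- 2^(0:9)  # 1,2,4,...,512 deg/s

#' Octave-binned velocity histogram
#'
#' Speeds are counted in 11 logarithmically spaced bins (octaves): < 1, 1-2,
#' 2-4, 4-8, 8-16, 16-32, 32-64, 64-128, 128-256, 256-512, > 512 deg/s.
#' Bins are left-closed, so a speed exactly at a boundary falls in the upper
#' bin (2 deg/s counts in 2-4).
#'
#' @param speeds non-negative speeds in deg/s (e.g. from
#'   [sample_velocities()]).
#' @param normalize divide counts by their total (unit integral per
#'   individual, for averaging across participants).
#' @return object of class `velocity_histogram`: list with `mass`, `labels`,
#'   `n`.
#' @export
velocity_histogram <- function(speeds, normalize = FALSE) {
  stopifnot(all(speeds >= 0))
  bin <- findInterval(speeds, .vel_edges, left.open = FALSE) + 1L
  counts <- tabulate(bin, nbins = 11L)
  labels <- c("<1", paste0(c(1, 2, 4, 8, 16, 32, 64, 128, 256),
                           "-", c(2, 4, 8, 16, 32, 64, 128, 256, 512)), ">512")
  mass <- if (normalize && sum(counts) > 0) counts / sum(counts) else counts
  structure(list(mass = mass, labels = labels, n = length(speeds)),
            class = "velocity_histogram")
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.gauss_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

.smooth2d <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(a, n) rbind(matrix(0, n, ncol(a)), a, matrix(0, n, ncol(a)))
  # separable convolution, zero padding (mass near borders is truncated)
  conv_cols <- function(a) {
    ap <- pad(a, r)
    out <- matrix(0, nrow(a), ncol(a))
    for (i in seq_along(k)) {
      out <- out + k[i] * ap[i:(i + nrow(a) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' 2D gaze position histogram (heatmap)
#'
#' Valid samples are accumulated in a 101 x 101 grid of 1-degree bins
#' spanning +/-50 degrees on each axis; samples outside this range are
#' accumulated in the outermost bins, so the total mass before smoothing
#' equals the valid sample count exactly. Optionally the map is smoothed with
#' a Gaussian low-pass filter (FWHM 1 bin by default) and divided by a
#' normalization scale (typically the participant's maximum bin over all
#' sectors of one world, see [normalize_heatmaps()]).
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @param smooth_fwhm Gaussian FWHM in bins (0 disables smoothing).
#' @param normalize_scale divisor applied after smoothing (`NULL` = none).
#' @return object of class `gaze_heatmap`: list with `counts` (101 x 101,
#'   rows = y from -50 (up) to 50 (down), cols = x), `xmid`, `ymid`,
#'   `n`, `smooth_fwhm`, `scale`.
#' @export
gaze_heatmap <- function(seg, smooth_fwhm = 1, normalize_scale = NULL) {
  s <- gaze_samples(seg, valid_only = TRUE)
  mids <- -50:50
  ix <- pmin(pmax(round(s$x), -50), 50) + 51L
  iy <- pmin(pmax(round(s$y), -50), 50) + 51L
  m <- matrix(0, 101, 101, dimnames = list(y = mids, x = mids))
  if (nrow(s)) {
    tab <- table(factor(iy, levels = 1:101), factor(ix, levels = 1:101))
    m[] <- as.numeric(tab)
  }
  raw_n <- sum(m)
  if (smooth_fwhm > 0) m <- .smooth2d(m, .fwhm_to_sigma(smooth_fwhm))
  scale <- NA_real_
  if (!is.null(normalize_scale)) {
    scale <- normalize_scale
    m <- m / scale
  }
  structure(list(counts = m, xmid = mids, ymid = mids, n = raw_n,
                 smooth_fwhm = smooth_fwhm, scale = scale),
            class = "gaze_heatmap")
}

#' Normalize a participant's heatmaps to a common range
#'
#' Divides every map in the list by the participant's single maximum bin
#' value across the maps (per participant and world), preserving relative
#' density across sectors.
#'
#' @param maps list of `gaze_heatmap` objects from one participant/world.
#' @return the list with counts rescaled and `scale` recorded.
#' @export
normalize_heatmaps <- function(maps) {
  stopifnot(length(maps) > 0, all(vapply(maps, inherits, TRUE, "gaze_heatmap")))
  scale <- max(vapply(maps, function(m) max(m$counts), 0))
  if (scale == 0) stop("all heatmaps empty; cannot normalize")
  lapply(maps, function(m) {
    m$counts <- m$counts / scale
    m$scale <- scale
    m
  })
}

#' Heatmap values prepared for logarithmic display
#'
#' Adds a regularization of 5% of the scale before taking log10, so that
#' empty bins remain displayable on a log color scale.
#'
#' @param map a normalized `gaze_heatmap` (values in `[0, 1]`).
#' @param regularize fraction of the (normalized) scale to add.
#' @return matrix of log10 values.
#' @export
heatmap_log_display <- function(map, regularize = 0.05) {
  stopifnot(inherits(map, "gaze_heatmap"))
  log10(map$counts + regularize)
}
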