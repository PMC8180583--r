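#' Saccade detector parameters
#'
#' Parameters of the velocity-threshold saccade detector. `lambda` scales a
#' median-based estimate of the velocity noise into the elliptic detection
#' threshold; it was hand-tuned per participant and world in the original
#' workflow, so it is exposed as a per-recording setting with default 6.
#'
#' @param lambda noise-threshold multiplier, > 0.
#' @param window centered moving-window length (samples, odd, >= 3) of the
#'   velocity differentiation kernel.
#' @param min_duration minimum saccade duration in seconds (default 6 ms,
#'   i.e. at least 2 samples at 120 Hz).
#' @param merge_gap events separated by less than this gap (seconds) are
#'   merged.
#' @return list of class `saccade_params`.
#' @export
saccade_params <- function(lambda = 6, window = 5, min_duration = 0.006,
                           merge_gap = 0.02) {
  stopifnot(lambda > 0, window >= 3, window %% 2 == 1)
  structure(list(lambda = lambda, window = as.integer(window),
                 min_duration = min_duration, merge_gap = merge_gap),
            class = "saccade_params")
}

# centered moving-window velocity (5-point kernel for window = 5:
# v[i] = (x[i+2] + x[i+1] - x[i-1] - x[i-2]) / (6 * dt); generalizes to any
# odd window as a least-squares slope over the window). Edge samples get NA.
.window_velocity <- function(x, dt, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  v <- rep(NA_real_, n)
  if (n < window) return(v)
  num <- rep(0, n - 2L * h)
  den <- 2 * sum((1:h)^2) * dt
  idx <- (h + 1L):(n - h)
  for (k in 1:h) {
    num <- num + k * (x[idx + k] - x[idx - k])
  }
  v[idx] <- num / den
  v
}

# sigma^2 = median(v^2) - median(v)^2 (robust to the saccadic minority)
.median_sd <- function(v) {
  v <- v[is.finite(v)]
  sqrt(max(stats::median(v^2) - stats::median(v)^2, 0))
}

#' Detect saccades by an elliptic velocity threshold
#'
#' Velocities are computed per axis with a centered moving-window
#' differentiation kernel over runs of consecutive valid samples. A robust,
#' median-based noise scale is estimated per axis over the whole segment
#' (`sigma^2 = median(v^2) - median(v)^2`), thresholds are `eta = lambda *
#' sigma`, and a sample is saccadic when `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`.
#' Saccadic runs shorter than `min_duration` are dropped; runs separated by
#' less than `merge_gap` are merged. Detection restarts across invalid gaps;
#' events are never bridged over blinks.
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @param params a [saccade_params()].
#' @return data.frame of class `saccade_events` with columns `onset`,
#'   `offset` (seconds), `amplitude` (degrees, onset-to-offset displacement),
#'   `peak_speed` (deg/s), sorted and non-overlapping.
#' @export
detect_saccades <- function(seg, params = saccade_params()) {
  stopifnot(inherits(params, "saccade_params"))
  s <- gaze_samples(seg)
  ok <- s$valid & !s$excluded
  run_id <- cumsum(c(TRUE, diff(ok) != 0))
  runs <- split(seq_len(nrow(s)), run_id)
  runs <- runs[vapply(runs, function(i) ok[i[1]], TRUE)]
  runs <- runs[vapply(runs, length, 1L) >= params$window]
  if (!length(runs)) {
    return(.empty_events())
  }
  vel <- lapply(runs, function(i) {
    dt <- stats::median(diff(s$t[i]))
    data.frame(i = i,
               vx = .window_velocity(s$x[i], dt, params$window),
               vy = .window_velocity(s$y[i], dt, params$window))
  })
  all_v <- do.call(rbind, vel)
  sx <- .median_sd(all_v$vx)
  sy <- .median_sd(all_v$vy)
  # the median estimator can collapse on very short / peculiar segments even
  # though the signal varies; fall back to the plain SD before giving up
  if (sx == 0) sx <- stats::sd(all_v$vx[is.finite(all_v$vx)])
  if (sy == 0) sy <- stats::sd(all_v$vy[is.finite(all_v$vy)])
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("velocity noise scale is zero (constant signal); ",
         "saccade threshold is degenerate — segment needs signal variance")
  }
  eta_x <- params$lambda * sx
  eta_y <- params$lambda * sy
  ev <- list()
  for (v in vel) {
    crit <- (v$vx / eta_x)^2 + (v$vy / eta_y)^2 > 1
    crit[is.na(crit)] <- FALSE
    r <- rle(crit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- v$i[starts[j]]; i1 <- v$i[ends[j]]
      ev[[length(ev) + 1L]] <- c(onset = s$t[i0], offset = s$t[i1],
                                 i0 = i0, i1 = i1)
    }
  }
  if (!length(ev)) return(.empty_events())
  ev <- as.data.frame(do.call(rbind, ev))
  ev <- ev[order(ev$onset), , drop = FALSE]
  # merge events separated by a short gap (within the same valid run)
  merged <- ev[1, , drop = FALSE]
  for (k in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    gap_ok <- ev$onset[k] - merged$offset[last] < params$merge_gap
    same_run <- all(ok[merged$i1[last]:ev$i0[k]])
    if (gap_ok && same_run) {
      merged$offset[last] <- ev$offset[k]
      merged$i1[last] <- ev$i1[k]
    } else {
      merged <- rbind(merged, ev[k, ])
    }
  }
  merged <- merged[merged$offset - merged$onset >= params$min_duration, ,
                   drop = FALSE]
  if (!nrow(merged)) return(.empty_events())
  amp <- sqrt((s$x[merged$i1] - s$x[merged$i0])^2 +
              (s$y[merged$i1] - s$y[merged$i0])^2)
  speed <- sqrt(all_v$vx^2 + all_v$vy^2)
  pk <- mapply(function(i0, i1) {
    max(speed[all_v$i >= i0 & all_v$i <= i1], na.rm = TRUE)
  }, merged$i0, merged$i1)
  out <- data.frame(onset = merged$onset, offset = merged$offset,
                    amplitude = amp, peak_speed = pk)
  rownames(out) <- NULL
  class(out) <- c("saccade_events", "data.frame")
  out
}

.empty_events <- function() {
  structure(data.frame(onset = numeric(0), offset = numeric(0),
                       amplitude = numeric(0), peak_speed = numeric(0)),
            class = c("saccade_events", "data.frame"))
}

#' Valid (analyzable) duration of a segment
#'
#' Sum of inter-sample intervals whose two endpoint samples are both valid
#' and non-excluded. This is the denominator for saccade rates: time lost to
#' blinks or exclusion windows does not count.
#'
#' @param seg a `gaze_recording` segment or sample data.frame.
#' @return duration in seconds.
#' @export
valid_duration <- function(seg) {
  s <- gaze_samples(seg)
  if (nrow(s) < 2) return(0)
  ok <- s$valid & !s$excluded
  sum(diff(s$t)[ok[-nrow(s)] & ok[-1]])
}

#' Saccade rate of a segment
#'
#' Number of detected saccades per second of valid segment duration.
#'
#' @param events a `saccade_events` table (from [detect_saccades()]).
#' @param seg the segment the events were detected in.
#' @return rate in 1/s.
#' @export
saccade_rate <- function(events, seg) {
  dur <- valid_duration(seg)
  if (dur <= 0) stop("segment has zero valid duration")
  nrow(events) / dur
}
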