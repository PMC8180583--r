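#' Per-cell generator parameters
#'
#' Parameters of the simulated gaze process for one world-by-sector cell.
#' The process alternates fixations and saccades: fixation targets are drawn
#' around the cell center `(mu_x, mu_y)` with between-fixation scatter
#' `(sigma_x, sigma_y)`; within a fixation the eye performs a slow random
#' wander of small steps; saccades move to the next target along a
#' raised-cosine velocity profile whose peak velocity grows with amplitude
#' (main-sequence behavior). Saccade amplitudes are emergent from the target
#' scatter rather than a separate dial.
#'
#' @param mu_x,mu_y cell center in degrees (y positive downward).
#' @param sigma_x,sigma_y SD of fixation-target scatter, degrees.
#' @param spread_ratio upper/lower horizontal spread ratio: horizontal
#'   scatter is multiplied by `sqrt(spread_ratio)` for targets above the
#'   vertical center and divided by it below, so the expected T-shape ratio
#'   equals approximately `spread_ratio`.
#' @param sacc_rate target saccade rate, 1/s; sets the mean fixation
#'   duration given the expected saccade duration.
#' @param cardinal_bias probability in `[0, 1]` that a movement direction
#'   (wander step or saccade) is snapped to the nearest cardinal axis rather
#'   than drawn isotropically.
#' @param sigma_step SD of a single within-fixation wander step, degrees.
#' @param fix_dur_shape gamma shape of fixation durations.
#' @return list of class `gg_cell_params`.
#' @export
cell_params <- function(mu_x = 0, mu_y = 0, sigma_x = 5, sigma_y = 4,
                        spread_ratio = 1, sacc_rate = 2, cardinal_bias = 0.3,
                        sigma_step = 0.15, fix_dur_shape = 4) {
  stopifnot(sigma_x > 0, sigma_y > 0, spread_ratio > 0, sacc_rate >= 0,
            cardinal_bias >= 0, cardinal_bias <= 1, sigma_step >= 0,
            fix_dur_shape > 0)
  structure(as.list(environment()), class = "gg_cell_params")
}

# saccade duration from amplitude (simple main-sequence rule)
.sacc_duration <- function(amp) pmin(pmax(0.02 + 0.0025 * amp, 0.012), 0.1)

# expected saccade amplitude for a cell (targets iid Gaussian around mu)
.expected_amp <- function(cp) {
  sqrt(pi / 2) * sqrt(cp$sigma_x^2 + cp$sigma_y^2)
}

.fix_dur_mean <- function(cp) {
  if (cp$sacc_rate <= 0) return(Inf)
  max(1 / cp$sacc_rate - .sacc_duration(.expected_amp(cp)), 0.05)
}

#' Per-world generator parameters
#'
#' Device- and session-level parameters for one world, plus the per-sector
#' cell parameters. `unclassified` time (connecting areas) reuses the
#' corridor cell.
#'
#' @param world `"VR"` or `"RW"`.
#' @param cells named list of [cell_params()] for `corridor`, `ascending`,
#'   `descending`.
#' @param rate_hz nominal sampling rate.
#' @param valid_frac expected fraction of valid samples in `(0, 1]`; blinks
#'   are injected as a Poisson process with gamma-distributed durations at a
#'   rate chosen so that the expected unoccupied fraction equals
#'   `valid_frac`.
#' @param blink_dur_mean mean blink duration, seconds.
#' @param drift_total accumulated measurement drift `(dx, dy)` in degrees,
#'   applied linearly over the session (measured = true + drift * t/T).
#' @param tracking_range device tracking extents (width, height), degrees.
#' @param head_pitch,head_roll named per-sector mean headset pitch (positive
#'   down) and roll (positive rightward tilt), degrees; VR only in practice.
#' @param head_noise_sd,head_ar SD and AR(1) coefficient of head orientation
#'   noise.
#' @param horizon_below mean vertical distance of gaze below the visual
#'   horizon during corridors, degrees (`NULL` disables horizon-trace
#'   simulation).
#' @param aoi list of AOI-track settings: `frame_rate` (Hz), `on_frac`
#'   (fraction of corridor time with gaze on the marker), `on_dur_mean`
#'   (mean on-episode duration, s), `low_conf_frac` (fraction of frames with
#'   sub-threshold detector confidence).
#' @return list of class `gg_world_params`.
#' @export
world_params <- function(world = c("VR", "RW"), cells = NULL,
                         rate_hz = NULL, valid_frac = NULL,
                         blink_dur_mean = 0.25,
                         drift_total = c(0, 0), tracking_range = NULL,
                         head_pitch = c(corridor = 0, ascending = 0.55,
                                        descending = 14.6),
                         head_roll = c(corridor = 0, ascending = 0.34,
                                       descending = -0.27),
                         head_noise_sd = 2, head_ar = 0.95,
                         horizon_below = NULL,
                         aoi = list(frame_rate = 25, on_frac = 0.02,
                                    on_dur_mean = 0.5, low_conf_frac = 0.05)) {
  world <- match.arg(world)
  if (is.null(rate_hz)) rate_hz <- if (world == "VR") 120 else 60
  if (is.null(valid_frac)) valid_frac <- if (world == "VR") 0.995 else 0.855
  if (is.null(tracking_range)) {
    tracking_range <- if (world == "VR") c(100, 110) else c(60, 46)
  }
  if (is.null(cells)) {
    cells <- list(corridor = cell_params(), ascending = cell_params(),
                  descending = cell_params())
  }
  stopifnot(valid_frac > 0, valid_frac <= 1,
            all(c("corridor", "ascending", "descending") %in% names(cells)))
  structure(as.list(environment()), class = "gg_world_params")
}

#' Study-calibrated generator defaults
#'
#' Generator parameters emulating the walking-route study conditions: an
#' eight-participant within-subject cohort walking the same route in a
#' virtual (VR, 120 Hz, 100 x 110 deg tracking, 99.5% valid) and a real
#' (RW, 60 Hz, 60 x 46 deg tracking, 85.5% valid) building. Cell centers
#' follow the reported per-sector median gaze, saccade rates the reported
#' per-sector rates, T-shape spread ratios the reported IQR ratios, drift
#' magnitudes the reported end-of-session validation offsets, and head pitch
#' the reported sector-relative headset orientation.
#'
#' @return list with elements `VR` and `RW` ([world_params()]), plus cohort
#'   settings `between` (between-subject SDs) and `drift` (per-world drift
#'   magnitude mean and SD).
#' @export
study_gen_params <- function() {
  vr_cells <- list(
    corridor = cell_params(mu_x = -2.62, mu_y = 4.43, sigma_x = 5.0,
                            sigma_y = 3.5, spread_ratio = 1.16,
                            sacc_rate = 1.64, cardinal_bias = 0.45),
    ascending = cell_params(mu_x = -1.92, mu_y = 6.17, sigma_x = 3.5,
                             sigma_y = 4.5, spread_ratio = 1.27,
                             sacc_rate = 2.28, cardinal_bias = 0.40),
    descending = cell_params(mu_x = -0.93, mu_y = 15.16, sigma_x = 3.0,
                              sigma_y = 5.0, spread_ratio = 1.54,
                              sacc_rate = 2.21, cardinal_bias = 0.40))
  rw_cells <- list(
    corridor = cell_params(mu_x = 2.40, mu_y = -4.15, sigma_x = 5.0,
                            sigma_y = 3.5, spread_ratio = 1.15,
                            sacc_rate = 3.48, cardinal_bias = 0.30),
    ascending = cell_params(mu_x = 2.69, mu_y = 1.46, sigma_x = 3.5,
                             sigma_y = 4.5, spread_ratio = 1.58,
                             sacc_rate = 3.63, cardinal_bias = 0.25),
    descending = cell_params(mu_x = 2.49, mu_y = 5.27, sigma_x = 3.0,
                              sigma_y = 5.0, spread_ratio = 2.77,
                              sacc_rate = 3.27, cardinal_bias = 0.25))
  list(
    VR = world_params("VR", cells = vr_cells, horizon_below = 2.2,
                      aoi = list(frame_rate = 30, on_frac = 0.035,
                                 on_dur_mean = 0.3, low_conf_frac = 0.05)),
    RW = world_params("RW", cells = rw_cells, horizon_below = 4.2,
                      aoi = list(frame_rate = 25, on_frac = 0.018,
                                 on_dur_mean = 0.3, low_conf_frac = 0.05)),
    between = list(sd_mu_x = 2.0, sd_mu_y = 4.0, sd_mu_world = 2.0,
                   sd_log_rate = 0.08, sd_log_spread = 0.08,
                   sd_log_tshape = 0.10),
    drift = list(VR = c(mean = 6.4, sd = 5.7), RW = c(mean = 10.8, sd = 2.6))
  )
}

#' Study-route sector plan
#'
#' The walking route covered 6 corridors, 4 ascending stair segments and 2
#' descending stair segments, with connecting (unclassified) areas between
#' them. Per-sector durations are the reported per-world means divided
#' evenly across segments; unclassified gaps fill up the reported total
#' session duration (400 s VR, 333 s RW).
#'
#' @param world `"VR"` or `"RW"`.
#' @param scale multiplies all durations (scaled-down plans for quick runs).
#' @return a [sector_map()].
#' @export
default_sector_plan <- function(world = c("VR", "RW"), scale = 1) {
  world <- match.arg(world)
  if (world == "VR") {
    dur <- c(corridor = 167.5 / 6, ascending = 29.1 / 4,
             descending = 23.13 / 2)
    total <- 400
  } else {
    dur <- c(corridor = 123.0 / 6, ascending = 25.1 / 4,
             descending = 24.3 / 2)
    total <- 333
  }
  order <- c("corridor", "ascending", "ascending", "corridor", "ascending",
             "ascending", "corridor", "descending", "corridor", "descending",
             "corridor", "corridor")
  gap <- (total - sum(dur[order])) / (length(order) + 1)
  t0 <- gap
  starts <- ends <- numeric(length(order))
  for (i in seq_along(order)) {
    starts[i] <- t0
    ends[i] <- t0 + dur[order[i]]
    t0 <- ends[i] + gap
  }
  sector_map(starts * scale, ends * scale, order)
}

.label_at_times <- function(t, map) {
  lab <- rep("unclassified", length(t))
  for (i in which(map$label != "excluded")) {
    lab[t >= map$t_start[i] & t < map$t_end[i]] <- map$label[i]
  }
  for (i in which(map$label == "excluded")) {
    lab[t >= map$t_start[i] & t < map$t_end[i]] <- "excluded"
  }
  lab
}

.cell_for <- function(wp, label) {
  if (label %in% names(wp$cells)) wp$cells[[label]] else wp$cells$corridor
}

# draw one fixation target for a cell (asymmetric horizontal scatter -> T)
.draw_target <- function(cp) {
  y <- cp$mu_y + cp$sigma_y * stats::rnorm(1)
  mult <- if (y < cp$mu_y) sqrt(cp$spread_ratio) else 1 / sqrt(cp$spread_ratio)
  x <- cp$mu_x + cp$sigma_x * mult * stats::rnorm(1)
  c(x, y)
}

# direction angles (radians), cardinal-snapped with probability bias
.draw_step_dirs <- function(m, bias) {
  th <- stats::runif(m, 0, 2 * pi)
  snap <- stats::runif(m) < bias
  th[snap] <- sample(c(0, .5, 1, 1.5) * pi, sum(snap), replace = TRUE)
  th
}

#' Simulate one gaze session
#'
#' Generates a sampled gaze recording over a sector plan: an alternating
#' fixation/saccade process with per-sector cell parameters, within-fixation
#' wander, raised-cosine saccade profiles, Poisson blinks (pupil 0, gaze
#' `NA`), and linear measurement drift. Head pose (pitch/roll with AR(1)
#' noise around per-sector means) is generated on the same clock.
#'
#' @param wp a [world_params()].
#' @param plan a [sector_map()]; must be non-empty.
#' @param participant_id id stored in the recording.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return list of class `gg_session` with elements `rec`
#'   (`gaze_recording`), `head` (`head_pose_track`), `plan`, `params`, and
#'   `truth`: ground-truth saccade table and count, per-sector median/IQR of
#'   the true (drift-free) gaze stream, the drift total, and the target
#'   valid fraction.
#' @export
simulate_session <- function(wp, plan, participant_id = "S1", seed = NULL) {
  stopifnot(inherits(wp, "gg_world_params"), nrow(plan) > 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / wp$rate_hz
  t_end <- max(plan$t_end)
  t <- seq(0, t_end - dt / 2, by = dt)
  n <- length(t)
  x <- y <- numeric(n)
  sacc <- list()
  cur_t <- 0
  ptr <- 1L
  cp <- .cell_for(wp, .label_at_times(0, plan))
  cur_pos <- c(cp$mu_x, cp$mu_y)
  take <- function(t1) {
    # consume sample indices with t < t1 (monotone pointer)
    if (ptr > n || t[ptr] >= t1) return(integer(0))
    last <- ptr
    while (last < n && t[last + 1L] < t1) last <- last + 1L
    idx <- ptr:last
    ptr <<- last + 1L
    idx
  }
  # terrain changes truncate fixations: gaze redirects to the new sector's
  # distribution as soon as it is entered. Only boundaries where the
  # effective cell actually changes count (connecting areas share the
  # corridor cell, so corridor/unclassified transitions are seamless).
  eff_label <- function(tt) {
    L <- .label_at_times(tt, plan)
    ifelse(L %in% names(wp$cells), L, "corridor")
  }
  cand <- sort(unique(c(plan$t_start[plan$label != "excluded"],
                        plan$t_end[plan$label != "excluded"])))
  cand <- cand[cand > 0 & cand < t_end]
  bounds <- cand[eff_label(cand - 1e-9) != eff_label(cand)]
  next_bound <- function(tt) {
    nb <- bounds[bounds > tt + 1e-9]
    if (length(nb)) nb[1] else Inf
  }
  while (cur_t < t_end) {
    cp <- .cell_for(wp, .label_at_times(cur_t, plan))
    fm <- .fix_dur_mean(cp)
    d_f <- if (is.finite(fm)) {
      stats::rgamma(1, shape = cp$fix_dur_shape, scale = fm / cp$fix_dur_shape)
    } else {
      Inf
    }
    t1 <- min(cur_t + d_f, t_end, next_bound(cur_t))
    idx <- take(t1)
    if (length(idx)) {
      m <- length(idx)
      len <- abs(stats::rnorm(m, 0, cp$sigma_step))
      th <- .draw_step_dirs(m, cp$cardinal_bias)
      wx <- cumsum(len * cos(th))
      wy <- cumsum(len * -sin(th))  # screen y positive-down
      x[idx] <- cur_pos[1] + wx
      y[idx] <- cur_pos[2] + wy
      cur_pos <- c(x[idx[m]], y[idx[m]])
    }
    cur_t <- t1
    if (cur_t >= t_end) break
    # saccade to the next target
    cp2 <- .cell_for(wp, .label_at_times(cur_t, plan))
    # saccade direction follows the target geometry; the cardinal bias acts
    # on the (far more numerous) wander steps, which dominate the direction
    # histogram, so the engineered spatial distribution stays intact
    tgt <- .draw_target(cp2)
    disp <- tgt - cur_pos
    amp <- sqrt(sum(disp^2))
    d_s <- .sacc_duration(amp)
    t1s <- min(cur_t + d_s, t_end)
    idx <- take(t1s)
    if (length(idx)) {
      tau <- (t[idx] - cur_t) / d_s
      prog <- tau - sin(2 * pi * tau) / (2 * pi)
      x[idx] <- cur_pos[1] + disp[1] * prog
      y[idx] <- cur_pos[2] + disp[2] * prog
    }
    sacc[[length(sacc) + 1L]] <- c(onset = cur_t, offset = t1s, amplitude = amp)
    cur_pos <- tgt
    cur_t <- t1s
  }
  x_true <- x
  y_true <- y
  # linear drift
  x <- x + wp$drift_total[1] * t / t_end
  y <- y + wp$drift_total[2] * t / t_end
  # blinks: Poisson starts; rate set so E[unoccupied fraction] = valid_frac
  pupil <- 3 + 0.1 * stats::rnorm(n)
  if (wp$valid_frac < 1) {
    b_rate <- -log(wp$valid_frac) / wp$blink_dur_mean
    n_b <- stats::rpois(1, b_rate * t_end)
    if (n_b > 0) {
      b0 <- stats::runif(n_b, 0, t_end)
      b_dur <- stats::rgamma(n_b, shape = 2, scale = wp$blink_dur_mean / 2)
      blink <- rep(FALSE, n)
      for (k in seq_len(n_b)) {
        blink <- blink | (t >= b0[k] & t < b0[k] + b_dur[k])
      }
      pupil[blink] <- 0
      x[blink] <- NA_real_
      y[blink] <- NA_real_
    }
  }
  rec <- gaze_recording(t, x, y, pupil, participant_id = participant_id,
                        world = wp$world, nominal_rate = wp$rate_hz,
                        tracking_range = wp$tracking_range)
  # head pose: per-sector mean + AR(1) noise
  labs <- .label_at_times(t, plan)
  pitch_mean <- unname(wp$head_pitch[ifelse(labs %in% names(wp$head_pitch),
                                            labs, "corridor")])
  roll_mean <- unname(wp$head_roll[ifelse(labs %in% names(wp$head_roll),
                                          labs, "corridor")])
  innov_sd <- wp$head_noise_sd * sqrt(1 - wp$head_ar^2)
  ar1 <- function() {
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), wp$head_ar,
                             method = "recursive"))
  }
  head <- head_pose_track(t, pitch_mean + ar1(), roll_mean + ar1())
  # ground truth from the drift-free stream
  sacc_df <- if (length(sacc)) {
    as.data.frame(do.call(rbind, sacc))
  } else {
    data.frame(onset = numeric(0), offset = numeric(0), amplitude = numeric(0))
  }
  per_sector <- do.call(rbind, lapply(
    intersect(c("corridor", "ascending", "descending"), unique(labs)),
    function(L) {
      i <- labs == L
      q <- function(v) unname(stats::quantile(v, c(.25, .5, .75), type = 7))
      qx <- q(x_true[i]); qy <- q(y_true[i])
      data.frame(label = L, median_x = qx[2], median_y = qy[2],
                 iqr_x = qx[3] - qx[1], iqr_y = qy[3] - qy[1],
                 n = sum(i))
    }))
  structure(list(
    rec = rec, head = head, plan = plan, params = wp,
    truth = list(saccades = sacc_df, n_saccades = nrow(sacc_df),
                 per_sector = per_sector,
                 true_x = x_true, true_y = y_true,
                 drift_total = wp$drift_total,
                 valid_frac_target = wp$valid_frac)
  ), class = "gg_session")
}

#' Simulate an end-of-session validation grid
#'
#' The calibration grid is re-presented at session end; measured positions
#' equal the true targets plus the accumulated drift plus fixational noise.
#'
#' @param drift_total length-2 drift vector, degrees.
#' @param spacing grid spacing (horizontal, vertical), degrees.
#' @param noise_sd per-point measurement noise SD, degrees.
#' @return a [calibration_grid()].
#' @export
simulate_validation_grid <- function(drift_total, spacing = c(11.5, 10),
                                     noise_sd = 0.2) {
  tg <- calibration_targets(spacing)
  calibration_grid(tg[, 1], tg[, 2],
                   tg[, 1] + drift_total[1] + stats::rnorm(9, 0, noise_sd),
                   tg[, 2] + drift_total[2] + stats::rnorm(9, 0, noise_sd))
}

#' Simulate a within-subject cohort
#'
#' Generates both worlds for each of `n` participants with shared
#' participant-level random effects (gaze offset, rate / spread / T-shape
#' multipliers) plus a world-specific placement offset, per-session drawn
#' drift, and an end-of-session validation grid per session.
#'
#' @param n number of participants (>= 2).
#' @param params generator parameters as returned by [study_gen_params()];
#'   cells may be edited to inject effects before calling.
#' @param seed integer master seed; one derived seed per session makes
#'   cohorts reproducible session-by-session.
#' @param scale duration scale passed to [default_sector_plan()].
#' @param between between-subject SD list (overrides `params$between`).
#' @param drift `"study"` draws per-participant drift magnitudes from a
#'   gamma distribution with the per-world mean/SD in `params$drift` and a
#'   uniform random direction; `"none"` disables drift.
#' @param drift_in_stream also apply the drawn drift linearly to the gaze
#'   stream. Off by default: the cell centers are specified as
#'   session-average measured gaze statistics, which already embed placement
#'   and drift offsets, so adding the endpoint drift to the stream would
#'   double-count it; the drawn drift always shapes the end-of-session
#'   validation grid.
#' @param mu_y_shift optional 2 x 3 matrix (rows VR, RW; columns corridor,
#'   ascending, descending) added to the cell vertical centers, for
#'   injecting main effects or interactions.
#' @return list of class `gg_cohort`: per participant, a list with `VR` and
#'   `RW` session objects (each with an added `validation` grid).
#' @export
simulate_cohort <- function(n = 8, params = study_gen_params(), seed = 1,
                            scale = 1, between = NULL,
                            drift = c("study", "none"),
                            drift_in_stream = FALSE, mu_y_shift = NULL) {
  stopifnot(n >= 2)
  drift <- match.arg(drift)
  if (is.null(between)) between <- params$between
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, n * 2), n, 2)
  re <- list(
    mu_x = stats::rnorm(n, 0, between$sd_mu_x),
    mu_y = stats::rnorm(n, 0, between$sd_mu_y),
    mu_world = matrix(stats::rnorm(n * 2, 0, between$sd_mu_world), n, 2),
    log_rate = stats::rnorm(n, 0, between$sd_log_rate),
    log_spread = stats::rnorm(n, 0, between$sd_log_spread),
    log_tshape = stats::rnorm(n, 0, between$sd_log_tshape)
  )
  drift_draw <- matrix(0, n, 4)  # VRx VRy RWx RWy
  if (drift == "study") {
    for (w in 1:2) {
      dw <- params$drift[[c("VR", "RW")[w]]]
      shape <- (dw[["mean"]] / dw[["sd"]])^2
      mag <- stats::rgamma(n, shape = shape, scale = dw[["mean"]] / shape)
      ang <- stats::runif(n, 0, 2 * pi)
      drift_draw[, 2 * w - 1] <- mag * cos(ang)
      drift_draw[, 2 * w] <- mag * sin(ang)
    }
  }
  worlds <- c("VR", "RW")
  sectors <- c("corridor", "ascending", "descending")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("S%d", i)
    sess <- list()
    for (w in 1:2) {
      wp <- params[[worlds[w]]]
      for (s in seq_along(sectors)) {
        cp <- wp$cells[[sectors[s]]]
        cp$mu_x <- cp$mu_x + re$mu_x[i] + re$mu_world[i, w]
        cp$mu_y <- cp$mu_y + re$mu_y[i] + re$mu_world[i, w]
        if (!is.null(mu_y_shift)) cp$mu_y <- cp$mu_y + mu_y_shift[w, s]
        cp$sacc_rate <- cp$sacc_rate * exp(re$log_rate[i])
        cp$sigma_x <- cp$sigma_x * exp(re$log_spread[i])
        cp$sigma_y <- cp$sigma_y * exp(re$log_spread[i])
        cp$spread_ratio <- cp$spread_ratio * exp(re$log_tshape[i])
        wp$cells[[sectors[s]]] <- cp
      }
      d_i <- drift_draw[i, (2 * w - 1):(2 * w)]
      if (drift_in_stream) wp$drift_total <- d_i
      plan <- default_sector_plan(worlds[w], scale = scale)
      ss <- simulate_session(wp, plan, participant_id = pid,
                             seed = seeds[i, w])
      ss$validation <- simulate_validation_grid(
        d_i, spacing = if (worlds[w] == "VR") c(11.5, 10) else c(10, 10))
      ss$drift_drawn <- d_i
      sess[[worlds[w]]] <- ss
    }
    out[[i]] <- sess
  }
  structure(out, class = "gg_cohort", names = sprintf("S%d", seq_len(n)))
}

# trapezoid corner offsets (deg) for a marker of base width w, centered at c
.trap_corners <- function(cx, cy, w) {
  h <- 0.8 * w
  top <- 0.7 * w
  # counterclockwise in screen coords: bottom-left, bottom-right, top-right,
  # top-left (y positive-down)
  data.frame(x1 = cx - w / 2, y1 = cy + h / 2,
             x2 = cx + w / 2, y2 = cy + h / 2,
             x3 = cx + top / 2, y3 = cy - h / 2,
             x4 = cx - top / 2, y4 = cy - h / 2)
}

#' Simulate an AOI (navigational-marker) track for a session
#'
#' Generates per-frame trapezoid observations over the session's corridor
#' segments. Gaze is on the marker for a controlled fraction of corridor
#' time: on/off episodes alternate with exponential durations, the marker is
#' placed at the gaze point during on-episodes and a safe distance away
#' (beyond `threshold`) otherwise, and the trapezoid grows as each corridor
#' is traversed (approach). Detector confidence has a sub-threshold tail.
#' Marker placement is kept inside the real-world tracking extents so that
#' range harmonization drops only gaze-driven frames.
#'
#' @param session a `gg_session`.
#' @param threshold the on-marker distance criterion the analysis will use,
#'   degrees; off-episodes stay clear of it.
#' @param seed optional integer seed.
#' @return list with `track` (an `aoi_track`) and `truth`: the constructed
#'   on-episodes (`data.frame(t0, t1)`) and the target on-fraction.
#' @export
simulate_aoi_track <- function(session, threshold = 1, seed = NULL) {
  stopifnot(inherits(session, "gg_session"))
  if (!is.null(seed)) set.seed(seed)
  wp <- session$params
  plan <- session$plan
  corr <- plan[plan$label == "corridor", , drop = FALSE]
  if (!nrow(corr)) stop("session has no corridor segments")
  fr <- wp$aoi$frame_rate
  f <- wp$aoi$on_frac
  on_mean <- wp$aoi$on_dur_mean
  s <- session$rec$samples
  rows <- list()
  episodes <- list()
  rw_half <- c(30, 23) - 0.5  # keep whole trapezoid inside RW extents
  for (ci in seq_len(nrow(corr))) {
    t0c <- corr$t_start[ci]; t1c <- corr$t_end[ci]
    frame_t <- seq(t0c, t1c - 1e-9, by = 1 / fr)
    if (!length(frame_t)) next
    # on-episodes cover exactly the target fraction of each corridor:
    # n_ep glances of equal length at random non-overlapping positions
    on <- rep(FALSE, length(frame_t))
    dur_c <- t1c - t0c
    if (f > 0) {
      total_on <- f * dur_c
      n_ep <- max(1L, round(total_on / on_mean))
      ep_len <- total_on / n_ep
      gaps <- stats::runif(n_ep + 1)
      gaps <- gaps / sum(gaps) * (dur_c - total_on)
      starts <- t0c + cumsum(gaps)[seq_len(n_ep)] +
        (seq_len(n_ep) - 1L) * ep_len
      for (k in seq_len(n_ep)) {
        tt <- starts[k]; t_next <- tt + ep_len
        on[frame_t >= tt & frame_t < t_next] <- TRUE
        episodes[[length(episodes) + 1L]] <- c(t0 = tt, t1 = t_next)
      }
    }
    w <- 2 + 8 * (frame_t - t0c) / (t1c - t0c)  # marker grows on approach
    # nearest gaze sample per frame (marker anchor during on-episodes)
    gi <- findInterval(frame_t, s$t)
    gi[gi < 1] <- 1
    gx <- s$x[gi]; gy <- s$y[gi]
    gx[!is.finite(gx)] <- 0; gy[!is.finite(gy)] <- 0
    # all samples the analysis can assign to each frame (one frame interval):
    # off-placements must stay clear of every one of them, since gaze can
    # sweep several degrees within a frame during a saccade
    lo <- findInterval(frame_t - 1 / fr, s$t) + 1L
    hi <- findInterval(frame_t + 1 / fr, s$t)
    cx <- cy <- numeric(length(frame_t))
    half_w <- w / 2
    half_h <- 0.4 * w
    for (k in seq_along(frame_t)) {
      if (on[k]) {
        cx[k] <- gx[k]; cy[k] <- gy[k]
      } else {
        ii <- if (hi[k] >= lo[k]) seq.int(max(1L, lo[k]), hi[k]) else integer(0)
        sx <- s$x[ii]; sy <- s$y[ii]
        ok <- is.finite(sx) & is.finite(sy)
        if (any(ok)) {
          bx <- mean(range(sx[ok])); by <- mean(range(sy[ok]))
          srad <- sqrt(max((sx[ok] - bx)^2 + (sy[ok] - by)^2))
        } else {
          bx <- gx[k]; by <- gy[k]; srad <- 0
        }
        margin <- threshold + 1 + abs(stats::rnorm(1, 6, 3))
        dist_needed <- margin + srad + sqrt(half_w[k]^2 + half_h[k]^2)
        best <- -Inf
        for (ang in stats::runif(1, 0, 2 * pi) + (0:7) * pi / 4) {
          px <- min(max(bx + dist_needed * cos(ang), -rw_half[1] + half_w[k]),
                    rw_half[1] - half_w[k])
          py <- min(max(by + dist_needed * sin(ang), -rw_half[2] + half_h[k]),
                    rw_half[2] - half_h[k])
          # achievable clearance after clamping into the tracking extents
          clr <- sqrt((px - bx)^2 + (py - by)^2) - srad -
            sqrt(half_w[k]^2 + half_h[k]^2)
          if (clr > best) {
            best <- clr
            cx[k] <- px; cy[k] <- py
          }
          if (clr >= margin - 1e-9) break
        }
      }
      # clamp inside RW extents (on-frames near the border)
      cx[k] <- min(max(cx[k], -rw_half[1] + half_w[k]), rw_half[1] - half_w[k])
      cy[k] <- min(max(cy[k], -rw_half[2] + half_h[k]), rw_half[2] - half_h[k])
    }
    conf <- 0.9 + 0.1 * stats::rbeta(length(frame_t), 2, 1)
    low <- stats::runif(length(frame_t)) < wp$aoi$low_conf_frac
    conf[low] <- stats::runif(sum(low), 0.3, 0.9)
    rows[[ci]] <- cbind(data.frame(frame_t = frame_t),
                        .trap_corners(cx, cy, w),
                        data.frame(confidence = conf))
  }
  track <- as_aoi_track(do.call(rbind, rows))
  ep <- if (length(episodes)) {
    as.data.frame(do.call(rbind, episodes))
  } else {
    data.frame(t0 = numeric(0), t1 = numeric(0))
  }
  list(track = track, truth = list(on_episodes = ep,
                                   on_frac_target = f))
}

#' Simulate a horizon trace for a session
#'
#' Generates a per-frame vertical horizon position (in head-centered
#' degrees, positive down) over the session's corridor segments, such that
#' gaze lies on average `horizon_below` degrees below the horizon: the
#' horizon is placed at the participant's true corridor median gaze minus
#' that distance, plus AR(1) head-bobbing noise. This is the ground-truth
#' counterpart of video-based horizon tracking; it shares any
#' headset-placement offset with the gaze stream, which is exactly what
#' eye-in-world referencing is meant to cancel.
#'
#' @param session a `gg_session` whose world parameters set
#'   `horizon_below`.
#' @param frame_rate frames per second of the simulated scene video.
#' @param noise_sd SD of the horizon-position noise, degrees.
#' @param seed optional integer seed.
#' @return data.frame with `frame_t` and `y` (degrees, positive-down),
#'   usable directly by [eye_in_world_vertical()] with `px_to_deg = 1`.
#' @export
simulate_horizon_trace <- function(session, frame_rate = 25, noise_sd = 0.3,
                                   seed = NULL) {
  stopifnot(inherits(session, "gg_session"))
  if (!is.null(seed)) set.seed(seed)
  h <- session$params$horizon_below
  if (is.null(h)) stop("world params do not define horizon_below")
  per <- session$truth$per_sector
  mu_corr <- per$median_y[per$label == "corridor"]
  if (!length(mu_corr)) stop("session has no corridor sectors")
  plan <- session$plan
  corr <- plan[plan$label == "corridor", , drop = FALSE]
  rows <- lapply(seq_len(nrow(corr)), function(ci) {
    ft <- seq(corr$t_start[ci], corr$t_end[ci] - 1e-9, by = 1 / frame_rate)
    ar <- as.numeric(stats::filter(stats::rnorm(length(ft), 0,
                                                noise_sd * sqrt(1 - 0.9^2)),
                                   0.9, method = "recursive"))
    data.frame(frame_t = ft, y = mu_corr - h + ar,
               sector_index = corr$sector_index[ci])
  })
  do.call(rbind, rows)
}

#' Simulate a vertically shifting frame stack
#'
#' Builds a textured grayscale base image and emits `n_frames` copies, each
#' translated vertically by the corresponding trace value (linear
#' interpolation for fractional shifts) plus pixel noise. Fixture generator
#' for the horizon tracker.
#'
#' @param n_frames number of frames.
#' @param shift_trace numeric vertical shift per frame, pixels (positive =
#'   image content moves down); length `n_frames`.
#' @param noise_sd pixel noise SD as a fraction of the image dynamic range.
#' @param height,width frame size, pixels.
#' @param seed optional integer seed.
#' @return list with `frames` (array height x width x n_frames, values in
#'   [0, 1] plus noise) and `trace` (the true shifts).
#' @export
simulate_horizon_frames <- function(n_frames, shift_trace, noise_sd = 0,
                                    height = 80, width = 120, seed = NULL) {
  stopifnot(length(shift_trace) == n_frames)
  if (!is.null(seed)) set.seed(seed)
  pad <- ceiling(max(abs(shift_trace))) + 2L
  base <- matrix(stats::rnorm((height + 2 * pad) * width), height + 2 * pad,
                 width)
  base <- .smooth2d(base, 1.5)
  base <- (base - min(base)) / diff(range(base))
  frames <- array(0, dim = c(height, width, n_frames))
  rows <- seq_len(height) + pad
  for (i in seq_len(n_frames)) {
    sh <- shift_trace[i]
    lo <- floor(sh)
    frac <- sh - lo
    # content moves down by sh: frame row r shows base row r - sh
    f <- (1 - frac) * base[rows - lo, , drop = FALSE] +
      frac * base[rows - lo - 1L, , drop = FALSE]
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    frames[, , i] <- f
  }
  list(frames = frames, trace = shift_trace)
}
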