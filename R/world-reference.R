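# normalized cross-correlation of a template against a search region,
# returning the (dy, dx) displacement of the best match
.ncc_shift <- function(template, frame, center, search) {
  th <- nrow(template); tw <- ncol(template)
  hh <- (th - 1L) %/% 2L; hw <- (tw - 1L) %/% 2L
  tm <- template - mean(template)
  tden <- sqrt(sum(tm^2))
  best <- -Inf
  best_dy <- best_dx <- 0L
  scores <- matrix(NA_real_, 2 * search + 1, 2 * search + 1)
  for (dy in -search:search) {
    r0 <- center[1] + dy - hh
    if (r0 < 1 || r0 + th - 1 > nrow(frame)) next
    for (dx in -search:search) {
      c0 <- center[2] + dx - hw
      if (c0 < 1 || c0 + tw - 1 > ncol(frame)) next
      sub <- frame[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)]
      sm <- sub - mean(sub)
      den <- tden * sqrt(sum(sm^2))
      sc <- if (den > 0) sum(tm * sm) / den else 0
      scores[dy + search + 1L, dx + search + 1L] <- sc
      if (sc > best) {
        best <- sc
        best_dy <- dy
        best_dx <- dx
      }
    }
  }
  at_edge <- abs(best_dy) == search || abs(best_dx) == search
  # parabolic sub-pixel refinement on the vertical axis; skipped on a
  # perfect match, where the integer peak is already exact
  iy <- best_dy + search + 1L
  ix <- best_dx + search + 1L
  dy_ref <- best_dy
  if (best < 1 - 1e-6 && iy > 1 && iy < nrow(scores)) {
    s0 <- scores[iy - 1L, ix]; s1 <- scores[iy, ix]; s2 <- scores[iy + 1L, ix]
    if (all(is.finite(c(s0, s1, s2))) && (s0 - 2 * s1 + s2) < 0) {
      dy_ref <- best_dy + 0.5 * (s0 - s2) / (s0 - 2 * s1 + s2)
    }
  }
  list(dy = dy_ref, dx = best_dx, score = best, at_edge = at_edge)
}

#' Track the horizon through a frame stack
#'
#' Hybrid manual/correlation tracking: every ninth frame carries a manual
#' horizon mark, used as the reference point of a correlation tracker that
#' assigns displacements to the 4 preceding and 4 following frames via the
#' peak of the normalized 2D cross-correlation of a patch centered on the
#' mark. Every frame is assigned exactly once; keyframes pass through their
#' marks with zero error. Remainder frames at the stack edges attach to the
#' nearest keyframe.
#'
#' @param frames array `height x width x n` of grayscale values.
#' @param keyframes data.frame with columns `frame` (1-based index, cadence
#'   9) and `y` (marked horizon row, pixels).
#' @param patch square patch size in pixels (default 32).
#' @param search half-width of the displacement search window, pixels.
#' @return data.frame of class `horizon_trace` with columns `frame`, `y`
#'   (pixels), `source` (`"keyframe"` or `"tracked"`), and `low_confidence`
#'   (correlation peak at the search-window edge).
#' @export
track_horizon <- function(frames, keyframes, patch = 32, search = 12) {
  stopifnot(length(dim(frames)) == 3, all(c("frame", "y") %in% names(keyframes)))
  n <- dim(frames)[3]
  h <- dim(frames)[1]; w <- dim(frames)[2]
  kf <- keyframes[order(keyframes$frame), , drop = FALSE]
  if (nrow(kf) > 1 && any(diff(kf$frame) != 9)) {
    stop("keyframe marks must be provided every 9 frames")
  }
  y <- rep(NA_real_, n)
  src <- rep("tracked", n)
  low <- rep(FALSE, n)
  hp <- (patch - 1L) %/% 2L
  cx <- as.integer(round(w / 2))
  # which keyframe serves each frame: nearest, ties to the earlier one
  owner <- vapply(seq_len(n), function(i) {
    which.min(abs(kf$frame - i))
  }, 1L)
  for (k in seq_len(nrow(kf))) {
    fk <- kf$frame[k]
    yk <- kf$y[k]
    y[fk] <- yk
    src[fk] <- "keyframe"
    cy <- as.integer(round(yk))
    r0 <- max(1L, min(cy - hp, h - patch + 1L))
    template <- frames[r0:(r0 + patch - 1L), max(1L, cx - hp):min(w, cx - hp + patch - 1L), fk]
    tc <- c(r0 + hp, cx)
    for (i in seq_len(n)) {
      if (owner[i] != k || i == fk) next
      res <- .ncc_shift(template, frames[, , i], tc, search)
      y[i] <- yk + res$dy
      low[i] <- res$at_edge
    }
  }
  structure(data.frame(frame = seq_len(n), y = y, source = src,
                       low_confidence = low),
            class = c("horizon_trace", "data.frame"))
}

#' Attach frame times to a horizon trace
#'
#' @param trace a `horizon_trace`.
#' @param frame_t numeric frame times, seconds (length = rows of trace).
#' @return the trace with a `frame_t` column.
#' @export
horizon_trace_times <- function(trace, frame_t) {
  stopifnot(length(frame_t) == nrow(trace))
  trace$frame_t <- frame_t
  trace
}

#' Vertical gaze relative to the horizon (eye-in-world)
#'
#' Subtracts the frame-by-frame horizon position from vertical gaze, giving
#' gaze referenced to the world rather than the head. Both inputs use the
#' positive-down convention, so positive values mean gaze below the horizon.
#' Headset-placement offsets move gaze and horizon together and cancel out.
#' Gaze samples are aligned to the nearest frame (gaze rate >= frame rate).
#'
#' @param rec a `gaze_recording` (or sample data.frame with `t`, `y`).
#' @param trace a `horizon_trace` with a `frame_t` column (see
#'   [horizon_trace_times()]); `y` in pixels unless `px_to_deg = 1` and
#'   already degrees.
#' @param px_to_deg degrees per pixel.
#' @param horizon_ref pixel row corresponding to 0 deg (straight ahead);
#'   horizon degrees = `(y - horizon_ref) * px_to_deg`.
#' @return data.frame with `t`, `eye_in_world_y` (degrees, positive below
#'   horizon) for valid samples covered by the trace.
#' @export
eye_in_world_vertical <- function(rec, trace, px_to_deg = 1, horizon_ref = 0) {
  s <- gaze_samples(rec, valid_only = TRUE)
  if (is.null(trace$frame_t)) stop("trace needs frame times; see horizon_trace_times()")
  tr <- trace[is.finite(trace$y), , drop = FALSE]
  if (!nrow(tr)) stop("trace has no finite horizon values")
  # nearest-frame assignment
  idx <- findInterval(s$t, tr$frame_t)
  idx[idx < 1] <- 1L
  nxt <- pmin(idx + 1L, nrow(tr))
  use_next <- abs(tr$frame_t[nxt] - s$t) < abs(s$t - tr$frame_t[idx])
  idx[use_next] <- nxt[use_next]
  # only samples within half a frame interval of an observed frame
  med_dt <- if (nrow(tr) > 1) stats::median(diff(tr$frame_t)) else Inf
  keep <- abs(s$t - tr$frame_t[idx]) <= med_dt
  horizon_deg <- (tr$y[idx] - horizon_ref) * px_to_deg
  data.frame(t = s$t[keep],
             eye_in_world_y = s$y[keep] - horizon_deg[keep])
}

#' Head-orientation statistics referenced to the corridors
#'
#' The headset's zero orientation depends on how it sits on each head, so
#' per-sector head statistics are referenced to the participant's mean
#' orientation during the corridor sectors. Pitch (positive down) and roll
#' (positive rightward tilt) are summarized per sector by the referenced
#' mean and the IQR; yaw is not analyzed (contaminated by route turns).
#'
#' @param track a `head_pose_track`.
#' @param map a [sector_map()].
#' @return data.frame with one row per sector label present: `label`,
#'   `mean_pitch`, `iqr_pitch`, `mean_roll`, `iqr_roll` (degrees,
#'   corridor-referenced), `n`.
#' @export
head_stats <- function(track, map) {
  stopifnot(inherits(track, "head_pose_track"))
  labs <- .label_at_times(track$t, map)
  in_corr <- labs == "corridor"
  if (!any(in_corr)) stop("no corridor samples; cannot establish zero reference")
  ref_pitch <- mean(track$pitch[in_corr])
  ref_roll <- mean(track$roll[in_corr])
  sectors <- intersect(c("corridor", "ascending", "descending"), unique(labs))
  do.call(rbind, lapply(sectors, function(L) {
    i <- labs == L
    data.frame(label = L,
               mean_pitch = mean(track$pitch[i]) - ref_pitch,
               iqr_pitch = stats::IQR(track$pitch[i], type = 7),
               mean_roll = mean(track$roll[i]) - ref_roll,
               iqr_roll = stats::IQR(track$roll[i], type = 7),
               n = sum(i))
  }))
}
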