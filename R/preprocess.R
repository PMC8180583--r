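#' Mark invalid gaze samples
#'
#' Samples are marked invalid wherever the pupil-size proxy is zero (lid
#' closure or pupil outside the camera's tracking area) or the gaze
#' coordinates are non-finite; all other samples are valid. Gaze values are
#' left untouched.
#'
#' @param rec a `gaze_recording` with a pupil column.
#' @param verbose message the invalid count.
#' @return the recording with its `valid` flags recomputed.
#' @export
mark_invalid_samples <- function(rec, verbose = FALSE) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  rec$samples$valid <- s$pupil > 0 & is.finite(s$x) & is.finite(s$y)
  if (verbose) {
    message(sum(!rec$samples$valid), " of ", nrow(s),
            " samples marked invalid")
  }
  rec
}

#' Construct a calibration grid
#'
#' Nine point pairs from a 3x3 marker grid: known target positions in
#' degrees and the corresponding raw tracker readings. Used both for fitting
#' the raw-to-degrees calibration map at session start and for drift
#' estimation from the validation grid at session end.
#'
#' @param true_x,true_y known target positions, degrees.
#' @param meas_x,meas_y raw tracker readings at those targets.
#' @param point_id optional ids.
#' @return data.frame of class `calibration_grid`.
#' @export
calibration_grid <- function(true_x, true_y, meas_x, meas_y,
                             point_id = seq_along(true_x)) {
  n <- length(true_x)
  stopifnot(length(true_y) == n, length(meas_x) == n, length(meas_y) == n)
  structure(data.frame(point_id = point_id, true_x = true_x, true_y = true_y,
                       meas_x = meas_x, meas_y = meas_y),
            class = c("calibration_grid", "data.frame"))
}

#' Standard 3x3 calibration target layout
#'
#' Targets at the crossings of a 3x3 grid centered on straight ahead. The VR
#' markers were spaced 11.5 deg horizontally and 10 deg vertically; the RW
#' markers 10 deg in both directions.
#'
#' @param spacing numeric length-2 (horizontal, vertical) spacing in degrees.
#' @return 9x2 matrix of (x, y) target positions.
#' @export
calibration_targets <- function(spacing = c(11.5, 10)) {
  g <- expand.grid(x = c(-1, 0, 1) * spacing[1], y = c(-1, 0, 1) * spacing[2])
  as.matrix(g)
}

.poly_terms <- function(x, y, order) {
  stopifnot(order >= 1)
  cols <- list()
  nm <- character(0)
  for (total in 0:order) {
    for (i in total:0) {
      j <- total - i
      cols[[length(cols) + 1L]] <- x^i * y^j
      nm <- c(nm, paste0("x", i, "y", j))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Fit a polynomial calibration map
#'
#' Least-squares fit of a 2-dimensional polynomial mapping raw tracker
#' readings onto the known grid positions, one polynomial per output channel.
#' The default full bivariate quadratic (6 coefficients per channel) is
#' identifiable from the 9 grid points.
#'
#' @param grid a [calibration_grid()].
#' @param order polynomial order (>= 1); coefficient count per channel must
#'   not exceed the number of points.
#' @return object of class `calibration_model` with per-channel coefficients
#'   and the fit residual RMS in degrees.
#' @export
fit_calibration <- function(grid, order = 2) {
  stopifnot(inherits(grid, "calibration_grid"))
  X <- .poly_terms(grid$meas_x, grid$meas_y, order)
  if (ncol(X) > nrow(X)) {
    stop("order ", order, " needs ", ncol(X), " coefficients but only ",
         nrow(X), " points are available")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient calibration design (collinear points?)")
  bx <- qr.coef(qrX, grid$true_x)
  by <- qr.coef(qrX, grid$true_y)
  res <- cbind(grid$true_x - X %*% bx, grid$true_y - X %*% by)
  structure(list(order = order, coef_x = bx, coef_y = by,
                 residual_rms = sqrt(mean(res^2))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> order %d, residual RMS %.3g deg\n",
              x$order, x$residual_rms))
  invisible(x)
}

#' Apply a calibration map to a recording
#'
#' Replaces the gaze columns by their calibrated values; validity flags are
#' untouched and `NA` samples stay `NA`.
#'
#' @param model a fitted `calibration_model`.
#' @param rec a `gaze_recording` holding raw readings.
#' @return the calibrated recording.
#' @export
apply_calibration <- function(model, rec) {
  stopifnot(inherits(model, "calibration_model"),
            inherits(rec, "gaze_recording"))
  s <- rec$samples
  ok <- is.finite(s$x) & is.finite(s$y)
  if (any(ok)) {
    X <- .poly_terms(s$x[ok], s$y[ok], model$order)
    rec$samples$x[ok] <- as.numeric(X %*% model$coef_x)
    rec$samples$y[ok] <- as.numeric(X %*% model$coef_y)
  }
  rec
}

#' Estimate drift from an end-of-session validation grid
#'
#' Headset slippage over a session shifts all measured gaze by a common
#' offset. Re-presenting the calibration grid at session end and comparing
#' measured (already calibrated) against true positions estimates that
#' offset: per-point offsets `measured - true`, their componentwise mean
#' vector, and the mean Euclidean offset magnitude.
#'
#' @param end_grid a [calibration_grid()] recorded at session end, with
#'   `meas_*` in calibrated degrees.
#' @return list with `mean_offset` (length-2), `mean_magnitude` (scalar,
#'   degrees) and `offsets` (n x 2 matrix).
#' @export
estimate_drift <- function(end_grid) {
  stopifnot(inherits(end_grid, "calibration_grid"))
  if (nrow(end_grid) < 9) {
    warning("only ", nrow(end_grid), " validation points; computing on those")
  }
  off <- cbind(dx = end_grid$meas_x - end_grid$true_x,
               dy = end_grid$meas_y - end_grid$true_y)
  list(mean_offset = colMeans(off),
       mean_magnitude = mean(sqrt(rowSums(off^2))),
       offsets = off)
}

#' Flag samples inside exclusion windows
#'
#' Periods of equipment disturbance are excluded from analysis. Samples
#' falling in any `excluded` window of the map get `excluded = TRUE`; they
#' are flagged, never deleted, so audits can recount them. Overlapping
#' windows exclude their union once.
#'
#' @param rec a `gaze_recording`.
#' @param map a [sector_map()] whose `excluded` rows define the windows.
#' @return the recording with its `excluded` flags set.
#' @export
apply_exclusion_windows <- function(rec, map) {
  stopifnot(inherits(rec, "gaze_recording"))
  t <- rec$samples$t
  exc <- rep(FALSE, length(t))
  for (i in which(map$label == "excluded")) {
    exc <- exc | (t >= map$t_start[i] & t < map$t_end[i])
  }
  rec$samples$excluded <- exc
  rec
}

#' Read a calibration grid table
#'
#' Columns: `point_id, true_x, true_y, meas_x, meas_y`.
#' @param path file path.
#' @return a `calibration_grid`.
#' @export
read_calibration_grid <- function(path) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
                           stringsAsFactors = FALSE)
  calibration_grid(tab$true_x, tab$true_y, tab$meas_x, tab$meas_y,
                   point_id = tab$point_id)
}
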