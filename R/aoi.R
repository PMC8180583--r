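#' Construct a trapezoid AOI
#'
#' A simple (non-self-intersecting) quadrilateral in head-centered degrees,
#' stored with a consistent winding order.
#'
#' @param corners 4 x 2 matrix of (x, y) corner coordinates, degrees, in
#'   boundary order.
#' @return matrix of class `trapezoid`.
#' @export
trapezoid <- function(corners) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4, ncol(corners) == 2, all(is.finite(corners)))
  a2 <- .polygon_area2(corners)
  if (abs(a2) < 1e-12) stop("degenerate quadrilateral (zero area)")
  if (.self_intersects(corners)) stop("self-intersecting quadrilateral")
  if (a2 < 0) corners <- corners[4:1, , drop = FALSE]  # normalize winding
  structure(corners, class = c("trapezoid", "matrix"))
}

# twice the signed area (shoelace)
.polygon_area2 <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

.seg_intersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.self_intersects <- function(p) {
  .seg_intersects(p[1, ], p[2, ], p[3, ], p[4, ]) ||
    .seg_intersects(p[2, ], p[3, ], p[4, ], p[1, ])
}

# even-odd ray casting; boundary points may go either way (distance handles
# them: they are at distance 0 from an edge anyway)
.in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.point_seg_dist <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 > 0) pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1) else 0
  sqrt((px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2)
}

#' Angular distance from gaze to an AOI trapezoid
#'
#' Distance from a gaze point to the nearest point of the filled
#' quadrilateral: 0 when the point is inside or on the boundary, otherwise
#' the Euclidean distance to the nearest boundary point. Vectorized over
#' gaze points.
#'
#' @param px,py gaze coordinates, degrees (vectors of equal length).
#' @param trap a [trapezoid()] (or 4 x 2 corner matrix).
#' @return numeric vector of distances in degrees.
#' @export
gaze_aoi_distance <- function(px, py, trap) {
  if (!inherits(trap, "trapezoid")) trap <- trapezoid(trap)
  stopifnot(length(px) == length(py))
  d <- pmin(.point_seg_dist(px, py, trap[1, ], trap[2, ]),
            .point_seg_dist(px, py, trap[2, ], trap[3, ]),
            .point_seg_dist(px, py, trap[3, ], trap[4, ]),
            .point_seg_dist(px, py, trap[4, ], trap[1, ]))
  d[.in_polygon(px, py, trap)] <- 0
  d
}

#' Fit a quadrilateral to a binary mask
#'
#' Recovers the 4 corner coordinates of a rendered marker from its binary
#' pixel mask: the convex hull of the foreground pixel centers is computed,
#' and the 4 hull vertices spanning the maximum-area quadrilateral are taken
#' as corners (for an axis-aligned rectangle this recovers its pixel-center
#' corners exactly). Pixel coordinates are `(col, row)`, converted to
#' degrees by `px_to_deg` around `origin`.
#'
#' @param mask logical (or 0/1) matrix; `TRUE` = foreground.
#' @param px_to_deg degrees per pixel.
#' @param origin pixel coordinates (col, row) of 0 degrees.
#' @return a [trapezoid()] in degrees.
#' @export
fit_trapezoid <- function(mask, px_to_deg = 1, origin = c(0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask must contain at least 4 foreground pixels")
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  hull <- grDevices::chull(pts)  # clockwise indices
  hp <- pts[hull, , drop = FALSE]
  if (nrow(hp) < 3 || abs(.polygon_area2(hp)) < 1e-9) {
    stop("degenerate (collinear) mask; cannot fit a quadrilateral")
  }
  if (nrow(hp) == 3) stop("mask hull is a triangle; cannot fit a quadrilateral")
  best <- NULL
  best_a <- -Inf
  combs <- utils::combn(nrow(hp), 4)
  for (k in seq_len(ncol(combs))) {
    q <- hp[combs[, k], , drop = FALSE]  # hull order preserved -> simple
    a <- abs(.polygon_area2(q)) / 2
    if (a > best_a) {
      best_a <- a
      best <- q
    }
  }
  deg <- cbind((best[, 1] - origin[1]) * px_to_deg,
               (best[, 2] - origin[2]) * px_to_deg)
  trapezoid(deg)
}

.track_corners <- function(track, i) {
  matrix(c(track$x1[i], track$y1[i], track$x2[i], track$y2[i],
           track$x3[i], track$y3[i], track$x4[i], track$y4[i]),
         4, 2, byrow = TRUE)
}

#' Harmonize AOI frames to a common tracking range
#'
#' The VR tracker covers a much larger field than the RW tracker, which
#' would exaggerate gaze-to-marker distances in VR. Frames are kept only
#' when the gaze point and the whole trapezoid lie within the given extents
#' (full width/height centered on straight ahead; half-extents 30 and 23
#' degrees for the RW device).
#'
#' @param gaze_xy 2-column matrix of gaze points aligned to the AOI frames.
#' @param track an `aoi_track` (same number of rows).
#' @param range full extents (width, height), degrees.
#' @return logical vector: frame kept.
#' @export
filter_to_tracking_range <- function(gaze_xy, track, range = c(60, 46)) {
  stopifnot(nrow(gaze_xy) == nrow(track))
  hw <- range[1] / 2; hh <- range[2] / 2
  gaze_ok <- abs(gaze_xy[, 1]) <= hw & abs(gaze_xy[, 2]) <= hh
  xs <- as.matrix(track[, c("x1", "x2", "x3", "x4")])
  ys <- as.matrix(track[, c("y1", "y2", "y3", "y4")])
  trap_ok <- apply(abs(xs) <= hw, 1, all) & apply(abs(ys) <= hh, 1, all)
  gaze_ok & trap_ok & !is.na(gaze_ok)
}

#' Dwell time on AOI markers
#'
#' Fraction of analyzed time during which gaze rests on a marker: AOI
#' observations are confidence-thresholded, each valid gaze sample is
#' assigned the nearest AOI frame (within one frame interval), the angular
#' distance to the filled trapezoid is computed, and a sample counts as
#' on-marker when that distance is at most `threshold`. The denominator is
#' the total valid analyzed sample time; the mean distance is reported over
#' samples with a visible marker.
#'
#' @param seg a `gaze_recording` segment (typically corridor segments) or
#'   sample data.frame.
#' @param track an `aoi_track`.
#' @param threshold on-marker distance criterion, degrees.
#' @param confidence_min observations with confidence not above this are
#'   discarded.
#' @param range optional full extents (width, height) for
#'   [filter_to_tracking_range()] harmonization (`NULL` = no filtering).
#' @return list with `dwell_frac`, `mean_distance` (degrees), `n_on`,
#'   `n_analyzed`, `n_visible`. With no marker-visible frames, `dwell_frac`
#'   is 0 and `mean_distance` `NaN` with a warning.
#' @export
dwell_time <- function(seg, track, threshold = 1, confidence_min = 0.9,
                       range = NULL) {
  s <- gaze_samples(seg, valid_only = TRUE)
  if (!nrow(s)) stop("no valid samples to analyze")
  tr <- track[track$confidence > confidence_min, , drop = FALSE]
  n_analyzed <- nrow(s)
  dist <- rep(NA_real_, nrow(s))
  if (nrow(tr)) {
    med_dt <- if (nrow(tr) > 1) stats::median(diff(tr$frame_t)) else Inf
    idx <- findInterval(s$t, tr$frame_t)
    idx[idx < 1] <- 1L
    nxt <- pmin(idx + 1L, nrow(tr))
    use_next <- abs(tr$frame_t[nxt] - s$t) < abs(s$t - tr$frame_t[idx])
    idx[use_next] <- nxt[use_next]
    visible <- abs(s$t - tr$frame_t[idx]) <= med_dt
    if (!is.null(range)) {
      frame_ok <- filter_to_tracking_range(cbind(s$x, s$y), tr[idx, ], range)
      # frames failing harmonization leave the analysis entirely
      drop <- visible & !frame_ok
      n_analyzed <- n_analyzed - sum(drop)
      visible <- visible & frame_ok
    }
    by_frame <- split(which(visible), idx[visible])
    for (f in names(by_frame)) {
      i <- by_frame[[f]]
      dist[i] <- gaze_aoi_distance(s$x[i], s$y[i],
                                   .track_corners(tr, as.integer(f)))
    }
  }
  vis <- is.finite(dist)
  if (!any(vis)) {
    warning("no marker-visible frames; mean distance undefined")
    return(list(dwell_frac = 0, mean_distance = NaN, n_on = 0L,
                n_analyzed = n_analyzed, n_visible = 0L))
  }
  on <- vis & dist <= threshold
  list(dwell_frac = sum(on) / n_analyzed,
       mean_distance = mean(dist[vis]),
       n_on = sum(on), n_analyzed = n_analyzed, n_visible = sum(vis))
}
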