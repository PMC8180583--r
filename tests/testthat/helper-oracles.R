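# Independent oracles and small fixture builders used across the suite.

# plain recording from coordinate vectors at a fixed rate
make_rec <- function(x, y, rate = 120, pupil = NULL, world = "VR", ...) {
  t <- (seq_along(x) - 1) / rate
  gaze_recording(t, x, y, pupil = pupil, world = world,
                 nominal_rate = rate, ...)
}

# sort-based quantile oracle (linear interpolation between order statistics)
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
oracle_median <- function(v) oracle_quantile(v, 0.5)
oracle_iqr <- function(v) oracle_quantile(v, 0.75) - oracle_quantile(v, 0.25)

# ---- repeated-measures ANOVA oracle: explicit projection matrices ----------

# y: n x 2 x 3 array -> per-effect F/p via sequential projections on the
# full 6n-observation design (balanced, so projections are orthogonal)
oracle_rm_anova <- function(y) {
  n <- dim(y)[1]
  d <- expand.grid(subject = factor(seq_len(n)), world = factor(1:2),
                   sector = factor(1:3))
  d$value <- as.vector(y)
  proj_norm2 <- function(form) {
    X <- stats::model.matrix(form, d)
    Q <- qr.Q(qr(X))
    sum((t(Q) %*% d$value)^2)
  }
  ss <- function(full, reduced) proj_norm2(full) - proj_norm2(reduced)
  ss_world <- ss(~ subject + world, ~ subject)
  ss_sector <- ss(~ subject + sector, ~ subject)
  ss_ws <- ss(~ subject + world * sector, ~ subject + world + sector)
  ss_sw_err <- ss(~ world + subject * world, ~ world + subject)
  ss_ss_err <- ss(~ sector + subject * sector, ~ sector + subject)
  ss_tot <- sum((d$value - mean(d$value))^2)
  ss_subj <- proj_norm2(~ subject) - proj_norm2(~ 1)
  ss_res <- ss_tot - ss_subj - ss_world - ss_sector - ss_ws -
    ss_sw_err - ss_ss_err
  eff <- data.frame(
    effect = c("world", "sector", "world:sector"),
    ssn = c(ss_world, ss_sector, ss_ws),
    df1 = c(1, 2, 2),
    sse = c(ss_sw_err, ss_ss_err, ss_res),
    df2 = c(n - 1, 2 * (n - 1), 2 * (n - 1)))
  eff$F <- (eff$ssn / eff$df1) / (eff$sse / eff$df2)
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  # Box epsilon via double-centered covariance (independent of the
  # orthonormal-contrast eigenvalue route used by the implementation)
  box_eps <- function(M) {
    k <- ncol(M)
    S <- stats::cov(M)
    H <- diag(k) - matrix(1 / k, k, k)
    D <- H %*% S %*% H
    sum(diag(D))^2 / ((k - 1) * sum(D * D))
  }
  # Mauchly W via determinant of the contrast covariance
  mauchly_p <- function(M) {
    k <- ncol(M)
    C <- qr.Q(qr(stats::contr.helmert(k)))
    S <- t(C) %*% stats::cov(M) %*% C
    p <- k - 1
    if (nrow(M) - 1 <= p) return(NA_real_)
    W <- det(S) / (sum(diag(S)) / p)^p
    dd <- 1 - (2 * p^2 + p + 2) / (6 * p * (nrow(M) - 1))
    stats::pchisq(-(nrow(M) - 1) * dd * log(W), p * (p + 1) / 2 - 1,
                  lower.tail = FALSE)
  }
  m_is <- apply(y, c(1, 3), mean)
  d_ws <- y[, 1, ] - y[, 2, ]
  eff$epsilon <- c(1, box_eps(m_is), box_eps(d_ws))
  eff$mauchly_p <- c(NA_real_, mauchly_p(m_is), mauchly_p(d_ws))
  eff$p_gg <- stats::pf(eff$F, eff$df1 * eff$epsilon, eff$df2 * eff$epsilon,
                        lower.tail = FALSE)
  eff
}

# long-format table matching the array layout (world index 1/2, sector 1/2/3)
cells_to_long <- function(y) {
  n <- dim(y)[1]
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n)),
                   world = c("W1", "W2"), sector = c("A", "B", "C"))
  d$value <- as.vector(y)
  d
}

# ---- point-to-quadrilateral distance oracle --------------------------------

# convex inside test via triangle-area decomposition, distance via dense
# boundary sampling
oracle_quad_distance <- function(px, py, quad, m = 20000) {
  tri_area <- function(a, b, c) {
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  qa <- tri_area(quad[1, ], quad[2, ], quad[3, ]) +
    tri_area(quad[1, ], quad[3, ], quad[4, ])
  pa <- sum(sapply(1:4, function(i) {
    j <- i %% 4 + 1
    tri_area(quad[i, ], quad[j, ], c(px, py))
  }))
  if (abs(pa - qa) < 1e-9 * max(1, qa)) return(0)
  dmin <- Inf
  for (i in 1:4) {
    j <- i %% 4 + 1
    s <- seq(0, 1, length.out = m)
    bx <- quad[i, 1] + s * (quad[j, 1] - quad[i, 1])
    by <- quad[i, 2] + s * (quad[j, 2] - quad[i, 2])
    dmin <- min(dmin, sqrt(min((px - bx)^2 + (py - by)^2)))
  }
  dmin
}

# random convex quadrilateral: 4 random points whose convex hull is a quad
random_convex_quad <- function(center = c(0, 0), radius = 5) {
  repeat {
    p <- cbind(center[1] + stats::runif(4, -radius, radius),
               center[2] + stats::runif(4, -radius, radius))
    h <- grDevices::chull(p)
    if (length(h) == 4) {
      q <- p[h, , drop = FALSE]
      # reject near-degenerate quads (tiny area relative to extent)
      a2 <- abs(sum(q[, 1] * q[c(2:4, 1), 2] - q[c(2:4, 1), 1] * q[, 2]))
      if (a2 > 0.2 * radius^2) return(q)
    }
  }
}

# rasterize a convex quad onto a pixel grid using the triangle-area test
rasterize_quad <- function(quad, nrow_px, ncol_px) {
  mask <- matrix(FALSE, nrow_px, ncol_px)
  tri_area <- function(a, b, c) {
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  }
  qa <- tri_area(quad[1, ], quad[2, ], quad[3, ]) +
    tri_area(quad[1, ], quad[3, ], quad[4, ])
  for (r in seq_len(nrow_px)) {
    for (c in seq_len(ncol_px)) {
      pa <- sum(sapply(1:4, function(i) {
        j <- i %% 4 + 1
        tri_area(quad[i, ], quad[j, ], c(c, r))
      }))
      if (abs(pa - qa) < 1e-9 * max(1, qa)) mask[r, c] <- TRUE
    }
  }
  mask
}

# piecewise-constant gaze with raised-cosine saccades, for detector tests
make_saccade_signal <- function(fix_pos, fix_dur, sacc_dur = 0.03,
                                rate = 120, noise_sd = 0) {
  dt <- 1 / rate
  t <- x <- y <- numeric(0)
  tt <- 0
  for (k in seq_along(fix_dur)) {
    ts <- seq(tt, tt + fix_dur[k] - dt / 2, by = dt)
    t <- c(t, ts)
    x <- c(x, rep(fix_pos[k, 1], length(ts)))
    y <- c(y, rep(fix_pos[k, 2], length(ts)))
    tt <- tt + fix_dur[k]
    if (k < nrow(fix_pos)) {
      ts <- seq(tt, tt + sacc_dur - dt / 2, by = dt)
      tau <- (ts - tt) / sacc_dur
      prog <- tau - sin(2 * pi * tau) / (2 * pi)
      t <- c(t, ts)
      x <- c(x, fix_pos[k, 1] + (fix_pos[k + 1, 1] - fix_pos[k, 1]) * prog)
      y <- c(y, fix_pos[k, 2] + (fix_pos[k + 1, 2] - fix_pos[k, 2]) * prog)
      tt <- tt + sacc_dur
    }
  }
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  rec <- gaze_recording(t, x, y, world = "VR", nominal_rate = rate)
  # true saccade onset times (start of each transition)
  attr(rec, "true_onsets") <-
    cumsum(fix_dur) + (seq_along(fix_dur) - 1) * sacc_dur
  rec
}
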