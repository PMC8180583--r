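#' Paired t-test on per-subject values
#'
#' Two-sided paired t-test (wraps [stats::t.test()]); degrees of freedom
#' `n - 1`.
#'
#' @param a,b numeric vectors of equal length, paired by subject.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero-variance differences; t undefined")
    return(list(t = NaN, df = length(d) - 1L, p = NaN, mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

# orthonormal polynomial-style contrasts for a k-level factor
.orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))  # orthonormalize columns
}

# Mauchly's sphericity test and Greenhouse-Geisser epsilon for the
# covariance of subject-level orthonormal contrast scores Z (n x p)
.sphericity <- function(Z) {
  n <- nrow(Z)
  p <- ncol(Z)
  S <- stats::cov(Z)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- sum(lam)^2 / (p * sum(lam^2))
  if (p < 2) {
    return(list(mauchly_W = NA_real_, mauchly_p = NA_real_, epsilon = 1))
  }
  if (any(lam <= 0) || n - 1 <= p) {
    return(list(mauchly_W = NA_real_, mauchly_p = NA_real_, epsilon = eps))
  }
  W <- prod(lam) / (sum(lam) / p)^p
  df <- p * (p + 1) / 2 - 1
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
  chi2 <- -(n - 1) * d * log(W)
  list(mauchly_W = W,
       mauchly_p = stats::pchisq(chi2, df, lower.tail = FALSE),
       epsilon = eps)
}

#' Two-by-three repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA for the world (2 levels) by sector
#' (3 levels) design: each effect is tested against its own
#' subject-by-effect interaction error term. Mauchly's sphericity test and
#' the Greenhouse-Geisser epsilon are computed per effect from the
#' covariance of the effect's orthonormal contrast scores; a 2-level effect
#' is spherical by construction (epsilon exactly 1, no test). The reported
#' p-value uses Greenhouse-Geisser-scaled degrees of freedom when Mauchly's
#' test is significant at `alpha_sphericity`, otherwise the uncorrected
#' p-value; both are always stored. Uncorrected degrees of freedom are
#' reported alongside, following the convention of reporting
#' `F(df1, df2) = ..., p = ..., eps_GG = ...`.
#'
#' @param data data.frame with columns `subject`, `world`, `sector`,
#'   `value`: one value per subject and cell, complete and balanced.
#' @param alpha_sphericity significance level of Mauchly's test that
#'   triggers the correction.
#' @return object of class `rm_anova` (data.frame, one row per effect:
#'   `world`, `sector`, `world:sector`) with columns `effect`, `F`,
#'   `df_num`, `df_den`, `p_uncorrected`, `mauchly_p`, `epsilon_gg`,
#'   `p_gg`, `gg_applied`, `p_reported`.
#' @export
rm_anova_2x3 <- function(data, alpha_sphericity = 0.05) {
  need <- c("subject", "world", "sector", "value")
  stopifnot(all(need %in% names(data)))
  worlds <- sort(unique(as.character(data$world)))
  sectors <- unique(as.character(data$sector))
  # keep the natural route order when the standard labels are used
  std <- c("corridor", "ascending", "descending")
  sectors <- if (setequal(sectors, std)) std else sort(sectors)
  subjects <- unique(as.character(data$subject))
  n <- length(subjects)
  if (n < 3) stop("need at least 3 subjects")
  if (length(worlds) != 2 || length(sectors) != 3) {
    stop("design must be 2 worlds x 3 sectors")
  }
  # cell array y[subject, world, sector]
  y <- array(NA_real_, c(n, 2, 3))
  for (r in seq_len(nrow(data))) {
    i <- match(as.character(data$subject[r]), subjects)
    w <- match(as.character(data$world[r]), worlds)
    s <- match(as.character(data$sector[r]), sectors)
    y[i, w, s] <- data$value[r]
  }
  if (any(is.na(y))) {
    bad <- which(is.na(y), arr.ind = TRUE)[1, ]
    stop("missing cell: subject ", subjects[bad[1]], ", world ",
         worlds[bad[2]], ", sector ", sectors[bad[3]])
  }
  g <- mean(y)
  m_i <- apply(y, 1, mean)
  m_w <- apply(y, 2, mean)
  m_s <- apply(y, 3, mean)
  m_iw <- apply(y, c(1, 2), mean)
  m_is <- apply(y, c(1, 3), mean)
  m_ws <- apply(y, c(2, 3), mean)
  ss_world <- 3 * n * sum((m_w - g)^2)
  ss_sector <- 2 * n * sum((m_s - g)^2)
  ss_ws <- n * sum((m_ws - outer(m_w, rep(1, 3)) -
                      outer(rep(1, 2), m_s) + g)^2)
  ss_subj <- 6 * sum((m_i - g)^2)
  ss_iw <- 3 * sum((m_iw - outer(m_i, rep(1, 2)) -
                      outer(rep(1, n), m_w) + g)^2)
  ss_is <- 2 * sum((m_is - outer(m_i, rep(1, 3)) -
                      outer(rep(1, n), m_s) + g)^2)
  ss_total <- sum((y - g)^2)
  ss_iws <- ss_total - ss_world - ss_sector - ss_ws - ss_subj - ss_iw - ss_is
  eff <- data.frame(
    effect = c("world", "sector", "world:sector"),
    ss = c(ss_world, ss_sector, ss_ws),
    df_num = c(1L, 2L, 2L),
    ss_err = c(ss_iw, ss_is, ss_iws),
    df_den = c(n - 1L, 2L * (n - 1L), 2L * (n - 1L))
  )
  eff$F <- (eff$ss / eff$df_num) / (eff$ss_err / eff$df_den)
  eff$p_uncorrected <- stats::pf(eff$F, eff$df_num, eff$df_den,
                                 lower.tail = FALSE)
  # sphericity per effect from subject-level contrast scores
  Cs <- .orth_contrasts(3)
  Z_sector <- m_is %*% Cs
  d_ws <- y[, 1, ] - y[, 2, ]  # world difference per subject x sector
  Z_inter <- d_ws %*% Cs
  sp <- list(list(mauchly_W = NA_real_, mauchly_p = NA_real_, epsilon = 1),
             .sphericity(Z_sector),
             .sphericity(Z_inter))
  eff$mauchly_p <- vapply(sp, `[[`, 0, "mauchly_p")
  eff$epsilon_gg <- vapply(sp, `[[`, 0, "epsilon")
  eff$p_gg <- stats::pf(eff$F, eff$df_num * eff$epsilon_gg,
                        eff$df_den * eff$epsilon_gg, lower.tail = FALSE)
  eff$gg_applied <- !is.na(eff$mauchly_p) & eff$mauchly_p < alpha_sphericity
  eff$p_reported <- ifelse(eff$gg_applied, eff$p_gg, eff$p_uncorrected)
  out <- eff[, c("effect", "F", "df_num", "df_den", "p_uncorrected",
                 "mauchly_p", "epsilon_gg", "p_gg", "gg_applied",
                 "p_reported")]
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' One-way repeated-measures ANOVA over sectors
#'
#' Within-subject one-factor ANOVA (3 sector levels), used for measures
#' available in one world only (head orientation). Same sphericity handling
#' as [rm_anova_2x3()].
#'
#' @param data data.frame with columns `subject`, `sector`, `value`,
#'   complete and balanced.
#' @param alpha_sphericity Mauchly significance level triggering the
#'   Greenhouse-Geisser correction.
#' @return an `rm_anova` data.frame with a single `sector` effect row.
#' @export
rm_anova_sector <- function(data, alpha_sphericity = 0.05) {
  need <- c("subject", "sector", "value")
  stopifnot(all(need %in% names(data)))
  std <- c("corridor", "ascending", "descending")
  sectors <- unique(as.character(data$sector))
  sectors <- if (setequal(sectors, std)) std else sort(sectors)
  subjects <- unique(as.character(data$subject))
  n <- length(subjects)
  k <- length(sectors)
  if (n < 3) stop("need at least 3 subjects")
  y <- matrix(NA_real_, n, k)
  for (r in seq_len(nrow(data))) {
    y[match(as.character(data$subject[r]), subjects),
      match(as.character(data$sector[r]), sectors)] <- data$value[r]
  }
  if (any(is.na(y))) stop("incomplete subject x sector table")
  g <- mean(y)
  m_i <- rowMeans(y)
  m_s <- colMeans(y)
  ss_sector <- n * sum((m_s - g)^2)
  ss_err <- sum((y - outer(m_i, rep(1, k)) - outer(rep(1, n), m_s) + g)^2)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  F <- (ss_sector / df1) / (ss_err / df2)
  sp <- .sphericity(y %*% .orth_contrasts(k))
  p_unc <- stats::pf(F, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(F, df1 * sp$epsilon, df2 * sp$epsilon, lower.tail = FALSE)
  gg <- !is.na(sp$mauchly_p) && sp$mauchly_p < alpha_sphericity
  out <- data.frame(effect = "sector", F = F, df_num = df1, df_den = df2,
                    p_uncorrected = p_unc, mauchly_p = sp$mauchly_p,
                    epsilon_gg = sp$epsilon, p_gg = p_gg, gg_applied = gg,
                    p_reported = if (gg) p_gg else p_unc)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Format ANOVA results in reporting style
#'
#' One line per effect: `F(df1, df2) = ..., p = ...`, with the
#' Greenhouse-Geisser epsilon appended when the correction was applied
#' (epsilon of 1 for 2-level effects is suppressed).
#'
#' @param x an `rm_anova` result.
#' @param metric optional metric name prefix.
#' @return character vector of formatted lines.
#' @export
format_anova_lines <- function(x, metric = NULL) {
  stopifnot(inherits(x, "rm_anova"))
  fmt_p <- function(p) {
    ifelse(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
  }
  lines <- sprintf("%s: F(%d,%d) = %.2f, %s%s",
                   x$effect, x$df_num, x$df_den, x$F, fmt_p(x$p_reported),
                   ifelse(x$gg_applied,
                          sprintf(", eps_GG = %.2f", x$epsilon_gg), ""))
  if (!is.null(metric)) lines <- paste0(metric, " | ", lines)
  lines
}
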