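.pool_segments <- function(segs) {
  do.call(rbind, lapply(segs, function(s) s$samples))
}

#' Per-sector descriptive metrics for one recording
#'
#' Runs the descriptive stage on one recording: validity marking, exclusion
#' flags, sector slicing, and per sector the robust positional summary,
#' T-shape ratio, cardinal/oblique direction ratio, median gaze speed, and
#' saccade rate. Position statistics pool samples across same-label
#' segments; sequential statistics (velocities, direction bins, saccade
#' detection) are computed within segments and then combined, so segment
#' boundaries and blinks never contribute spurious movements.
#'
#' @param rec a `gaze_recording`.
#' @param map a [sector_map()].
#' @param sacc a [saccade_params()] (lambda may be tuned per recording).
#' @return list with `metrics` (tidy data.frame: participant, world, sector,
#'   metric, value), `events` (saccade table with sector), `valid_frac`.
#' @export
analyze_recording <- function(rec, map, sacc = saccade_params()) {
  rec <- mark_invalid_samples(rec)
  rec <- apply_exclusion_windows(rec, map)
  rows <- list()
  events <- list()
  add <- function(sector, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = rec$participant_id, world = rec$world, sector = sector,
      metric = metric, value = value)
  }
  for (label in c("corridor", "ascending", "descending")) {
    segs <- slice_by_sector(rec, map, label)
    if (!length(segs)) next
    pooled <- .pool_segments(segs)
    sm <- summarize_gaze(pooled, tracking_range = rec$tracking_range)
    add(label, "median_x", sm$median_x)
    add(label, "median_y", sm$median_y)
    add(label, "iqr_x", sm$iqr_x)
    add(label, "iqr_y", sm$iqr_y)
    add(label, "tshape", tshape_ratio(pooled))
    # direction histogram: accumulate per-segment counts, then normalize
    counts <- rep(0, 8)
    speeds <- numeric(0)
    n_ev <- 0L
    dur <- 0
    for (sg in segs) {
      dh <- direction_histogram(sg)
      counts <- counts + dh$mass * dh$n_moves
      speeds <- c(speeds, sample_velocities(sg)$speed)
      ev <- detect_saccades(sg, sacc)
      if (nrow(ev)) {
        ev$sector <- label
        ev$participant <- rec$participant_id
        ev$world <- rec$world
        events[[length(events) + 1L]] <- as.data.frame(ev)
      }
      n_ev <- n_ev + nrow(ev)
      dur <- dur + valid_duration(sg)
    }
    h <- structure(list(mass = counts / sum(counts), centers = .dir_centers,
                        n_moves = sum(counts)),
                   class = "direction_histogram")
    add(label, "cardinal_oblique", cardinal_oblique_ratio(h))
    add(label, "velocity_median", stats::median(speeds))
    add(label, "saccade_rate", n_ev / dur)
  }
  list(metrics = do.call(rbind, rows),
       events = if (length(events)) do.call(rbind, events) else NULL,
       valid_frac = mean(rec$samples$valid[!rec$samples$excluded]))
}

.metric_anovas <- function(metrics) {
  fams <- c("median_x", "median_y", "iqr_x", "iqr_y", "tshape",
            "cardinal_oblique", "velocity_median", "saccade_rate")
  out <- list()
  for (m in intersect(fams, unique(metrics$metric))) {
    d <- metrics[metrics$metric == m, ]
    d <- data.frame(subject = d$participant, world = d$world,
                    sector = d$sector, value = d$value)
    a <- tryCatch(rm_anova_2x3(d), error = function(e) NULL)
    if (!is.null(a)) {
      a$metric <- m
      out[[m]] <- a
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Run the demonstration pipeline on a synthetic cohort
#'
#' Simulates a within-subject cohort walking the study route in both worlds
#' and runs the full analysis: validity marking, sector slicing, descriptive
#' metrics per cell, saccade detection, drift estimation from the
#' end-of-session validation grids, AOI dwell over corridors (with VR
#' frames harmonized to the real-world tracking range), eye-in-world
#' referencing over the designated corridor, head-orientation statistics
#' (VR), and the within-subject inference tables. Deterministic given
#' `seed`.
#'
#' @param seed integer master seed for cohort generation and AOI/horizon
#'   simulation.
#' @param n participants.
#' @param out_dir optional output directory; when given, all tables, the
#'   report and a run manifest are written there.
#' @param scale duration scale of the route plan (1 = full study-length
#'   sessions).
#' @param params generator parameters (default [study_gen_params()]).
#' @param sacc a [saccade_params()].
#' @param horizon_corridor corridor `sector_index` used for eye-in-world
#'   referencing (the study corridor with a visible far horizon).
#' @return bundle list: `metrics`, `events`, `anovas`, `head`,
#'   `head_anovas`, `session_stats` (valid fraction, drift, dwell,
#'   eye-in-world per participant x world), `ttests`, `report`, `truth`.
#' @export
run_demo <- function(seed = 1, n = 8, out_dir = NULL, scale = 1,
                     params = study_gen_params(), sacc = saccade_params(),
                     horizon_corridor = 5) {
  cohort <- simulate_cohort(n = n, params = params, seed = seed,
                            scale = scale)
  set.seed(seed + 1000003L)
  metrics <- list()
  events <- list()
  sess_rows <- list()
  head_rows <- list()
  truth <- list()
  for (pid in names(cohort)) {
    for (w in c("VR", "RW")) {
      ss <- cohort[[pid]][[w]]
      an <- analyze_recording(ss$rec, ss$plan, sacc)
      metrics[[paste(pid, w)]] <- an$metrics
      if (!is.null(an$events)) events[[paste(pid, w)]] <- an$events
      dr <- estimate_drift(ss$validation)
      # AOI dwell over pooled corridor segments (VR harmonized to RW range)
      aoi <- simulate_aoi_track(ss)
      rec2 <- apply_exclusion_windows(mark_invalid_samples(ss$rec), ss$plan)
      corr <- .pool_segments(slice_by_sector(rec2, ss$plan, "corridor"))
      dw <- dwell_time(corr, aoi$track,
                       range = if (w == "VR") c(60, 46) else NULL)
      # eye-in-world over the designated corridor
      trace <- simulate_horizon_trace(ss)
      ci <- ss$plan$label == "corridor" &
        ss$plan$sector_index == horizon_corridor
      eiw_mean <- NA_real_
      if (any(ci)) {
        t0 <- ss$plan$t_start[ci][1]; t1 <- ss$plan$t_end[ci][1]
        sub <- rec2$samples[rec2$samples$t >= t0 & rec2$samples$t < t1, ]
        tr <- trace[trace$frame_t >= t0 & trace$frame_t < t1, ]
        eiw <- eye_in_world_vertical(sub, tr)
        eiw_mean <- mean(eiw$eye_in_world_y)
      }
      sess_rows[[paste(pid, w)]] <- data.frame(
        participant = pid, world = w,
        valid_frac = an$valid_frac,
        drift_magnitude = dr$mean_magnitude,
        drift_dx = dr$mean_offset[1], drift_dy = dr$mean_offset[2],
        dwell_frac = dw$dwell_frac, aoi_mean_distance = dw$mean_distance,
        eye_in_world_y = eiw_mean)
      truth[[paste(pid, w)]] <- list(participant = pid, world = w,
                                     session = ss$truth,
                                     aoi = aoi$truth,
                                     drift_drawn = ss$drift_drawn)
      if (w == "VR") {
        hs <- head_stats(ss$head, ss$plan)
        hs$participant <- pid
        head_rows[[pid]] <- hs
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  events <- if (length(events)) do.call(rbind, events) else NULL
  session_stats <- do.call(rbind, sess_rows)
  rownames(session_stats) <- NULL
  head_tab <- do.call(rbind, head_rows)
  rownames(head_tab) <- NULL
  anovas <- .metric_anovas(metrics)
  head_anovas <- do.call(rbind, lapply(
    c("mean_pitch", "iqr_pitch", "mean_roll", "iqr_roll"),
    function(m) {
      a <- rm_anova_sector(data.frame(subject = head_tab$participant,
                                      sector = head_tab$label,
                                      value = head_tab[[m]]))
      a$metric <- m
      a
    }))
  pick <- function(col, w) {
    v <- session_stats[session_stats$world == w, ]
    v[order(v$participant), col]
  }
  ttests <- list(
    dwell_frac = paired_ttest(pick("dwell_frac", "VR"),
                              pick("dwell_frac", "RW")),
    aoi_mean_distance = paired_ttest(pick("aoi_mean_distance", "VR"),
                                     pick("aoi_mean_distance", "RW")),
    eye_in_world_y = paired_ttest(pick("eye_in_world_y", "VR"),
                                  pick("eye_in_world_y", "RW")))
  bundle <- list(metrics = metrics, events = events, anovas = anovas,
                 head = head_tab, head_anovas = head_anovas,
                 session_stats = session_stats, ttests = ttests,
                 truth = truth, seed = seed, n = n, scale = scale)
  bundle$report <- write_report(bundle)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

#' Format the result bundle as a human-readable report
#'
#' One line per metric and effect in the standard reporting style
#' (`F(df1,df2) = ..., p = ...`, epsilon appended only where the
#' Greenhouse-Geisser correction was applied), followed by paired-test and
#' session-level summaries.
#'
#' @param bundle a result bundle from [run_demo()] or [run_pipeline()].
#' @return character vector of report lines.
#' @export
write_report <- function(bundle) {
  lines <- c("== Within-subject ANOVAs (world x sector) ==")
  if (!is.null(bundle$anovas)) {
    for (m in unique(bundle$anovas$metric)) {
      a <- bundle$anovas[bundle$anovas$metric == m, ]
      class(a) <- c("rm_anova", "data.frame")
      lines <- c(lines, format_anova_lines(a, metric = m))
    }
  }
  if (!is.null(bundle$head_anovas)) {
    lines <- c(lines, "== Head orientation (VR, sector only) ==")
    for (m in unique(bundle$head_anovas$metric)) {
      a <- bundle$head_anovas[bundle$head_anovas$metric == m, ]
      class(a) <- c("rm_anova", "data.frame")
      lines <- c(lines, format_anova_lines(a, metric = m))
    }
  }
  if (!is.null(bundle$ttests)) {
    lines <- c(lines, "== Paired t-tests (VR vs RW) ==")
    for (m in names(bundle$ttests)) {
      tt <- bundle$ttests[[m]]
      lines <- c(lines, sprintf("%s: t(%d) = %.2f, p = %.3f", m, tt$df,
                                tt$t, tt$p))
    }
  }
  if (!is.null(bundle$session_stats)) {
    ss <- bundle$session_stats
    lines <- c(lines, "== Session summaries (mean across participants) ==")
    num <- function(v) {
      if (is.null(v) || !any(is.finite(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    for (w in unique(ss$world)) {
      sw <- ss[ss$world == w, ]
      lines <- c(lines, sprintf(
        "%s: valid %.1f%%, drift %.1f deg, dwell %.1f%%, eye-in-world %+.1f deg",
        w, 100 * num(sw$valid_frac), num(sw$drift_magnitude),
        100 * num(sw$dwell_frac), num(sw$eye_in_world_y)))
    }
  }
  lines
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) {
    if (is.null(obj)) return(NULL)
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  files <- c(
    w(bundle$metrics, "metrics.tsv"),
    w(bundle$events, "saccade_events.tsv"),
    w(bundle$anovas, "anova_results.tsv"),
    w(bundle$head, "head_stats.tsv"),
    w(bundle$head_anovas, "head_anova_results.tsv"),
    w(bundle$session_stats, "session_stats.tsv"))
  rp <- file.path(out_dir, "report.txt")
  writeLines(bundle$report, rp)
  files <- c(files, rp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitgaze")),
    seed = bundle$seed, n = bundle$n, scale = bundle$scale,
    n_metric_rows = nrow(bundle$metrics),
    n_events = if (is.null(bundle$events)) 0L else nrow(bundle$events),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run the analysis pipeline from a configuration file
#'
#' Config-driven run over recorded data. The YAML config names, per
#' participant and world, the gaze table, sector map, and optionally a head
#' pose table, an AOI track, and an end-of-session validation grid; global
#' settings cover saccade parameters (lambda may be set per recording), the
#' AOI threshold and the output directory. Every referenced file must
#' exist; a missing file aborts the run naming it.
#'
#' @param config path to a YAML file, or an equivalent named list. Layout:
#'   \preformatted{
#'   out_dir: results
#'   lambda: 6
#'   participants:
#'     - id: S1
#'       VR: {gaze: s1_vr.tsv, sectors: s1_vr_sectors.tsv,
#'            validation: s1_vr_grid.tsv}
#'       RW: {gaze: s1_rw.tsv, sectors: s1_rw_sectors.tsv}
#'   }
#' @return result bundle as for [run_demo()] (entries for inputs not
#'   provided are omitted).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$participants))
  lambda <- if (is.null(config$lambda)) 6 else config$lambda
  metrics <- list()
  events <- list()
  sess_rows <- list()
  for (p in config$participants) {
    for (w in intersect(c("VR", "RW"), names(p))) {
      pw <- p[[w]]
      for (f in unlist(pw[c("gaze", "sectors")])) {
        if (!file.exists(f)) {
          stop("participant ", p$id, " [", w, "]: input file not found: ", f)
        }
      }
      rec <- read_gaze_table(pw$gaze, participant_id = p$id, world = w)
      map <- read_sector_map(pw$sectors)
      lam <- if (is.null(pw$lambda)) lambda else pw$lambda
      an <- analyze_recording(rec, map, saccade_params(lambda = lam))
      metrics[[paste(p$id, w)]] <- an$metrics
      if (!is.null(an$events)) events[[paste(p$id, w)]] <- an$events
      row <- data.frame(participant = p$id, world = w,
                        valid_frac = an$valid_frac,
                        drift_magnitude = NA_real_, dwell_frac = NA_real_)
      if (!is.null(pw$validation)) {
        if (!file.exists(pw$validation)) {
          stop("participant ", p$id, " [", w, "]: input file not found: ",
               pw$validation)
        }
        row$drift_magnitude <-
          estimate_drift(read_calibration_grid(pw$validation))$mean_magnitude
      }
      if (!is.null(pw$aoi)) {
        track <- read_aoi_track(pw$aoi)
        rec2 <- apply_exclusion_windows(mark_invalid_samples(rec), map)
        corr <- .pool_segments(slice_by_sector(rec2, map, "corridor"))
        thr <- if (is.null(config$aoi_threshold)) 1 else config$aoi_threshold
        row$dwell_frac <- dwell_time(
          corr, track, threshold = thr,
          range = if (w == "VR") c(60, 46) else NULL)$dwell_frac
      }
      sess_rows[[paste(p$id, w)]] <- row
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  bundle <- list(metrics = metrics,
                 events = if (length(events)) do.call(rbind, events) else NULL,
                 anovas = .metric_anovas(metrics),
                 session_stats = do.call(rbind, sess_rows))
  bundle$report <- write_report(bundle)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}
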