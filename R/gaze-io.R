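#' Construct a gaze recording
#'
#' A gaze recording holds a timestamped stream of monocular gaze samples in
#' head-centered degrees, together with device metadata. Horizontal gaze `x`
#' is positive rightward; vertical gaze `y` is positive downward (screen
#' convention of head-mounted trackers). Invalid samples (blinks, lost pupil)
#' carry `NA` gaze but are retained so that duration bookkeeping stays exact.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param x,y numeric gaze position in degrees (`NA` allowed on invalid
#'   samples).
#' @param pupil numeric pupil-size proxy, arbitrary units, `>= 0`; a value of
#'   0 marks a blink / lost pupil.
#' @param valid logical per-sample validity flag. If `NULL`, computed as
#'   `pupil > 0 & is.finite(x) & is.finite(y)`.
#' @param participant_id character scalar.
#' @param world `"VR"` or `"RW"`.
#' @param nominal_rate nominal sampling rate in Hz.
#' @param tracking_range numeric length-2, full extents (width, height) in
#'   degrees of the device tracking window, centered on (0, 0). Defaults to
#'   the device conventions: (100, 110) for VR, (60, 46) for RW.
#'
#' @return An object of class `gaze_recording`: a list with element
#'   `samples` (data.frame with columns `t`, `x`, `y`, `pupil`, `valid`,
#'   `excluded`) and metadata fields.
#' @export
gaze_recording <- function(t, x, y, pupil = NULL, valid = NULL,
                           participant_id = "P00", world = c("VR", "RW"),
                           nominal_rate = NULL, tracking_range = NULL) {
  world <- match.arg(world)
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n)
  if (is.null(pupil)) pupil <- rep(1, n)
  stopifnot(length(pupil) == n)
  if (n > 1 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop("sample times must be strictly increasing; first offending row: ",
         bad)
  }
  if (is.null(valid)) valid <- pupil > 0 & is.finite(x) & is.finite(y)
  if (is.null(nominal_rate)) nominal_rate <- if (world == "VR") 120 else 60
  if (is.null(tracking_range)) {
    tracking_range <- if (world == "VR") c(100, 110) else c(60, 46)
  }
  structure(
    list(
      samples = data.frame(t = as.numeric(t), x = as.numeric(x),
                           y = as.numeric(y), pupil = as.numeric(pupil),
                           valid = as.logical(valid),
                           excluded = rep(FALSE, n)),
      participant_id = as.character(participant_id),
      world = world,
      nominal_rate = nominal_rate,
      tracking_range = as.numeric(tracking_range)
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gaze_recording> %s [%s] %d samples, %.1f s, %.0f Hz nominal, %.1f%% valid\n",
    x$participant_id, x$world, nrow(s),
    if (nrow(s)) diff(range(s$t)) else 0, x$nominal_rate,
    if (nrow(s)) 100 * mean(s$valid) else NA_real_))
  invisible(x)
}

#' Extract the analyzable samples of a recording
#'
#' Returns the sample table of a recording (or passes a data.frame through),
#' optionally restricted to valid, non-excluded samples.
#'
#' @param rec a `gaze_recording` or a data.frame with columns `t`, `x`, `y`.
#' @param valid_only drop invalid and excluded samples.
#' @return data.frame of samples; attribute `tracking_range` is carried along
#'   when available.
#' @export
gaze_samples <- function(rec, valid_only = FALSE) {
  if (inherits(rec, "gaze_recording")) {
    s <- rec$samples
    attr(s, "tracking_range") <- rec$tracking_range
  } else if (is.data.frame(rec)) {
    s <- rec
    if (is.null(s$valid)) s$valid <- is.finite(s$x) & is.finite(s$y)
    if (is.null(s$excluded)) s$excluded <- FALSE
  } else {
    stop("expected a gaze_recording or data.frame")
  }
  if (valid_only) s <- s[s$valid & !s$excluded, , drop = FALSE]
  s
}

#' Construct a sector map
#'
#' A sector map partitions a recording into labeled time intervals:
#' `corridor`, `ascending`, `descending` route sectors, plus `excluded`
#' windows (equipment disturbances) and implicitly `unclassified` time not
#' covered by any interval. Intervals are half-open `[t_start, t_end)` so
#' that adjacent intervals partition time exactly. `excluded` windows may
#' overlap sector intervals and always win.
#'
#' @param t_start,t_end numeric vectors, interval bounds in seconds.
#' @param label character vector in
#'   `c("corridor", "ascending", "descending", "excluded", "unclassified")`.
#' @param sector_index optional integer id per interval (auto-numbered within
#'   label if missing).
#' @return data.frame of class `sector_map`.
#' @export
sector_map <- function(t_start, t_end, label, sector_index = NULL) {
  lv <- c("corridor", "ascending", "descending", "excluded", "unclassified")
  stopifnot(length(t_start) == length(t_end),
            length(label) == length(t_start))
  if (!all(label %in% lv)) {
    stop("unknown sector label(s): ",
         paste(setdiff(unique(label), lv), collapse = ", "))
  }
  if (any(t_end <= t_start)) stop("intervals must have t_end > t_start")
  m <- data.frame(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                  label = as.character(label))
  if (is.null(sector_index)) {
    sector_index <- stats::ave(seq_along(m$label), m$label, FUN = seq_along)
  }
  m$sector_index <- as.integer(sector_index)
  m <- m[order(m$t_start), , drop = FALSE]
  rownames(m) <- NULL
  # sector intervals (non-excluded) must not overlap each other
  sec <- m[m$label != "excluded", , drop = FALSE]
  if (nrow(sec) > 1 && any(sec$t_start[-1] < sec$t_end[-nrow(sec)])) {
    stop("sector intervals overlap")
  }
  class(m) <- c("sector_map", "data.frame")
  m
}

#' Label every sample of a recording by sector
#'
#' Assigns each sample the label of the half-open interval containing it;
#' samples inside any `excluded` window are labeled `excluded` regardless of
#' sector; samples covered by no interval are `unclassified`.
#'
#' @param rec a `gaze_recording` (or sample data.frame with column `t`).
#' @param map a [sector_map()].
#' @return character vector, one label per sample, plus an integer attribute
#'   `interval` giving the row of `map` (NA for unclassified).
#' @export
sample_sector_labels <- function(rec, map) {
  s <- gaze_samples(rec)
  lab <- rep("unclassified", nrow(s))
  ivl <- rep(NA_integer_, nrow(s))
  sec <- which(map$label != "excluded")
  for (i in sec) {
    in_i <- s$t >= map$t_start[i] & s$t < map$t_end[i]
    lab[in_i] <- map$label[i]
    ivl[in_i] <- i
  }
  for (i in which(map$label == "excluded")) {
    in_i <- s$t >= map$t_start[i] & s$t < map$t_end[i]
    lab[in_i] <- "excluded"
  }
  attr(lab, "interval") <- ivl
  lab
}

#' Cut a recording into per-sector segments
#'
#' Returns one `gaze_recording` segment per map interval carrying the
#' requested label, each restricted to samples with
#' `t_start <= t < t_end`. Samples falling in `excluded` windows are removed
#' from the segments; segments left empty are dropped.
#'
#' @param rec a `gaze_recording`.
#' @param map a [sector_map()].
#' @param label sector label to extract.
#' @return list of `gaze_recording` segments; each has attributes
#'   `sector_label` and `sector_index`. A label absent from the map yields an
#'   empty list.
#' @export
slice_by_sector <- function(rec, map, label) {
  stopifnot(inherits(rec, "gaze_recording"))
  lab <- sample_sector_labels(rec, map)
  ivl <- attr(lab, "interval")
  rows <- which(map$label == label)
  out <- list()
  for (i in rows) {
    keep <- which(ivl == i & lab == label)
    if (!length(keep)) next
    seg <- rec
    seg$samples <- rec$samples[keep, , drop = FALSE]
    rownames(seg$samples) <- NULL
    attr(seg, "sector_label") <- label
    attr(seg, "sector_index") <- map$sector_index[i]
    out[[length(out) + 1L]] <- seg
  }
  out
}

# ---- tabular readers / writers ----------------------------------------------

.gg_required_cols <- c("t", "x", "y", "pupil", "valid")

#' Read a gaze recording from a delimited text table
#'
#' Expects a UTF-8 delimited table with one header line and the five columns
#' `t, x, y, pupil, valid` (renameable through `schema`). Metadata written by
#' [write_gaze_table()] as `#key: value` comment lines is recovered; it can
#' also be supplied through arguments, which win over file metadata.
#'
#' @param path file path.
#' @param schema named character vector mapping required names to file column
#'   names, e.g. `c(t = "timestamp")`; unmapped names are used as-is.
#' @param sep field separator (default auto: TAB if present in header else
#'   comma).
#' @param ... metadata overrides passed to [gaze_recording()]
#'   (`participant_id`, `world`, `nominal_rate`, `tracking_range`).
#' @return a `gaze_recording`. Rows with non-finite time are dropped (count
#'   reported via a message).
#' @export
read_gaze_table <- function(path, schema = NULL, sep = NULL, ...) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no header line in ", path)
  if (is.null(sep)) sep <- if (grepl("\t", body[1])) "\t" else ","
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  cols <- stats::setNames(.gg_required_cols, .gg_required_cols)
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_cols <- cols[!cols %in% names(tab)]
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[key]] <- val
  }
  args <- list(t = tab[[cols["t"]]], x = tab[[cols["x"]]],
               y = tab[[cols["y"]]], pupil = tab[[cols["pupil"]]],
               valid = as.logical(tab[[cols["valid"]]]))
  n_bad <- sum(!is.finite(args$t))
  if (n_bad > 0) {
    message("dropping ", n_bad, " row(s) with non-finite time")
    keep <- is.finite(args$t)
    args <- lapply(args, `[`, keep)
  }
  if (!is.null(meta$participant_id)) args$participant_id <- meta$participant_id
  if (!is.null(meta$world)) args$world <- meta$world
  if (!is.null(meta$nominal_rate)) {
    args$nominal_rate <- as.numeric(meta$nominal_rate)
  }
  if (!is.null(meta$tracking_range)) {
    args$tracking_range <- as.numeric(strsplit(meta$tracking_range, "[ ,]+")[[1]])
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(gaze_recording, args)
}

#' Write a gaze recording as a delimited text table
#'
#' Writes metadata as leading `#key: value` lines, then a header and one line
#' per sample at full `%.10g` precision, so that
#' `read_gaze_table(write_gaze_table(rec))` round-trips losslessly at that
#' precision. `NA` gaze on invalid samples is preserved.
#'
#' @param rec a `gaze_recording`.
#' @param path output file path.
#' @param sep field separator (default TAB).
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "gaze_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#participant_id: ", rec$participant_id),
    paste0("#world: ", rec$world),
    paste0("#nominal_rate: ", format(rec$nominal_rate, digits = 10)),
    paste0("#tracking_range: ",
           paste(format(rec$tracking_range, digits = 10), collapse = " "))
  ), con)
  s <- rec$samples[, .gg_required_cols]
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))
  writeLines(paste(.gg_required_cols, collapse = sep), con)
  if (nrow(s)) {
    writeLines(paste(num(s$t), num(s$x), num(s$y), num(s$pupil),
                     ifelse(s$valid, "TRUE", "FALSE"), sep = sep), con)
  }
  invisible(path)
}

#' Read / write a sector map table
#'
#' Sector maps are stored as delimited tables with columns
#' `label, t_start, t_end` (and optional `sector_index`).
#'
#' @param path file path.
#' @return [read_sector_map()]: a `sector_map`; [write_sector_map()]: `path`.
#' @export
read_sector_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
                           stringsAsFactors = FALSE)
  need <- c("label", "t_start", "t_end")
  if (!all(need %in% names(tab))) {
    stop("sector map must have columns: ", paste(need, collapse = ", "))
  }
  sector_map(tab$t_start, tab$t_end, tab$label, tab$sector_index)
}

#' @param map a `sector_map`.
#' @rdname read_sector_map
#' @export
write_sector_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("label", "t_start", "t_end",
                                            "sector_index")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a head-pose track
#'
#' Orientation of the headset over time, sharing the clock of the owning
#' recording. Pitch is positive downward, roll positive for rightward tilt.
#'
#' @param t seconds; strictly increasing.
#' @param pitch,roll,yaw degrees.
#' @return data.frame of class `head_pose_track`.
#' @export
head_pose_track <- function(t, pitch, roll, yaw = rep(0, length(t))) {
  stopifnot(length(pitch) == length(t), length(roll) == length(t))
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(data.frame(t = t, pitch = pitch, roll = roll, yaw = yaw),
            class = c("head_pose_track", "data.frame"))
}

#' Read / write an AOI (area-of-interest) track
#'
#' Per-frame quadrilateral corner coordinates of a tracked navigational
#' marker, in head-centered degrees, with a detector confidence in `[0, 1]`.
#' Columns: `frame_t, x1, y1, x2, y2, x3, y3, x4, y4, confidence`.
#'
#' @param path file path.
#' @return data.frame of class `aoi_track`.
#' @export
read_aoi_track <- function(path) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
                           stringsAsFactors = FALSE)
  as_aoi_track(tab)
}

#' @param track a data.frame with AOI track columns.
#' @rdname read_aoi_track
#' @export
as_aoi_track <- function(track) {
  need <- c("frame_t", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)),
            "confidence")
  if (!all(need %in% names(track))) {
    stop("AOI track must have columns: ", paste(need, collapse = ", "))
  }
  track <- track[order(track$frame_t), need, drop = FALSE]
  rownames(track) <- NULL
  class(track) <- c("aoi_track", "data.frame")
  track
}

#' @rdname read_aoi_track
#' @export
write_aoi_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
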