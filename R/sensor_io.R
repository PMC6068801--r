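#' Read a tri-axial accelerometer stream
#'
#' Reads a CSV with header `t,x,y,z`: timestamps in seconds from recording
#' start (nominally 30 Hz) and acceleration in g per axis. Timestamps must be
#' strictly increasing; NaN/NA values are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with columns `t`, `x`, `y`, `z`.
#' @export
read_accel <- function(path) {
  df <- read_stream_csv(path, c("t", "x", "y", "z"))
  if (nrow(df)) {
    for (col in names(df)) assert_no_nan(df[[col]], sprintf("%s (%s)", col, path))
    if (any(diff(df$t) <= 0)) {
      har_stop("accelerometer timestamps must be strictly increasing",
               "weakhar_integrity_error")
    }
  }
  df
}

#' Read a step-event series
#'
#' CSV with header `t`: one row per detected step, seconds from recording
#' start, strictly increasing.
#'
#' @param path CSV file path.
#' @return numeric vector of step timestamps.
#' @export
read_steps <- function(path) {
  df <- read_stream_csv(path, "t")
  t <- df$t
  if (length(t)) {
    assert_no_nan(t, sprintf("t (%s)", path))
    if (any(diff(t) <= 0)) {
      har_stop("step timestamps must be strictly increasing", "weakhar_integrity_error")
    }
  }
  t
}

#' Read GPS fixes
#'
#' CSV with header `t,lat,lon,accuracy`. Latitude/longitude in degrees,
#' accuracy in meters (lower is better, must be > 0). Fixes are returned
#' sorted by timestamp regardless of file order.
#'
#' @param path CSV file path.
#' @return data.frame with columns `t`, `lat`, `lon`, `accuracy`, sorted by `t`.
#' @export
read_gps <- function(path) {
  df <- read_stream_csv(path, c("t", "lat", "lon", "accuracy"))
  if (nrow(df)) {
    for (col in names(df)) assert_no_nan(df[[col]], sprintf("%s (%s)", col, path))
    if (any(df$lat < -90 | df$lat > 90)) {
      har_stop("latitude out of [-90, 90]", "weakhar_integrity_error")
    }
    if (any(df$lon < -180 | df$lon > 180)) {
      har_stop("longitude out of [-180, 180]", "weakhar_integrity_error")
    }
    if (any(df$accuracy <= 0)) {
      har_stop("GPS accuracy must be > 0 m", "weakhar_integrity_error")
    }
    df <- df[order(df$t), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read a manual activity label log and derive ground-truth segments
#'
#' The log is a time-ordered event sequence `t,tag` where `tag` is an
#' activity, `ERROR`, or `STOP`. An activity stays active until the next
#' event. Semantics of the annotation app are applied:
#'
#' * the activity segment immediately preceding an `ERROR` event is dropped
#'   entirely (the annotator flagged it as wrong);
#' * at every transition between two kept, temporally adjacent activity
#'   segments, `blank_halfwidth` seconds on each side of the transition are
#'   excluded from both segments (default 2 s each side, a 4-s blanked
#'   window) to absorb reaction-time uncertainty;
#' * no blanking is applied at recording start or at `STOP`.
#'
#' @param path CSV file path with header `t,tag`.
#' @param blank_halfwidth seconds blanked on each side of a kept transition.
#' @return data.frame with columns `start`, `end`, `activity`
#'   (half-open intervals, pairwise disjoint, positive duration).
#' @export
read_label_log <- function(path, blank_halfwidth = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "tag") %in% names(df))) {
    har_stop(sprintf("label log %s must have header t,tag", path), "weakhar_format_error")
  }
  parse_label_events(df$t, df$tag, blank_halfwidth = blank_halfwidth)
}

#' @rdname read_label_log
#' @param t,tag event times (seconds) and tags, time-ordered.
#' @export
parse_label_events <- function(t, tag, blank_halfwidth = 2) {
  if (length(t) == 0) har_stop("empty label log", "weakhar_format_error")
  assert_no_nan(t, "label log timestamps")
  if (any(diff(t) < 0)) har_stop("label log not time-ordered", "weakhar_format_error")
  tag <- toupper(trimws(tag))
  assert_activity(setdiff(tag, c("ERROR", "STOP")))
  if (tag[length(tag)] != "STOP") {
    har_stop("label log must end with a STOP event", "weakhar_format_error")
  }

  starts <- numeric(0); ends <- numeric(0); acts <- character(0)
  cur_act <- NA_character_; cur_start <- NA_real_
  for (i in seq_along(t)) {
    tg <- tag[i]
    if (tg == "ERROR") {
      if (is.na(cur_act)) {
        warning("consecutive ERROR events in label log; extra ERROR ignored")
      }
      # drop the active segment (do not record it)
      cur_act <- NA_character_; cur_start <- NA_real_
      next
    }
    if (!is.na(cur_act) && t[i] > cur_start) {
      starts <- c(starts, cur_start); ends <- c(ends, t[i]); acts <- c(acts, cur_act)
    }
    if (tg == "STOP") { cur_act <- NA_character_; break }
    cur_act <- tg; cur_start <- t[i]
  }

  n <- length(starts)
  if (n > 1) {
    # blank only where kept segments are temporally adjacent
    for (i in seq_len(n - 1)) {
      if (isTRUE(all.equal(ends[i], starts[i + 1])) || ends[i] == starts[i + 1]) {
        ends[i] <- ends[i] - blank_halfwidth
        starts[i + 1] <- starts[i + 1] + blank_halfwidth
      }
    }
  }
  keep <- ends > starts
  out <- data.frame(start = starts[keep], end = ends[keep],
                    activity = acts[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read the experimental dataset
#'
#' The dataset file pairs the manual label, the weak label (with its
#' probability), and the 18 features of each 1-s window:
#' `label,weak_label,probability,window_start,f1..f18`. `MISSING` weak labels
#' carry an empty probability field. Round-trips losslessly through
#' [read_dataset()].
#'
#' @param rows data.frame of labeled rows (see [align_rows()]), or a list of
#'   such rows; all rows must share the same feature dimensionality.
#' @param path output CSV path.
#' @export
write_dataset <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) > 1) {
      har_stop("inconsistent feature dimensionality across rows", "weakhar_integrity_error")
    }
    rows <- do.call(rbind, lapply(rows, as.data.frame))
  }
  fcols <- grep("^f[0-9]+$", names(rows), value = TRUE)
  if (!length(fcols)) har_stop("no feature columns f1..fn", "weakhar_format_error")
  fmat <- as.matrix(rows[fcols])
  if (nrow(rows)) assert_no_nan(fmat, "features")
  keep <- c("label", "weak_label",
            intersect(c("probability", "window_start"), names(rows)), fcols)
  data.table::fwrite(rows[keep], path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("label", "weak_label") %in% names(df))) {
    har_stop("dataset must have label and weak_label columns", "weakhar_format_error")
  }
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (nrow(df)) assert_no_nan(as.matrix(df[fcols]), "features")
  df
}

#' Writers for the raw stream schemas
#'
#' Mirror images of [read_accel()], [read_steps()], [read_gps()] and
#' [read_label_log()]; used by the simulator and the CLI.
#'
#' @param accel,steps,gps,schedule objects in the package's standard
#'   representations.
#' @param path output CSV path.
#' @export
write_accel <- function(accel, path) {
  data.table::fwrite(accel[c("t", "x", "y", "z")], path)
  invisible(path)
}

#' @rdname write_accel
#' @export
write_steps <- function(steps, path) {
  data.table::fwrite(data.frame(t = as.numeric(steps)), path)
  invisible(path)
}

#' @rdname write_accel
#' @export
write_gps <- function(gps, path) {
  data.table::fwrite(gps[c("t", "lat", "lon", "accuracy")], path)
  invisible(path)
}

#' @rdname write_accel
#' @export
write_label_log <- function(schedule, path) {
  # one event per segment start; explicit STOP at the end of the recording
  ev <- data.frame(t = c(schedule$start, max(schedule$end)),
                   tag = c(schedule$activity, "STOP"))
  data.table::fwrite(ev, path)
  invisible(path)
}

read_stream_csv <- function(path, required) {
  if (!file.exists(path)) har_stop(sprintf("file not found: %s", path), "weakhar_format_error")
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    har_stop(sprintf("%s: missing column(s) %s", path, paste(missing_cols, collapse = ", ")),
             "weakhar_format_error")
  }
  df[required]
}
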