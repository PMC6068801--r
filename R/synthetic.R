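#' Simulation configuration for synthetic free-living traces
#'
#' The generator's stated world: a single subject carrying a phone through
#' unscripted daily life. Defaults follow the field's standard figures —
#' walking cadence N(100, 5) spm and running N(170, 5) spm; ground speeds
#' N(1.4, 0.2) walking, N(3.5, 0.4) running, N(6, 1) cycling, N(25, 5) m/s
#' motorized transportation; GPS polled at uniform 60--180 s intervals with
#' accuracy N(8, 3) m outdoors and N(35, 10) m indoors (sitting), truncated
#' positive. Mixture weights and per-activity bout-duration bounds emulate a
#' sedentary-dominated free-living day. Transportation emits sparse spurious
#' step events (vehicle vibration false positives) at `spurious_spm`.
#'
#' @param mixture named time-share weights over the five activities (sum 1).
#' @param duration_bounds named list of `c(min, max)` bout durations (s).
#' @param cadence named list of `c(mean, sd)` steps/min for step-producing
#'   activities.
#' @param speed named list of `c(mean, sd)` m/s per activity.
#' @param gps_poll `c(min, max)` seconds between GPS fixes, within
#'   `[60, 180]`.
#' @param gps_accuracy list with `indoor` and `outdoor` `c(mean, sd)` meters.
#' @param accel named list per activity: `amp` (oscillation amplitude, g),
#'   `freq` (`NA` = use the bout cadence / 60), `noise` (white-noise sd, g).
#' @param spurious_spm spurious step rate during transportation (steps/min).
#' @param fs accelerometer sampling rate, Hz.
#' @param origin `c(lat, lon)` of the simulated area, degrees.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    mixture = c(SITTING = 0.55, WALKING = 0.20, RUNNING = 0.05,
                CYCLING = 0.08, TRANSPORTATION = 0.12),
    duration_bounds = list(SITTING = c(600, 3600), WALKING = c(300, 1800),
                           RUNNING = c(300, 1200), CYCLING = c(600, 1800),
                           TRANSPORTATION = c(300, 1800)),
    cadence = list(WALKING = c(mean = 100, sd = 5), RUNNING = c(mean = 170, sd = 5)),
    speed = list(SITTING = c(mean = 0, sd = 0), WALKING = c(mean = 1.4, sd = 0.2),
                 RUNNING = c(mean = 3.5, sd = 0.4), CYCLING = c(mean = 6, sd = 1),
                 TRANSPORTATION = c(mean = 25, sd = 5)),
    gps_poll = c(60, 180),
    gps_accuracy = list(indoor = c(mean = 35, sd = 10), outdoor = c(mean = 8, sd = 3)),
    accel = list(SITTING = list(amp = 0, freq = NA, noise = 0.01),
                 WALKING = list(amp = 0.4, freq = NA, noise = 0.05),
                 RUNNING = list(amp = 0.8, freq = NA, noise = 0.08),
                 CYCLING = list(amp = 0.15, freq = 1.5, noise = 0.05),
                 TRANSPORTATION = list(amp = 0, freq = NA, noise = 0.03)),
    spurious_spm = 2, fs = 30, origin = c(lat = 50, lon = 6)) {
  stopifnot(abs(sum(mixture) - 1) < 1e-9,
            all(gps_poll >= 60), all(gps_poll <= 180), gps_poll[1] <= gps_poll[2],
            all(vapply(speed, function(s) s[["sd"]] >= 0, logical(1))))
  assert_activity(names(mixture))
  structure(list(mixture = mixture, duration_bounds = duration_bounds,
                 cadence = cadence, speed = speed, gps_poll = gps_poll,
                 gps_accuracy = gps_accuracy, accel = accel,
                 spurious_spm = spurious_spm, fs = fs, origin = origin),
            class = "sim_config")
}

#' Draw a free-living activity schedule
#'
#' Samples bouts until `duration` is covered; the last bout is truncated.
#' Bout activities are drawn with probability proportional to
#' `mixture / mean(duration_bounds)` so that expected *time* shares match the
#' mixture weights. With `ensure_all = TRUE` the first five bouts are a
#' random permutation of the five classes, guaranteeing full class coverage
#' in short simulations.
#'
#' @param config a [sim_config()].
#' @param duration simulated seconds (>= 0).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param ensure_all guarantee every class appears at least once.
#' @return data.frame with columns `start`, `end`, `activity`, tiling
#'   `[0, duration)`.
#' @export
generate_schedule <- function(config, duration, seed = 1, ensure_all = FALSE) {
  if (duration < 0) har_stop("duration must be >= 0", "weakhar_value_error")
  acts <- names(config$mixture)
  if (duration == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      activity = character(0), stringsAsFactors = FALSE))
  }
  mean_dur <- vapply(acts, function(a) mean(config$duration_bounds[[a]]), numeric(1))
  p <- config$mixture / mean_dur
  p <- p / sum(p)
  withr::with_seed(seed, {
    sched_act <- character(0); sched_dur <- numeric(0)
    forced <- if (ensure_all) sample(acts) else character(0)
    total <- 0; i <- 0
    while (total < duration) {
      i <- i + 1
      a <- if (i <= length(forced)) forced[i] else sample(acts, 1, prob = p)
      b <- config$duration_bounds[[a]]
      d <- stats::runif(1, b[1], b[2])
      sched_act <- c(sched_act, a); sched_dur <- c(sched_dur, d)
      total <- total + d
    }
  })
  ends <- pmin(cumsum(sched_dur), duration)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep], activity = sched_act[keep],
             stringsAsFactors = FALSE)
}

#' Synthesize sensor streams for a schedule
#'
#' Per bout the generator draws a cadence (walking/running), a ground speed
#' and a straight-line heading, then emits:
#' * **steps** — near-periodic events at the bout cadence with small timing
#'   jitter; none while sitting or cycling; sparse spurious events at
#'   `spurious_spm` during transportation;
#' * **GPS** — fixes at uniform `gps_poll` intervals, positions integrated
#'   along the per-bout path, accuracy from the indoor distribution while
#'   sitting and the outdoor one otherwise (truncated > 0.5 m);
#' * **accelerometer** (optional, it dominates runtime) — per-axis white
#'   noise around a 1-g gravity baseline on z, plus a sinusoid at the step
#'   (or pedaling) frequency, so magnitude oscillates around 1 g and the PSD
#'   peaks at the cadence frequency.
#'
#' Channel streams are generated from seeds derived from `seed`, so e.g.
#' step events are identical whether or not the accelerometer is requested.
#'
#' @param schedule data.frame from [generate_schedule()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param channels subset of `c("accel", "steps", "gps")`.
#' @return list with `accel` (data.frame or NULL), `steps` (numeric vector),
#'   `gps` (data.frame), `bouts` (per-bout drawn parameters).
#' @export
synth_trace <- function(schedule, config, seed = 1,
                        channels = c("accel", "steps", "gps")) {
  nseg <- nrow(schedule)
  if (!nseg) {
    return(list(accel = NULL, steps = numeric(0),
                gps = data.frame(t = numeric(0), lat = numeric(0),
                                 lon = numeric(0), accuracy = numeric(0)),
                bouts = schedule))
  }
  bouts <- withr::with_seed(seed, draw_bout_params(schedule, config))
  steps <- if ("steps" %in% channels) {
    withr::with_seed(seed + 1L, synth_steps(bouts, config))
  } else numeric(0)
  gps <- if ("gps" %in% channels) {
    withr::with_seed(seed + 2L, synth_gps(bouts, config))
  } else data.frame(t = numeric(0), lat = numeric(0), lon = numeric(0),
                    accuracy = numeric(0))
  accel <- if ("accel" %in% channels) {
    withr::with_seed(seed + 3L, synth_accel(bouts, config))
  } else NULL
  list(accel = accel, steps = steps, gps = gps, bouts = bouts)
}

draw_bout_params <- function(schedule, config) {
  n <- nrow(schedule)
  cad <- numeric(n); spd <- numeric(n); heading <- stats::runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    a <- schedule$activity[i]
    cad[i] <- if (!is.null(config$cadence[[a]])) {
      max(1, stats::rnorm(1, config$cadence[[a]][["mean"]], config$cadence[[a]][["sd"]]))
    } else 0
    s <- config$speed[[a]]
    spd[i] <- max(0, stats::rnorm(1, s[["mean"]], s[["sd"]]))
  }
  cbind(schedule, data.frame(cadence = cad, speed = spd, heading = heading))
}

synth_steps <- function(bouts, config) {
  out <- list()
  for (i in seq_len(nrow(bouts))) {
    a <- bouts$activity[i]
    s <- bouts$start[i]; e <- bouts$end[i]
    if (bouts$cadence[i] > 0) {
      period <- 60 / bouts$cadence[i]
      tt <- seq(s + period / 2, e, by = period)
      tt <- tt + stats::rnorm(length(tt), 0, 0.05 * period)
    } else if (a == "TRANSPORTATION" && config$spurious_spm > 0) {
      k <- stats::rpois(1, config$spurious_spm / 60 * (e - s))
      tt <- sort(stats::runif(k, s, e))
    } else next
    out[[length(out) + 1]] <- tt[tt >= s & tt < e]
  }
  st <- sort(unlist(out))
  st[c(TRUE, diff(st) > 1e-6)]  # enforce strictly increasing
}

synth_gps <- function(bouts, config) {
  t0 <- bouts$start[1]; tend <- max(bouts$end)
  times <- t0
  repeat {
    nxt <- times[length(times)] + stats::runif(1, config$gps_poll[1], config$gps_poll[2])
    if (nxt >= tend) break
    times <- c(times, nxt)
  }
  # integrate the piecewise-linear path at fix times
  x <- numeric(length(times)); y <- numeric(length(times))
  px <- 0; py <- 0
  j <- 1
  seg_of <- findInterval(times, bouts$start)
  # cumulative position at bout starts
  bx <- numeric(nrow(bouts)); by <- numeric(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    bx[i] <- px; by[i] <- py
    d <- (bouts$end[i] - bouts$start[i]) * bouts$speed[i]
    px <- px + d * cos(bouts$heading[i]); py <- py + d * sin(bouts$heading[i])
  }
  for (k in seq_along(times)) {
    i <- max(1, seg_of[k])
    dt <- times[k] - bouts$start[i]
    x[k] <- bx[i] + dt * bouts$speed[i] * cos(bouts$heading[i])
    y[k] <- by[i] + dt * bouts$speed[i] * sin(bouts$heading[i])
  }
  indoor <- bouts$activity[pmax(1, seg_of)] == "SITTING"
  acc_par <- ifelse(indoor, "indoor", "outdoor")
  acc <- vapply(acc_par, function(p) {
    stats::rnorm(1, config$gps_accuracy[[p]][["mean"]], config$gps_accuracy[[p]][["sd"]])
  }, numeric(1))
  acc <- pmax(0.5, acc)
  m_per_deg <- 6371000 * pi / 180
  lat <- config$origin[["lat"]] + y / m_per_deg
  lon <- config$origin[["lon"]] + x / (m_per_deg * cos(config$origin[["lat"]] * pi / 180))
  data.frame(t = times, lat = lat, lon = lon, accuracy = unname(acc))
}

synth_accel <- function(bouts, config) {
  fs <- config$fs
  t <- seq(bouts$start[1], max(bouts$end) - 1 / fs, by = 1 / fs)
  n <- length(t)
  seg_of <- pmax(1, findInterval(t, bouts$start))
  amp <- vapply(bouts$activity, function(a) config$accel[[a]]$amp, numeric(1))[seg_of]
  noise_sd <- vapply(bouts$activity, function(a) config$accel[[a]]$noise, numeric(1))[seg_of]
  freq <- vapply(seq_len(nrow(bouts)), function(i) {
    f <- config$accel[[bouts$activity[i]]]$freq
    if (is.na(f)) bouts$cadence[i] / 60 else f
  }, numeric(1))[seg_of]
  osc <- amp * sin(2 * pi * freq * t)
  data.frame(
    t = t,
    x = 0.3 * osc + stats::rnorm(n, 0, noise_sd),
    y = stats::rnorm(n, 0, noise_sd),
    z = 1 + osc + stats::rnorm(n, 0, noise_sd))
}

#' Degrade a GPS stream
#'
#' Emulates urban-canyon or in-building reception: each fix is independently
#' dropped with probability `dropout_prob`, and surviving accuracy estimates
#' are multiplied by `accuracy_inflation`.
#'
#' @param gps data.frame of fixes.
#' @param dropout_prob dropout probability in `[0, 1]`.
#' @param accuracy_inflation multiplicative accuracy degradation (>= 1 makes
#'   fixes worse).
#' @param seed integer seed.
#' @return the degraded data.frame.
#' @export
degrade_gps <- function(gps, dropout_prob, accuracy_inflation = 1, seed = 1) {
  if (dropout_prob < 0 || dropout_prob > 1) {
    har_stop("dropout_prob must be in [0, 1]", "weakhar_value_error")
  }
  keep <- withr::with_seed(seed, stats::runif(nrow(gps)) >= dropout_prob)
  out <- gps[keep, , drop = FALSE]
  out$accuracy <- out$accuracy * accuracy_inflation
  rownames(out) <- NULL
  out
}

#' Simulate a recording and write all stream files
#'
#' Writes `accel.csv`, `steps.csv`, `gps.csv` and the manual label log
#' `labels.csv` (one event per bout plus a final `STOP`) in the package's
#' CSV schemas.
#'
#' @param dir output directory (created if needed).
#' @param duration simulated seconds.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param channels channels to generate; omitting `"accel"` makes long
#'   simulations much faster when only the heuristic is exercised.
#' @param ensure_all see [generate_schedule()].
#' @return invisibly, the list of written paths.
#' @export
simulate_recording <- function(dir, duration, config = sim_config(), seed = 1,
                               channels = c("accel", "steps", "gps"),
                               ensure_all = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- generate_schedule(config, duration, seed = seed, ensure_all = ensure_all)
  trace <- synth_trace(schedule, config, seed = seed, channels = channels)
  paths <- list(labels = file.path(dir, "labels.csv"),
                steps = file.path(dir, "steps.csv"),
                gps = file.path(dir, "gps.csv"))
  write_label_log(schedule, paths$labels)
  write_steps(trace$steps, paths$steps)
  write_gps(trace$gps, paths$gps)
  if (!is.null(trace$accel)) {
    paths$accel <- file.path(dir, "accel.csv")
    write_accel(trace$accel, paths$accel)
  }
  invisible(paths)
}
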