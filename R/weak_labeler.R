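#' Cadence windows: steps/min sampled on 1-minute fragments
#'
#' Tiles `[span_start, span_end)` with 1-minute windows and counts step
#' events in each; because the window is one minute, the count is the
#' steps/min rate. A trailing partial minute shorter than 30 s is discarded;
#' one of 30 s or longer is kept with its count scaled to a per-minute rate.
#'
#' @param steps numeric vector of step timestamps (seconds, increasing).
#' @param span_start,span_end recording span in seconds; duration must be
#'   at least 60 s.
#' @return data.frame with columns `start`, `end`, `spm`.
#' @export
compute_spm_windows <- function(steps, span_start, span_end) {
  dur <- span_end - span_start
  if (dur < 60) har_stop("span must be at least 60 s", "weakhar_value_error")
  n_full <- floor(dur / 60)
  starts <- span_start + 60 * (seq_len(n_full) - 1)
  ends <- starts + 60
  rem <- dur - 60 * n_full
  if (rem >= 30) {
    starts <- c(starts, span_start + 60 * n_full)
    ends <- c(ends, span_end)
  }
  counts <- vapply(seq_along(starts),
                   function(i) sum(steps >= starts[i] & steps < ends[i]),
                   numeric(1))
  data.frame(start = starts, end = ends,
             spm = counts * 60 / (ends - starts))
}

#' Merge adjacent cadence windows with similar rates
#'
#' Greedy left-to-right merge: the next window joins the running segment
#' when the two are contiguous and the absolute difference between the
#' window's rate and the segment's duration-weighted mean rate is strictly
#' below `spm_tol`. Comparing against the running mean (rather than the last
#' raw window) stabilizes long sessions such as prolonged walks.
#'
#' @param windows data.frame from [compute_spm_windows()], time-ordered.
#' @param spm_tol merge threshold in steps/min (default 10, strict `<`).
#' @return data.frame with columns `start`, `end`, `spm` (duration-weighted
#'   mean rate), segments ordered and disjoint, covering the input.
#' @export
merge_windows <- function(windows, spm_tol = 10) {
  n <- nrow(windows)
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0), spm = numeric(0)))
  out_start <- windows$start[1]; out_end <- windows$end[1]
  acc_spm <- windows$spm[1] * (out_end - out_start); acc_dur <- out_end - out_start
  res <- list()
  for (i in seq_len(n)[-1]) {
    contiguous <- isTRUE(all.equal(windows$start[i], out_end)) ||
      windows$start[i] == out_end
    seg_mean <- acc_spm / acc_dur
    if (contiguous && abs(windows$spm[i] - seg_mean) < spm_tol) {
      d <- windows$end[i] - windows$start[i]
      acc_spm <- acc_spm + windows$spm[i] * d
      acc_dur <- acc_dur + d
      out_end <- windows$end[i]
    } else {
      res[[length(res) + 1]] <- c(out_start, out_end, acc_spm / acc_dur)
      out_start <- windows$start[i]; out_end <- windows$end[i]
      d <- out_end - out_start
      acc_spm <- windows$spm[i] * d; acc_dur <- d
    }
  }
  res[[length(res) + 1]] <- c(out_start, out_end, acc_spm / acc_dur)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], spm = m[, 3])
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @param radius Earth radius in meters (default 6,371,000).
#' @return distance in meters.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2, radius = 6371000) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Speed between two consecutive GPS fixes
#'
#' Haversine distance divided by the time difference.
#'
#' @param a,b GPS fixes: lists or one-row data.frames with `t`, `lat`,
#'   `lon`; `b` must be later than `a`.
#' @return speed in m/s.
#' @export
estimate_speed <- function(a, b) {
  dt <- b$t - a$t
  if (dt <= 0) har_stop("fixes must be in increasing time order", "weakhar_value_error")
  haversine_distance(a$lat, a$lon, b$lat, b$lon) / dt
}

#' Weighted average speed and GPS weight over a segment
#'
#' Uses all consecutive fix pairs whose fixes fall inside `[start, end)`:
#' pairwise speeds are averaged with time-gap weights, and the GPS weight is
#' the mean over pairs of `min(1, a0 / max(accuracy_i, accuracy_j))`. With
#' fewer than two fixes in the segment no speed can be estimated and the
#' weight is 0.
#'
#' @param start,end segment interval in seconds.
#' @param fixes data.frame of GPS fixes sorted by `t`.
#' @param cfg a [fuzzy_config()] (for the reference accuracy `a0`).
#' @return list with `speed` (m/s, or `NA` when unavailable) and `w_gps`.
#' @export
segment_speed <- function(start, end, fixes, cfg = fuzzy_config()) {
  inside <- which(fixes$t >= start & fixes$t < end)
  if (length(inside) < 2) return(list(speed = NA_real_, w_gps = 0))
  f <- fixes[inside, , drop = FALSE]
  i <- seq_len(nrow(f) - 1)
  dt <- f$t[i + 1] - f$t[i]
  v <- haversine_distance(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1]) / dt
  w <- pmin(1, cfg$a0 / pmax(f$accuracy[i], f$accuracy[i + 1]))
  list(speed = sum(v * dt) / sum(dt), w_gps = mean(w))
}

#' Assign a weak label to one merged segment
#'
#' Computes the fused class probabilities and picks the argmax. Sitting,
#' walking and running — visible to both the step counter and the GPS — use
#' the accuracy-weighted fusion of [combine_probability()]; cycling and
#' transportation are GPS-only and use the speed membership directly, but
#' are eligible only when the segment's GPS weight reaches `cfg$w_min`.
#' Ties are broken toward the earlier class in [HAR_ACTIVITIES]. If the best
#' probability falls below `cfg$theta` the segment is `MISSING`.
#'
#' @param spm segment cadence in steps/min.
#' @param speed segment speed in m/s, or `NA` when unavailable.
#' @param w_gps GPS weight in `[0, 1]` (forced to 0 when `speed` is `NA`).
#' @param cfg a [fuzzy_config()].
#' @return list with `activity` (taxonomy value or `"MISSING"`) and
#'   `probability` (`NA` when missing).
#' @export
assign_weak_label <- function(spm, speed, w_gps, cfg = fuzzy_config()) {
  p_step <- step_membership(spm, cfg)
  if (is.na(speed)) {
    w_gps <- 0
    p_gps <- stats::setNames(numeric(5), HAR_ACTIVITIES)
  } else {
    p_gps <- speed_membership(speed, cfg)
  }
  p <- stats::setNames(numeric(5), HAR_ACTIVITIES)
  for (a in c("SITTING", "WALKING", "RUNNING")) {
    p[a] <- combine_probability(p_step[[a]], p_gps[[a]], w_gps)
  }
  if (w_gps >= cfg$w_min) {
    p["CYCLING"] <- p_gps[["CYCLING"]]
    p["TRANSPORTATION"] <- p_gps[["TRANSPORTATION"]]
  }
  best <- which.max(p)  # first max wins: fixed priority order
  if (p[best] < cfg$theta) {
    list(activity = HAR_MISSING, probability = NA_real_)
  } else {
    list(activity = HAR_ACTIVITIES[best], probability = unname(p[best]))
  }
}

# Subdivide a merged segment at GPS fix boundaries into runs of consistent
# speed class. Cadence merging fuses every near-zero-cadence activity
# (sitting, cycling, riding a vehicle) into a single block; the GPS is the
# only source that can tell those apart, so blocks are re-split wherever the
# consecutive-fix speed class changes. A pair whose speed class differs from
# both neighbors (typically a pair straddling an activity transition) forms
# its own sub-segment and usually ends up MISSING.
split_by_speed <- function(start, end, spm, fixes, cfg) {
  inside <- which(fixes$t >= start & fixes$t < end)
  if (length(inside) < 3) {
    return(data.frame(start = start, end = end, spm = spm))
  }
  f <- fixes[inside, , drop = FALSE]
  i <- seq_len(nrow(f) - 1)
  v <- haversine_distance(f$lat[i], f$lon[i], f$lat[i + 1], f$lon[i + 1]) /
    (f$t[i + 1] - f$t[i])
  mem <- speed_membership(v, cfg)
  cls <- max.col(mem, ties.method = "first")
  cls[mem[cbind(seq_along(cls), cls)] == 0] <- 0L  # no class supported
  change <- which(diff(cls) != 0)
  if (!length(change)) {
    return(data.frame(start = start, end = end, spm = spm))
  }
  bounds <- c(start, f$t[change + 1], end)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1], spm = spm)
}

#' Run the full weak-labeling heuristic over a recording
#'
#' Chains cadence windowing, merging, GPS-driven subdivision of
#' near-zero-cadence blocks, per-segment speed estimation, fuzzy label
#' assignment and the cycling/transportation smoothing pass.
#'
#' @param steps numeric vector of step timestamps (seconds).
#' @param gps data.frame of GPS fixes sorted by `t`.
#' @param span_start,span_end recording span in seconds.
#' @param cfg a [fuzzy_config()].
#' @return data.frame with columns `start`, `end`, `activity`,
#'   `probability` (NA on `MISSING` rows), `spm`, `speed`, `w_gps`.
#' @export
weak_label_trace <- function(steps, gps, span_start, span_end,
                             cfg = fuzzy_config()) {
  windows <- compute_spm_windows(steps, span_start, span_end)
  merged <- merge_windows(windows)
  pieces <- lapply(seq_len(nrow(merged)), function(i) {
    split_by_speed(merged$start[i], merged$end[i], merged$spm[i], gps, cfg)
  })
  segs <- do.call(rbind, pieces)
  out <- lapply(seq_len(nrow(segs)), function(i) {
    sp <- segment_speed(segs$start[i], segs$end[i], gps, cfg)
    lab <- assign_weak_label(segs$spm[i], sp$speed, sp$w_gps, cfg)
    data.frame(start = segs$start[i], end = segs$end[i],
               activity = lab$activity, probability = lab$probability,
               spm = segs$spm[i], speed = sp$speed, w_gps = sp$w_gps,
               stringsAsFactors = FALSE)
  })
  smooth_labels(do.call(rbind, out))
}

#' Smooth cycling/transportation alternations
#'
#' GPS speed alone cannot reliably separate cycling from motorized transport
#' in traffic, so any cycling segment strictly consecutive (in sequence
#' order; `MISSING` rows block adjacency) to a transportation segment is
#' relabeled transportation. Left-to-right passes repeat until a fixpoint.
#'
#' @param segments data.frame of weak-label segments, time-ordered.
#' @return the smoothed data.frame.
#' @export
smooth_labels <- function(segments) {
  if (!nrow(segments)) return(segments)
  act <- segments$activity
  repeat {
    cyc <- which(act == "CYCLING")
    flip <- cyc[(cyc > 1 & act[pmax(cyc - 1, 1)] == "TRANSPORTATION") |
                  (cyc < length(act) & act[pmin(cyc + 1, length(act))] == "TRANSPORTATION")]
    if (!length(flip)) break
    act[flip] <- "TRANSPORTATION"
  }
  segments$activity <- act
  rownames(segments) <- NULL
  segments
}

#' Heuristic label quality versus manual ground truth
#'
#' Scores the weak labeling against manually annotated segments, per
#' calendar day and overall:
#' * **precision** — time covered by correct non-missing weak labels divided
#'   by time covered by any non-missing weak label, both restricted to
#'   manually labeled time (undefined when no weak-labeled time exists on a
#'   day, reported `NA`);
#' * **missing rate** — manually labeled time not covered by a non-missing
#'   weak label, divided by manually labeled time.
#'
#' @param weak data.frame from [weak_label_trace()].
#' @param truth data.frame of ground-truth segments (`start`, `end`,
#'   `activity`).
#' @param day_length seconds per day used to bin the report (default 86400).
#' @return list with `per_day` (data.frame `day`, `precision`,
#'   `missing_rate`, `truth_s`, `labeled_s`), and overall `precision` and
#'   `missing_rate`.
#' @export
label_quality_report <- function(weak, truth, day_length = 86400) {
  lab <- weak[weak$activity != HAR_MISSING, , drop = FALSE]
  days <- sort(unique(floor(c(truth$start, pmax(truth$start, truth$end - 1e-9)) / day_length)))
  per_day <- lapply(days, function(d) {
    d0 <- d * day_length; d1 <- d0 + day_length
    ts <- pmax(truth$start, d0); te <- pmin(truth$end, d1)
    keep <- which(te > ts)
    truth_s <- sum(te[keep] - ts[keep])
    judged <- 0; correct <- 0
    for (k in keep) {
      ov <- interval_overlap(ts[k], te[k], lab$start, lab$end)
      judged <- judged + sum(ov)
      correct <- correct + sum(ov[lab$activity == truth$activity[k]])
    }
    data.frame(day = d,
               precision = if (judged > 0) correct / judged else NA_real_,
               missing_rate = if (truth_s > 0) (truth_s - judged) / truth_s else NA_real_,
               truth_s = truth_s, labeled_s = judged,
               correct_s = correct)
  })
  per_day <- do.call(rbind, per_day)
  tot_judged <- sum(per_day$labeled_s)
  tot_truth <- sum(per_day$truth_s)
  list(per_day = per_day[setdiff(names(per_day), "correct_s")],
       precision = if (tot_judged > 0) sum(per_day$correct_s) / tot_judged else NA_real_,
       missing_rate = if (tot_truth > 0) (tot_truth - tot_judged) / tot_truth else NA_real_)
}
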