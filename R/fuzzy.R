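#' Fuzzy membership configuration for the weak-labeling heuristic
#'
#' Bundles every tunable constant of the label-quality model:
#'
#' * **Cadence model** — walking and running memberships are Gaussians
#'   normalized to peak 1 at their means (walking 100 spm, running 170 spm;
#'   sd 12 spm for both). The sd is chosen so membership stays near 1 across
#'   the usual 90--110 / 160--180 spm bands yet falls below the decision
#'   threshold at the ambiguous cadences 50 and 130 spm. The sedentary
#'   membership is a trapezoid over cadence with plateau at 0 spm.
#' * **Speed model** — per-activity trapezoids over GPS ground speed (m/s),
#'   anchored at ~1.4 m/s walking, 3--4 m/s running, 4--8 m/s cycling and
#'   >= 20 m/s motorized transportation. The transportation trapezoid is
#'   right-open (no upper shoulder).
#' * **GPS weighting** — `a0` is the reference accuracy (m): a fix pair with
#'   accuracy no worse than `a0` gets full weight 1, worse pairs get
#'   `a0 / accuracy`. `w_min` gates the GPS-only classes (cycling,
#'   transportation): they are eligible only when the segment's GPS weight
#'   reaches `w_min`.
#' * **Decision threshold** — `theta`: a segment whose best class probability
#'   falls below `theta` is emitted as `MISSING`.
#'
#' @param walking_spm,running_spm `c(mean, sd)` in steps/min.
#' @param sedentary_spm trapezoid vertices `c(a, b, c, d)` in steps/min.
#' @param speed named list of trapezoid vertices (m/s), one per activity;
#'   vertices must be non-decreasing, `Inf` allowed for right-open shoulders.
#' @param a0 reference GPS accuracy in meters.
#' @param w_min minimum GPS weight for cycling/transportation eligibility.
#' @param theta decision threshold in (0, 1).
#' @return an object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(walking_spm = c(mean = 100, sd = 12),
                         running_spm = c(mean = 170, sd = 12),
                         sedentary_spm = c(0, 0, 15, 40),
                         speed = list(
                           SITTING        = c(0, 0, 0.2, 0.7),
                           WALKING        = c(0.6, 1.0, 1.8, 2.6),
                           RUNNING        = c(2.4, 3.0, 4.0, 5.0),
                           CYCLING        = c(3.5, 4.0, 8.0, 12.0),
                           TRANSPORTATION = c(8, 20, Inf, Inf)),
                         a0 = 10, w_min = 0.3, theta = 0.5) {
  stopifnot(walking_spm[["sd"]] > 0, running_spm[["sd"]] > 0,
            theta > 0, theta < 1, a0 > 0, w_min >= 0)
  check_trapezoid(sedentary_spm)
  if (!setequal(names(speed), HAR_ACTIVITIES)) {
    har_stop("speed trapezoids must cover exactly the five activities",
             "weakhar_value_error")
  }
  for (v in speed) check_trapezoid(v)
  structure(list(walking_spm = walking_spm, running_spm = running_spm,
                 sedentary_spm = sedentary_spm, speed = speed,
                 a0 = a0, w_min = w_min, theta = theta),
            class = "fuzzy_config")
}

check_trapezoid <- function(v) {
  if (length(v) != 4 || is.unsorted(v[is.finite(v)])) {
    har_stop("trapezoid vertices must be 4 non-decreasing values",
             "weakhar_value_error")
  }
  invisible(v)
}

#' Trapezoidal membership function
#'
#' Piecewise-linear membership with vertices `c(a, b, c, d)`: 0 below `a`,
#' rising on `[a, b]`, plateau 1 on `[b, c]`, falling on `[c, d]`, 0 above
#' `d`. Degenerate (zero-width) shoulders are sharp edges; infinite `c`/`d`
#' give a right-open plateau.
#'
#' @param x numeric vector.
#' @param v vertices `c(a, b, c, d)`.
#' @return membership values in `[0, 1]`.
#' @export
trapezoid_membership <- function(x, v) {
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  down <- if (is.infinite(d)) rep(1, length(x))
          else if (d > cc) (d - x) / (d - cc) else as.numeric(x <= cc)
  pmin(1, pmax(0, pmin(up, down)))
}

gaussian_membership <- function(x, mean, sd) exp(-0.5 * ((x - mean) / sd)^2)

#' Cadence (step-rate) memberships
#'
#' Maps a steps/min rate to graded memberships for the classes the step
#' counter can see: sedentary sitting (trapezoid), walking and running
#' (peak-normalized Gaussians). Memberships do not sum to 1.
#'
#' @param spm steps per minute (>= 0), vectorized.
#' @param cfg a [fuzzy_config()].
#' @return for scalar `spm` a named vector `SITTING`, `WALKING`, `RUNNING`;
#'   for vector input a matrix with those columns.
#' @export
step_membership <- function(spm, cfg = fuzzy_config()) {
  if (any(spm < 0)) har_stop("spm must be >= 0", "weakhar_value_error")
  m <- cbind(
    SITTING = trapezoid_membership(spm, cfg$sedentary_spm),
    WALKING = gaussian_membership(spm, cfg$walking_spm[["mean"]], cfg$walking_spm[["sd"]]),
    RUNNING = gaussian_membership(spm, cfg$running_spm[["mean"]], cfg$running_spm[["sd"]]))
  if (length(spm) == 1) m[1, ] else m
}

#' Ground-speed memberships
#'
#' Maps a GPS-estimated speed to trapezoidal memberships for all five
#' classes.
#'
#' @param v speed in m/s (>= 0), vectorized.
#' @param cfg a [fuzzy_config()].
#' @return for scalar `v` a named vector over the five activities; for
#'   vector input a matrix with those columns.
#' @export
speed_membership <- function(v, cfg = fuzzy_config()) {
  if (any(v < 0)) har_stop("speed must be >= 0", "weakhar_value_error")
  m <- vapply(HAR_ACTIVITIES,
              function(a) trapezoid_membership(v, cfg$speed[[a]]),
              numeric(length(v)))
  if (length(v) == 1) {
    m <- as.numeric(m); names(m) <- HAR_ACTIVITIES
    m
  } else m
}

#' Fuse cadence and GPS probabilities
#'
#' Accuracy-weighted average of the two information sources:
#' `(p_step + w_gps * p_gps) / (1 + w_gps)`. With `w_gps = 0` (no usable GPS)
#' the cadence probability passes through unchanged; when both sources agree
#' the fused value is their common value for any weight.
#'
#' @param p_step,p_gps probabilities in `[0, 1]` (vectorized).
#' @param w_gps GPS weight >= 0.
#' @return fused probability in `[0, 1]`.
#' @export
combine_probability <- function(p_step, p_gps, w_gps) {
  if (any(p_step < 0 | p_step > 1) || any(p_gps < 0 | p_gps > 1)) {
    har_stop("probabilities must lie in [0, 1]", "weakhar_value_error")
  }
  if (any(w_gps < 0)) har_stop("w_gps must be >= 0", "weakhar_value_error")
  (p_step + w_gps * p_gps) / (1 + w_gps)
}
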