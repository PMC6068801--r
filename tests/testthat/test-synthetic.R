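cfg <- sim_config()

test_that("schedule generation: empty, deterministic, tiling", {
  expect_equal(nrow(generate_schedule(cfg, 0, seed = 1)), 0)
  expect_error(generate_schedule(cfg, -5), class = "weakhar_value_error")

  a <- generate_schedule(cfg, 6 * 3600, seed = 9)
  b <- generate_schedule(cfg, 6 * 3600, seed = 9)
  expect_identical(a, b)

  expect_equal(a$start[1], 0)
  expect_equal(a$end[nrow(a)], 6 * 3600)
  expect_equal(a$start[-1], a$end[-nrow(a)])
  for (i in seq_len(nrow(a) - 1)) {  # last bout is truncated
    bounds <- cfg$duration_bounds[[a$activity[i]]]
    expect_gte(a$end[i] - a$start[i], bounds[1])
    expect_lte(a$end[i] - a$start[i], bounds[2])
  }
  expect_setequal(unique(generate_schedule(cfg, 4 * 3600, seed = 2,
                                           ensure_all = TRUE)$activity),
                  HAR_ACTIVITIES)
})

test_that("class time shares track the mixture weights over 200 h", {
  tot <- stats::setNames(numeric(5), HAR_ACTIVITIES)
  for (s in 1:20) {
    sch <- generate_schedule(cfg, 10 * 3600, seed = 100 + s)
    d <- tapply(sch$end - sch$start, sch$activity, sum)
    tot[names(d)] <- tot[names(d)] + d
  }
  shares <- tot / sum(tot)
  expect_true(all(abs(shares - cfg$mixture[names(shares)]) < 0.05))
})

test_that("trace structure: sample counts, cadence, GPS spacing, sitting silence", {
  sch <- data.frame(start = 0, end = 10, activity = "SITTING")
  tr <- synth_trace(sch, cfg, seed = 1)
  expect_equal(nrow(tr$accel), 300)  # 30 Hz x 10 s

  # empirical walking cadence at mean 100: Monte-Carlo over 10 seeds
  spm <- vapply(1:10, function(s) {
    sch <- data.frame(start = 0, end = 1800, activity = "WALKING")
    tr <- synth_trace(sch, cfg, seed = 200 + s, channels = "steps")
    length(tr$steps) / 30
  }, numeric(1))
  expect_gte(mean(spm), 95)
  expect_lte(mean(spm), 105)

  sch <- generate_schedule(cfg, 4 * 3600, seed = 3, ensure_all = TRUE)
  tr <- synth_trace(sch, cfg, seed = 3, channels = c("steps", "gps"))
  gaps <- diff(tr$gps$t)
  expect_true(all(gaps >= 60 & gaps <= 180))
  # no steps while sitting
  sit <- sch[sch$activity == "SITTING", ]
  for (i in seq_len(nrow(sit))) {
    expect_equal(sum(tr$steps >= sit$start[i] & tr$steps < sit$end[i]), 0)
  }
  # determinism of the full trace
  tr2 <- synth_trace(sch, cfg, seed = 3, channels = c("steps", "gps"))
  expect_identical(tr, tr2)
  # step stream unchanged by requesting the accelerometer as well
  tr3 <- synth_trace(sch, cfg, seed = 3)
  expect_identical(tr3$steps, tr$steps)
})

test_that("pure walking accel has its dominant PSD peak at the cadence bin", {
  sch <- data.frame(start = 0, end = 120, activity = "WALKING")
  tr <- synth_trace(sch, cfg, seed = 5)
  f <- extract_features_stream(tr$accel)
  target <- round(tr$bouts$cadence[1] / 60)
  dom <- f$f18
  share_near <- mean(abs(dom - target) <= 1)
  expect_gte(share_near, 0.9)
})

test_that("GPS degradation: identity, full dropout, binomial survival", {
  sch <- generate_schedule(cfg, 2 * 3600, seed = 4)
  gps <- synth_trace(sch, cfg, seed = 4, channels = "gps")$gps
  expect_identical(degrade_gps(gps, 0, 1, seed = 1), gps)
  expect_equal(nrow(degrade_gps(gps, 1, 1, seed = 1)), 0)

  big <- data.frame(t = 1:1000, lat = 0, lon = 0, accuracy = 10)
  surv <- nrow(degrade_gps(big, 0.5, 2, seed = 6))
  expect_gte(surv, stats::qbinom(0.005, 1000, 0.5))
  expect_lte(surv, stats::qbinom(0.995, 1000, 0.5))
  expect_equal(unique(degrade_gps(big, 0.5, 2, seed = 6)$accuracy), 20)
})

test_that("simulate_recording writes consistent, re-readable stream files", {
  dir <- tempfile("rec_")
  paths <- simulate_recording(dir, 3700, cfg, seed = 12, channels = c("steps", "gps"))
  truth <- read_label_log(paths$labels)
  expect_true(all(truth$activity %in% HAR_ACTIVITIES))
  steps <- read_steps(paths$steps)
  gps <- read_gps(paths$gps)
  expect_true(all(diff(steps) > 0))
  expect_true(all(gps$accuracy > 0))
})
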