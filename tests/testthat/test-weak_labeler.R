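test_that("spm windows count per minute and scale the trailing fragment", {
  steps <- seq(0.3, 59.7, length.out = 100)
  w <- compute_spm_windows(steps, 0, 60)
  expect_equal(nrow(w), 1)
  expect_equal(w$spm, 100)

  expect_equal(compute_spm_windows(numeric(0), 0, 60)$spm, 0)

  # 45-s trailing window with 75 steps scales to 100 spm
  steps <- seq(60.1, 104.9, length.out = 75)
  w <- compute_spm_windows(steps, 0, 105)
  expect_equal(nrow(w), 2)
  expect_equal(w$spm[2], 100)
  expect_equal(w$end[2], 105)

  # trailing fragment < 30 s is discarded
  w <- compute_spm_windows(numeric(0), 0, 85)
  expect_equal(nrow(w), 1)
  expect_error(compute_spm_windows(numeric(0), 0, 50), class = "weakhar_value_error")
})

test_that("window merging applies the strict 10-spm rule with weighted means", {
  win <- data.frame(start = 0:4 * 60, end = 1:5 * 60, spm = c(102, 98, 105, 0, 0))
  m <- merge_windows(win)
  expect_equal(nrow(m), 2)
  expect_equal(m$spm, c(305 / 3, 0))

  win <- data.frame(start = c(0, 60), end = c(60, 120), spm = c(100, 111))
  expect_equal(nrow(merge_windows(win)), 2)  # diff 11, not < 10
  win <- data.frame(start = c(0, 60), end = c(60, 120), spm = c(100, 109))
  expect_equal(nrow(merge_windows(win)), 1)

  single <- data.frame(start = 0, end = 60, spm = 42)
  expect_equal(merge_windows(single), single)
})

test_that("adjacent merged segments differ by >= 10 spm or are non-contiguous", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(5:30, 1)
      win <- data.frame(start = 0:(n - 1) * 60, end = 1:n * 60,
                        spm = sample(c(0, 0, 50, 95, 100, 105, 130, 170), n, TRUE))
      m <- merge_windows(win)
      # ordered, disjoint, covering the input exactly
      expect_equal(m$start[1], 0); expect_equal(m$end[nrow(m)], n * 60)
      if (nrow(m) > 1) {
        i <- seq_len(nrow(m) - 1)
        expect_equal(m$start[i + 1], m$end[i])
        # a break means the first window of the next segment was >= 10 spm
        # away from the previous segment's duration-weighted mean
        first_next <- win$spm[match(m$start[i + 1], win$start)]
        expect_true(all(abs(first_next - m$spm[i]) >= 10 - 1e-9))
      }
      # duration-weighted mean is conserved overall
      expect_equal(sum(m$spm * (m$end - m$start)), sum(win$spm * 60))
    }
  })
})

test_that("speed estimation matches the haversine oracle values", {
  a <- list(t = 0, lat = 0, lon = 0)
  expect_equal(estimate_speed(a, list(t = 60, lat = 0, lon = 0)), 0)
  v <- estimate_speed(a, list(t = 60, lat = 0.01, lon = 0))
  expect_equal(v, 18.5325, tolerance = 1e-4)
  v2 <- estimate_speed(a, list(t = 120, lat = 0.01, lon = 0))
  expect_equal(v2, v / 2)
  expect_error(estimate_speed(a, list(t = 0, lat = 1, lon = 1)),
               class = "weakhar_value_error")
})

test_that("segment speed is a time-weighted mean with accuracy weights", {
  cfg <- fuzzy_config()
  m_per_deg <- 6371000 * pi / 180
  # two pairs with speeds 1 and 3 m/s over equal 60-s gaps
  lat <- c(0, 60 * 1 / m_per_deg, 60 * 1 / m_per_deg + 60 * 3 / m_per_deg)
  fx <- data.frame(t = c(0, 60, 120), lat = lat, lon = 0, accuracy = c(5, 5, 5))
  sp <- segment_speed(0, 180, fx, cfg)
  expect_equal(sp$speed, 2, tolerance = 1e-6)
  expect_equal(sp$w_gps, 1)  # accuracy better than a0

  one_pair <- fx[1:2, ]; one_pair$accuracy <- c(20, 40)
  sp <- segment_speed(0, 180, one_pair, cfg)
  expect_equal(sp$w_gps, 10 / 40)

  expect_equal(segment_speed(0, 60, fx[1, , drop = FALSE], cfg),
               list(speed = NA_real_, w_gps = 0))
})

test_that("weak label assignment covers the canonical regimes", {
  cfg <- fuzzy_config()
  # treadmill: sustained walking cadence, no GPS
  lab <- assign_weak_label(100, NA, 0, cfg)
  expect_equal(lab$activity, "WALKING")
  expect_equal(lab$probability, 1.0)
  # ambiguous cadence
  expect_equal(assign_weak_label(50, NA, 0, cfg)$activity, HAR_MISSING)
  # spurious steps overridden by vehicle-grade speed
  expect_equal(assign_weak_label(0, 25, 1, cfg)$activity, "TRANSPORTATION")
  # GPS-only classes gated by w_min
  expect_equal(assign_weak_label(0, 6, 0.1, cfg)$activity, "SITTING")
  expect_equal(assign_weak_label(0, 6, 0.5, cfg)$activity, "CYCLING")
})

test_that("labeled segments never carry probability below theta", {
  cfg <- fuzzy_config()
  withr::with_seed(11, {
    for (i in 1:300) {
      spm <- stats::runif(1, 0, 200)
      speed <- if (stats::runif(1) < 0.3) NA else stats::runif(1, 0, 40)
      w <- stats::runif(1)
      lab <- assign_weak_label(spm, speed, w, cfg)
      if (lab$activity != HAR_MISSING) {
        expect_gte(lab$probability, cfg$theta)
        expect_true(lab$activity %in% HAR_ACTIVITIES)
      } else {
        expect_true(is.na(lab$probability))
      }
    }
  })
})

test_that("smoothing converts cycling next to transportation, and only that", {
  seg <- function(acts) data.frame(start = seq_along(acts) - 1, end = seq_along(acts),
                                   activity = acts, probability = 0.8)
  expect_equal(smooth_labels(seg(c("CYCLING", "TRANSPORTATION")))$activity,
               c("TRANSPORTATION", "TRANSPORTATION"))
  expect_equal(smooth_labels(seg(c("TRANSPORTATION", "CYCLING")))$activity,
               c("TRANSPORTATION", "TRANSPORTATION"))
  expect_equal(smooth_labels(seg(c("CYCLING", "WALKING")))$activity,
               c("CYCLING", "WALKING"))
  # cascades to a fixpoint through chains
  expect_equal(smooth_labels(seg(c("CYCLING", "CYCLING", "TRANSPORTATION")))$activity,
               rep("TRANSPORTATION", 3))
  # MISSING blocks adjacency
  expect_equal(smooth_labels(seg(c("CYCLING", "MISSING", "TRANSPORTATION")))$activity,
               c("CYCLING", "MISSING", "TRANSPORTATION"))

  withr::with_seed(8, {
    for (rep in 1:30) {
      acts <- sample(c(HAR_ACTIVITIES, HAR_MISSING), sample(2:15, 1), TRUE)
      out <- smooth_labels(seg(acts))$activity
      pairs <- paste(out[-length(out)], out[-1])
      expect_false(any(pairs %in% c("CYCLING TRANSPORTATION", "TRANSPORTATION CYCLING")))
    }
  })
})

test_that("quality report identities: perfect agreement and all-missing", {
  truth <- data.frame(start = c(0, 100), end = c(100, 200),
                      activity = c("WALKING", "SITTING"))
  weak_perfect <- cbind(truth, probability = 1)
  q <- label_quality_report(weak_perfect, truth)
  expect_equal(q$precision, 1)
  expect_equal(q$missing_rate, 0)

  weak_missing <- data.frame(start = 0, end = 200, activity = HAR_MISSING,
                             probability = NA_real_)
  q <- label_quality_report(weak_missing, truth)
  expect_true(is.na(q$precision))
  expect_equal(q$missing_rate, 1)
})
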