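test_that("window tiling: counts, short streams, and gaps", {
  mk <- function(t) data.frame(t = t, x = 0, y = 0, z = 1)
  idx <- segment_windows(mk((0:299) / 30))
  expect_equal(nrow(idx), 19)  # (300 - 30) / 15 + 1

  expect_equal(nrow(segment_windows(mk((0:26) / 30))), 0)

  # a 5-s gap breaks the tiling: no window straddles it
  t <- c((0:59) / 30, 5 + (0:59) / 30)
  idx <- segment_windows(mk(t))
  expect_equal(nrow(idx), 6)  # 3 per contiguous run
  starts <- t[idx[, "first"]]; ends <- t[idx[, "last"]]
  expect_true(all(ends - starts < 1 + 1e-9))
})

test_that("magnitude is the per-sample Euclidean norm", {
  w <- data.frame(x = rep(3, 30), y = rep(4, 30), z = 0)
  expect_equal(magnitude(w), rep(5, 30))
  expect_equal(magnitude(data.frame(x = 0, y = 0, z = 0)), 0)
  w2 <- w; w2$x <- -w2$x
  expect_equal(magnitude(w2), magnitude(w))
})

test_that("feature vector has 18 entries with degenerate-case conventions", {
  tt <- (0:29) / 30
  w <- data.frame(x = 1 + 0.1 * sin(2 * pi * 2 * tt), y = 0, z = 0)
  fv <- extract_features(w)
  expect_length(fv, 18)
  expect_named(fv, HAR_FEATURE_NAMES)
  expect_equal(unname(fv["psd_domfreq"]), 2)

  const <- data.frame(x = rep(0.5, 30), y = rep(-0.5, 30), z = rep(0.2, 30))
  fc <- extract_features(const)
  expect_equal(unname(fc[c("mag_var", "mag_range", "mag_skew", "mag_kurt",
                           "x_var", "x_range", "psd_peaks", "psd_domfreq")]),
               rep(0, 8))
  expect_equal(unname(fc["x_absmean"]), 0.5)
  expect_equal(unname(fc["y_absmean"]), 0.5)  # absolute value of the mean

  bad <- const; bad$x[3] <- NaN
  expect_error(extract_features(bad), class = "weakhar_integrity_error")
})

test_that("PSD features: flat series, single tone, tie toward lower frequency", {
  expect_equal(psd_features(rep(1, 30)), c(psd_peaks = 0, psd_domfreq = 0))

  tt <- (0:29) / 30
  expect_equal(psd_features(1 + sin(2 * pi * 5 * tt)),
               c(psd_peaks = 1, psd_domfreq = 5))

  two <- 1 + sin(2 * pi * 3 * tt) + sin(2 * pi * 7 * tt)
  out <- psd_features(two)
  expect_equal(unname(out["psd_peaks"]), 2)
  expect_equal(unname(out["psd_domfreq"]), 3)  # exact tie -> lower frequency
})

test_that("feature invariances: sign flips, axis permutation, constant shifts", {
  withr::with_seed(14, {
    tt <- (0:29) / 30
    w <- data.frame(x = stats::rnorm(30, 0.3, 0.2),
                    y = stats::rnorm(30, -0.1, 0.3),
                    z = 1 + 0.4 * sin(2 * pi * 2 * tt) + stats::rnorm(30, 0, 0.05))
    fv <- extract_features(w)
    mag_idx <- c(1:7, 17, 18)

    for (ax in c("x", "y", "z")) {
      wf <- w; wf[[ax]] <- -wf[[ax]]
      expect_equal(extract_features(wf), fv)  # full sign invariance
    }
    perm <- data.frame(x = w$z, y = w$x, z = w$y)
    expect_equal(extract_features(perm)[mag_idx], fv[mag_idx])

    shifted <- w + 0.7  # adds constant to every axis
    fs <- extract_features(shifted)
    var_range_idx <- c("x_var", "x_range", "y_var", "y_range", "z_var", "z_range")
    expect_equal(fs[var_range_idx], fv[var_range_idx])
  })
})

test_that("stream extraction matches the single-window path exactly", {
  withr::with_seed(2, {
    n <- 300
    accel <- data.frame(t = (0:(n - 1)) / 30,
                        x = stats::rnorm(n, 0, 0.2),
                        y = stats::rnorm(n, 0, 0.2),
                        z = 1 + 0.3 * sin(2 * pi * 1.7 * (0:(n - 1)) / 30) +
                          stats::rnorm(n, 0, 0.05))
    fs <- extract_features_stream(accel)
    expect_equal(nrow(fs), 19)
    idx <- segment_windows(accel)
    for (i in c(1, 7, 19)) {
      single <- extract_features(accel[idx[i, "first"]:idx[i, "last"], ])
      expect_equal(unname(unlist(fs[i, paste0("f", 1:18)])), unname(single))
    }
  })
})
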