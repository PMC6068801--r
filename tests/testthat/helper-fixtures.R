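# Fixtures are built in code; nothing binary ships with the package.

# idealized, well-separated 18-d class clusters (weak == manual unless
# scrambled); used for the "separable" classifier checks
make_separable_rows <- function(n_per = 60, sep = 6, seed = 1,
                                scramble_manual = FALSE) {
  withr::with_seed(seed, {
    cls <- rep(HAR_ACTIVITIES, each = n_per)
    ki <- match(cls, HAR_ACTIVITIES)
    mu <- sapply(1:18, function(j) sep * (ki == (j %% 5) + 1))
    x <- mu + matrix(stats::rnorm(length(cls) * 18), ncol = 18)
    df <- data.frame(
      label = if (scramble_manual) sample(cls) else cls,
      weak_label = cls,
      probability = stats::runif(length(cls), 0.5, 1),
      window_start = seq_along(cls))
    cbind(df, stats::setNames(as.data.frame(x), paste0("f", 1:18)))
  })
}

# a sustained-activity simulation world with outdoor-grade GPS everywhere:
# the regime in which the heuristic is expected to be near-perfect
sustained_config <- function() {
  sim_config(
    duration_bounds = list(SITTING = c(900, 2700), WALKING = c(900, 2700),
                           RUNNING = c(900, 2700), CYCLING = c(900, 2700),
                           TRANSPORTATION = c(900, 2700)),
    gps_accuracy = list(indoor = c(mean = 8, sd = 3), outdoor = c(mean = 8, sd = 3)))
}

# full-chain synthetic dataset (features + weak + manual labels, balanced,
# subsampled per class); cached because several tests share it
.weakhar_cache <- new.env(parent = emptyenv())
make_trace_rows <- function(hours = 6, seed = 21, n_per = 120) {
  key <- sprintf("rows_%d_%d_%d", hours, seed, n_per)
  if (!is.null(.weakhar_cache[[key]])) return(.weakhar_cache[[key]])
  cfg <- sim_config()
  sch <- generate_schedule(cfg, hours * 3600, seed = seed, ensure_all = TRUE)
  tr <- synth_trace(sch, cfg, seed = seed)
  weak <- weak_label_trace(tr$steps, tr$gps, 0, hours * 3600)
  feats <- extract_features_stream(tr$accel)
  rows <- align_rows(feats, weak, sch)
  rows <- rows[rows$weak_label != HAR_MISSING, , drop = FALSE]
  bal <- balance_rows(rows)
  sub <- withr::with_seed(seed + 7, {
    do.call(rbind, lapply(split(bal, bal$weak_label), function(g) {
      g[sample(nrow(g), min(n_per, nrow(g))), , drop = FALSE]
    }))
  })
  rownames(sub) <- NULL
  .weakhar_cache[[key]] <- sub
  sub
}

write_temp_csv <- function(text) {
  f <- tempfile(fileext = ".csv")
  writeLines(text, f)
  f
}
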