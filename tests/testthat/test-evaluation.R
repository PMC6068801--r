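test_that("macro metrics from first principles", {
  ident <- diag(c(5, 3, 7))
  m <- macro_metrics(ident)
  expect_equal(c(m$precision, m$recall, m$f_score), c(1, 1, 1))

  cm <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  m <- macro_metrics(cm)
  expect_equal(m$precision, (8 / 11 + 7 / 9) / 2, tolerance = 1e-12)
  expect_equal(m$recall, (8 / 10 + 7 / 10) / 2, tolerance = 1e-12)

  # permutation invariance
  withr::with_seed(4, {
    cm5 <- matrix(stats::rpois(25, 6), 5)
    p <- sample(5)
    m1 <- macro_metrics(cm5)
    m2 <- macro_metrics(cm5[p, p])
    expect_equal(m1$f_score, m2$f_score)
  })

  expect_error(macro_metrics(matrix(0, 3, 3)), class = "weakhar_value_error")
  expect_error(macro_metrics(matrix(1, 2, 3)), class = "weakhar_value_error")
})

test_that("run_cv arithmetic, determinism and report invariants", {
  rows <- make_separable_rows(n_per = 20, seed = 2)  # n = 100
  sp <- model_suite()$nearest_centroid
  r <- run_cv(rows, sp, folds = 10, seed = 5)
  # each of the 10 folds tests 10 rows; pooled confusion holds all of them
  expect_equal(sum(r$confusion), 100)
  expect_true(all(abs(rowSums(r$confusion_norm) - 1) < 1e-9 |
                    rowSums(r$confusion) == 0))
  expect_true(all(r$fold_scores$f_score >= 0 & r$fold_scores$f_score <= 1))

  r2 <- run_cv(rows, sp, folds = 10, seed = 5)
  expect_identical(r, r2)
})

test_that("training sees only weak labels; scoring uses only manual labels", {
  # weak labels carry the true cluster structure; manual labels are scrambled.
  # If fitting used the manual labels the model could not learn the clusters;
  # if scoring used the weak labels the f-score would be ~1. Both must fail.
  scrambled <- make_separable_rows(n_per = 24, seed = 9, scramble_manual = TRUE)
  sp <- model_suite()$nearest_centroid
  r_scrambled <- run_cv(scrambled, sp, folds = 5, seed = 1)
  expect_lt(r_scrambled$f_score, 0.45)   # scored against scrambled manual labels

  clean <- make_separable_rows(n_per = 24, seed = 9)
  r_clean <- run_cv(clean, sp, folds = 5, seed = 1)
  expect_gt(r_clean$f_score, 0.95)       # same weak labels, honest manual labels
})

test_that("label-noise injection flips exactly the requested rows", {
  rows <- make_separable_rows(n_per = 200, seed = 1)  # n = 1000
  expect_identical(inject_label_noise(rows, 0, seed = 3), rows)

  noisy <- inject_label_noise(rows, 0.15, seed = 3)
  expect_equal(sum(noisy$weak_label != rows$weak_label), 150)
  expect_identical(noisy$label, rows$label)  # manual labels untouched

  all_flipped <- inject_label_noise(rows, 1, seed = 3)
  expect_true(all(all_flipped$weak_label != rows$weak_label))
  expect_true(all(all_flipped$weak_label %in% HAR_ACTIVITIES))

  paired <- inject_label_noise(rows, 0.1, seed = 3, mode = "pair")
  moved <- which(paired$weak_label != rows$weak_label)
  expect_true(all(rows$weak_label[moved] %in% c("CYCLING", "TRANSPORTATION")))
  expect_true(all(paired$weak_label[moved] %in% c("CYCLING", "TRANSPORTATION")))
})

test_that("noise experiment: baseline row matches run_cv; noise never helps", {
  rows <- make_separable_rows(n_per = 30, sep = 2.5, seed = 12)
  sp <- model_suite()$nearest_centroid
  tab <- noise_experiment(rows, list(sp), rates = c(0, 0.4), seed = 2, folds = 4)
  base <- run_cv(rows, sp, folds = 4, seed = 2)
  expect_equal(tab$f_score[tab$rate == 0], base$f_score)
  expect_error(noise_experiment(rows, list(sp), rates = c(0.1, 0.2)),
               class = "weakhar_value_error")

  # f(0.4) <= f(0) on average over seeds
  d <- vapply(1:10, function(s) {
    rr <- make_separable_rows(n_per = 30, sep = 2.5, seed = 20 + s)
    f0 <- run_cv(rr, sp, folds = 3, seed = s)$f_score
    f4 <- run_cv(inject_label_noise(rr, 0.4, seed = 50 + s), sp,
                 folds = 3, seed = s)$f_score
    f0 - f4
  }, numeric(1))
  expect_gt(mean(d), 0)
})
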