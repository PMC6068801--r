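#' Macro precision, recall and f-score from a confusion matrix
#'
#' Rows are true classes, columns predicted classes (counts). Per-class
#' precision comes from columns, recall from rows, f-score is their harmonic
#' mean; macro scores are unweighted means over classes. Conventions: a
#' class never predicted has precision 0; a class with no true samples has
#' recall 0; f is 0 when precision + recall is 0.
#'
#' @param confusion square non-negative count matrix with a positive total.
#' @return list with `precision`, `recall`, `f_score` (macro scalars) and
#'   `per_class` (data.frame).
#' @export
macro_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) {
    har_stop("confusion must be a square non-negative matrix", "weakhar_value_error")
  }
  if (sum(cm) <= 0) har_stop("confusion matrix has zero total", "weakhar_value_error")
  tp <- diag(cm)
  pred <- colSums(cm); true <- rowSums(cm)
  precision <- ifelse(pred > 0, tp / pred, 0)
  recall <- ifelse(true > 0, tp / true, 0)
  f <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  list(precision = mean(precision), recall = mean(recall), f_score = mean(f),
       per_class = data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                              precision = precision, recall = recall, f_score = f))
}

#' Weak-label-train / true-label-test cross validation
#'
#' The validation routine for training sets whose labels were generated
#' automatically: `folds` times, the rows are shuffled and 10% held out; the
#' model is fitted on the *weak* labels of the remaining 90% (the manual
#' labels are removed before fitting), and predictions on the held-out rows
#' are scored against their *manual* labels. Features are standardized with
#' statistics fitted on the training split only.
#'
#' @param rows balanced data.frame from [balance_rows()] (columns `label`,
#'   `weak_label`, `f1..fn`).
#' @param spec a [model_spec()].
#' @param folds number of shuffle-and-holdout repetitions.
#' @param test_fraction held-out fraction per repetition.
#' @param seed integer seed; the whole report is reproducible from it.
#' @return object of class `har_cv_report`: mean macro `precision`,
#'   `recall`, `f_score`, `fold_scores`, pooled `confusion` (counts) and
#'   `confusion_norm` (rows sum to 1), `excluded` (per-fold classes missing
#'   from a training split, if any), `seed`.
#' @export
run_cv <- function(rows, spec, folds = 10, test_fraction = 0.10, seed = 1) {
  fcols <- grep("^f[0-9]+$", names(rows), value = TRUE)
  n <- nrow(rows)
  n_test <- max(1L, round(test_fraction * n))
  classes <- HAR_ACTIVITIES
  pooled <- matrix(0, 5, 5, dimnames = list(classes, classes))
  fold_scores <- data.frame(fold = integer(0), precision = numeric(0),
                            recall = numeric(0), f_score = numeric(0))
  excluded <- list()
  for (i in seq_len(folds)) {
    fold_seed <- seed * 1000L + i
    perm <- withr::with_seed(fold_seed, sample.int(n))
    test_idx <- perm[seq_len(n_test)]
    train_idx <- perm[-seq_len(n_test)]
    train <- rows[train_idx, , drop = FALSE]
    train$label <- NULL                      # manual labels never reach fitting
    x_tr <- as.matrix(train[fcols])
    mu <- colMeans(x_tr)
    sdv <- apply(x_tr, 2, stats::sd); sdv[sdv == 0 | is.na(sdv)] <- 1
    scale_x <- function(m) sweep(sweep(m, 2, mu), 2, sdv, `/`)
    missing_cls <- setdiff(classes, unique(train$weak_label))
    if (length(missing_cls)) {
      warning(sprintf("fold %d: class(es) absent from training split: %s",
                      i, paste(missing_cls, collapse = ", ")))
      excluded[[length(excluded) + 1]] <- data.frame(fold = i, class = missing_cls)
    }
    model <- har_fit(spec, scale_x(x_tr), train$weak_label, seed = fold_seed + 500L)
    pred <- har_predict(model, scale_x(as.matrix(rows[test_idx, fcols])))
    truth <- rows$label[test_idx]
    cm <- table(factor(truth, classes), factor(pred, classes))
    pooled <- pooled + unclass(cm)
    ms <- macro_metrics(cm + 0)  # fold-level scores
    fold_scores <- rbind(fold_scores,
                         data.frame(fold = i, precision = ms$precision,
                                    recall = ms$recall, f_score = ms$f_score))
  }
  norm <- pooled / pmax(rowSums(pooled), 1)
  structure(list(model = spec$label, family = spec$family,
                 precision = mean(fold_scores$precision),
                 recall = mean(fold_scores$recall),
                 f_score = mean(fold_scores$f_score),
                 fold_scores = fold_scores,
                 confusion = pooled, confusion_norm = norm,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
                 seed = seed),
            class = "har_cv_report")
}

#' @export
print.har_cv_report <- function(x, ...) {
  cat(sprintf("%s: macro precision %.4f, recall %.4f, f-score %.4f (%d folds)\n",
              x$model, x$precision, x$recall, x$f_score, nrow(x$fold_scores)))
  invisible(x)
}

#' Inject label noise into the weak labels
#'
#' Flips exactly `round(rate * n)` weak labels, chosen without replacement;
#' manual labels are untouched. `mode = "uniform"` draws a replacement
#' uniformly from the other four activities (symmetric noise);
#' `mode = "pair"` swaps labels only within a stated confusable class pair
#' (the heuristic's real noise concentrates on cycling vs transportation),
#' flipping up to the requested count among rows of those two classes.
#'
#' @param rows labeled data.frame.
#' @param rate noise rate in `[0, 1]`.
#' @param seed integer seed.
#' @param mode `"uniform"` or `"pair"`.
#' @param pair the two classes swapped in pair mode.
#' @return the data.frame with noisy `weak_label`.
#' @export
inject_label_noise <- function(rows, rate, seed = 1, mode = c("uniform", "pair"),
                               pair = c("CYCLING", "TRANSPORTATION")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate > 1) har_stop("rate must be in [0, 1]", "weakhar_value_error")
  n <- nrow(rows)
  n_flip <- round(rate * n)
  if (n_flip == 0) return(rows)
  withr::with_seed(seed, {
    if (mode == "uniform") {
      idx <- sample.int(n, n_flip)
      for (i in idx) {
        others <- setdiff(HAR_ACTIVITIES, rows$weak_label[i])
        rows$weak_label[i] <- sample(others, 1)
      }
    } else {
      eligible <- which(rows$weak_label %in% pair)
      idx <- sample(eligible, min(n_flip, length(eligible)))
      rows$weak_label[idx] <- ifelse(rows$weak_label[idx] == pair[1], pair[2], pair[1])
    }
  })
  rows
}

#' Label-noise robustness experiment
#'
#' Runs [run_cv()] for every model at every noise rate and reports the
#' f-score degradation relative to the noise-free run,
#' `delta_f = f(0) - f(rate)`.
#'
#' @param rows balanced labeled data.frame.
#' @param specs list of [model_spec()] objects.
#' @param rates noise rates; must include 0.
#' @param seed integer seed.
#' @param folds folds per [run_cv()].
#' @param mode,pair passed to [inject_label_noise()].
#' @return data.frame with columns `model`, `rate`, `f_score`, `delta_f`.
#' @export
noise_experiment <- function(rows, specs, rates, seed = 1, folds = 10,
                             mode = "uniform", pair = c("CYCLING", "TRANSPORTATION")) {
  if (!any(rates == 0)) har_stop("rates must include 0", "weakhar_value_error")
  out <- list()
  for (s in seq_along(specs)) {
    f0 <- NA_real_
    for (r in sort(rates)) {
      noisy <- inject_label_noise(rows, r, seed = seed + round(1000 * r), mode = mode, pair = pair)
      rep <- run_cv(noisy, specs[[s]], folds = folds, seed = seed)
      if (r == 0) f0 <- rep$f_score
      out[[length(out) + 1]] <- data.frame(model = specs[[s]]$label, rate = r,
                                           f_score = rep$f_score,
                                           delta_f = f0 - rep$f_score)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
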