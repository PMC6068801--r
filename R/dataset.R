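#' Align feature windows with weak and manual labels
#'
#' A window adopts a label (weak or manual) only when its `[start, end)`
#' interval is fully contained in a single segment of that labeling; windows
#' straddling a weak-segment boundary get `MISSING`, and windows without a
#' manual label are dropped — the experimental dataset is restricted to the
#' manually annotated portions of the recording.
#'
#' @param features data.frame from [extract_features_stream()].
#' @param weak data.frame of weak-label segments (`start`, `end`,
#'   `activity`, `probability`).
#' @param truth data.frame of ground-truth segments (`start`, `end`,
#'   `activity`).
#' @return data.frame with columns `label`, `weak_label`, `probability`,
#'   `window_start`, `f1` .. `f18`.
#' @export
align_rows <- function(features, weak, truth) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  lookup <- function(segs, s, e) {
    # index of the segment fully containing [s, e), or NA
    idx <- findInterval(s, segs$start)
    ok <- idx >= 1 & idx <= nrow(segs)
    idx[!ok] <- NA_integer_
    contained <- !is.na(idx) & s >= segs$start[pmax(idx, 1)] & e <= segs$end[pmax(idx, 1)]
    idx[!contained] <- NA_integer_
    idx
  }
  ti <- lookup(truth, features$start, features$end)
  keep <- !is.na(ti)
  f <- features[keep, , drop = FALSE]
  ti <- ti[keep]
  wi <- lookup(weak, f$start, f$end)
  weak_label <- rep(HAR_MISSING, nrow(f))
  probability <- rep(NA_real_, nrow(f))
  has_w <- !is.na(wi)
  weak_label[has_w] <- weak$activity[wi[has_w]]
  probability[has_w] <- weak$probability[wi[has_w]]
  probability[weak_label == HAR_MISSING] <- NA_real_
  out <- data.frame(label = truth$activity[ti], weak_label = weak_label,
                    probability = probability, window_start = f$start,
                    stringsAsFactors = FALSE)
  out <- cbind(out, f[fcols])
  rownames(out) <- NULL
  out
}

#' Balanced per-class sample counts
#'
#' Quality-aware undersampling cap: with `n_min` the smallest class
#' cardinality, each class retains `min(|C_i|, floor(cap_factor * n_min))`
#' samples — up to 30% more than the minimum class at the default cap of
#' 1.3. `cap_factor = 1` is classic undersampling.
#'
#' @param counts named integer vector of class cardinalities.
#' @param cap_factor cap multiplier (default 1.3).
#' @return named integer vector of retained counts.
#' @export
balance_counts <- function(counts, cap_factor = 1.3) {
  if (!length(counts) || any(counts < 0)) {
    har_stop("counts must be a non-empty non-negative vector", "weakhar_value_error")
  }
  n_min <- min(counts)
  pmin(counts, floor(cap_factor * n_min))
}

#' Balance a labeled dataset by weak-label quality
#'
#' Groups rows by *weak* label (the only label available in deployment;
#' manual labels ride along solely for scoring), sorts each group by the
#' heuristic's probability (descending; ties by earlier `window_start`), and
#' keeps the top `min(|C_i|, floor(cap_factor * n_min))` rows per class — so
#' the samples discarded from majority classes are those the heuristic
#' trusts least.
#'
#' @param rows data.frame from [align_rows()]; every row must carry a
#'   non-missing weak label and a probability.
#' @param cap_factor cap multiplier (default 1.3).
#' @return the balanced data.frame (ordered by `window_start`).
#' @export
balance_rows <- function(rows, cap_factor = 1.3) {
  if (any(rows$weak_label == HAR_MISSING) || any(is.na(rows$probability))) {
    har_stop("balance requires rows with weak labels and probabilities; drop MISSING rows first",
             "weakhar_value_error")
  }
  absent <- setdiff(HAR_ACTIVITIES, unique(rows$weak_label))
  if (length(absent)) {
    har_stop(sprintf("cannot balance: class(es) with no weak-labeled samples: %s",
                     paste(absent, collapse = ", ")),
             "weakhar_balance_error")
  }
  counts <- table(rows$weak_label)
  n_i <- balance_counts(as.integer(counts), cap_factor)
  names(n_i) <- names(counts)
  kept <- lapply(names(n_i), function(cl) {
    g <- rows[rows$weak_label == cl, , drop = FALSE]
    g <- g[order(-g$probability, g$window_start), , drop = FALSE]
    g[seq_len(n_i[[cl]]), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  out <- out[order(out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
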