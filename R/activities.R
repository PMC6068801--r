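#' Activity taxonomy
#'
#' The five target activity classes, in fixed priority order. The order is a
#' contract: argmax ties in [assign_weak_label()] and vote ties in the
#' classifiers are broken toward the earlier class, and confusion matrices
#' use this row/column ordering.
#'
#' @format Character vector of length 5.
#' @export
HAR_ACTIVITIES <- c("SITTING", "WALKING", "RUNNING", "CYCLING", "TRANSPORTATION")

#' Sentinel emitted when no activity reaches the decision threshold
#' @export
HAR_MISSING <- "MISSING"

# internal: stop() with a classed condition so callers/tests can distinguish
# format errors (bad file shape) from integrity errors (invariant violation).
har_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "weakhar_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_activity <- function(x) {
  bad <- setdiff(unique(x), HAR_ACTIVITIES)
  if (length(bad)) {
    har_stop(sprintf("unknown activity label(s): %s", paste(bad, collapse = ", ")),
             "weakhar_value_error")
  }
  invisible(x)
}

assert_no_nan <- function(x, what) {
  if (any(!is.finite(x))) {
    har_stop(sprintf("non-finite value (NaN/NA/Inf) in %s", what),
             "weakhar_integrity_error")
  }
  invisible(x)
}

#' Intersection length of two sets of half-open intervals
#'
#' Utility used by the label-quality report and the alignment step. Computes
#' the total overlap duration between one interval and a table of intervals.
#'
#' @param start,end scalar interval bounds, `[start, end)`.
#' @param starts,ends vectors of interval bounds.
#' @return numeric vector of pairwise overlap durations.
#' @keywords internal
interval_overlap <- function(start, end, starts, ends) {
  pmax(0, pmin(end, ends) - pmax(start, starts))
}
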