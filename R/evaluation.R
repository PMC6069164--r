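# Sequence-level confusion-matrix evaluation (fall = positive class).

#' Score detector output against sequence labels
#'
#' Sequence-level scoring: a sequence counts as detected-positive iff at
#' least one confirmed fall event occurs in it.  Counts partition the
#' sequences exactly.
#'
#' @param events_list list of `detection_events` (one per sequence), named or
#'   in the same order as `labels`.
#' @param labels logical vector (or data frame with an `is_fall` column):
#'   ground truth per sequence, `TRUE` for a fall sequence.
#' @return a `confusion_counts` list with fields `tp`, `fn`, `tn`, `fp`.
#' @export
score_sequences <- function(events_list, labels) {
  if (is.data.frame(labels)) labels <- labels$is_fall
  labels <- as.logical(labels)
  if (length(events_list) != length(labels)) {
    stop("events and labels must cover the same sequences", call. = FALSE)
  }
  if (!is.null(names(events_list)) && !is.null(names(labels)) &&
      !identical(names(events_list), names(labels))) {
    stop("sequence names of events and labels disagree", call. = FALSE)
  }
  detected <- vapply(events_list, function(e) {
    any(e$kind == "confirmed_fall")
  }, logical(1))
  counts <- list(tp = sum(detected & labels), fn = sum(!detected & labels),
                 tn = sum(!detected & !labels), fp = sum(detected & !labels))
  structure(lapply(counts, as.integer), class = "confusion_counts")
}

#' Confusion counts
#'
#' @param tp,fn,tn,fp non-negative integers; falls are the positive class,
#'   so `tp + fn` is the number of fall sequences and `tn + fp` the number of
#'   non-fall sequences.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  out <- as.list(as.integer(v))
  names(out) <- names(v)
  structure(out, class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and precision `tp/(tp+fp)`, reported as percentages rounded
#' to 2 decimals.  A metric whose denominator is zero is reported as `NA`
#' (unavailable), never as 0.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `fn`, `tn`,
#'   `fp`).
#' @return a `fall_metrics` list with fields `accuracy`, `sensitivity`,
#'   `specificity`, `precision` (percent) and `counts`.
#' @examples
#' metrics(confusion_counts(tp = 29, fn = 1, tn = 33, fp = 7))
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  total <- tp + fn + tn + fp
  if (total <= 0) stop("no sequences to score", call. = FALSE)
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2)
                            else NA_real_
  structure(list(
    accuracy = pct(tp + tn, total),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp),
    counts = counts), class = "fall_metrics")
}

#' @export
print.fall_metrics <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<fall_metrics> tp=%d fn=%d tn=%d fp=%d (n=%d)\n",
              c0$tp, c0$fn, c0$tn, c0$fp, c0$tp + c0$fn + c0$tn + c0$fp))
  for (m in c("accuracy", "sensitivity", "specificity", "precision")) {
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "unavailable" else sprintf("%.2f%%",
                                                              x[[m]])))
  }
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fn=%d tn=%d fp=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Run the standard suite end to end
#'
#' Generates the [standard_suite()] scenarios, simulates each, runs the
#' detector and scores the outcome.
#'
#' @param seed integer seed for the suite.
#' @param config an [fs_config()].
#' @return list with `metrics` (a `fall_metrics`), `counts`, `events`
#'   (per-sequence event tables) and `scenarios`.
#' @export
run_standard_suite <- function(seed, config = fs_config()) {
  config <- as_fs_config(config)
  scen <- standard_suite(seed)
  events <- lapply(scen, function(s) {
    run_detector(simulate_motion(s$script)$stream, config)
  })
  names(events) <- vapply(scen, `[[`, character(1), "id")
  labels <- vapply(scen, `[[`, logical(1), "is_fall")
  names(labels) <- names(events)
  counts <- score_sequences(events, labels)
  list(metrics = metrics(counts), counts = counts, events = events,
       scenarios = scen)
}
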