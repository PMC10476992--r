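# Tolerance-band prediction accuracy and total-duration prediction.

#' Tolerance-band prediction accuracy
#'
#' The fraction of cases whose prediction falls within `T` seconds of the
#' true duration: `acc = (1/n) * sum_p 1[|predicted_p - actual_p| <= T]`.
#' The boundary is inclusive.
#'
#' @param predicted,actual Equal-length, non-empty numeric vectors, seconds.
#' @param T Tolerance threshold, seconds, >= 0.
#' @return Accuracy in `[0, 1]`.
#' @export
tolerance_accuracy <- function(predicted, actual, T) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  if (length(T) != 1 || is.na(T) || T < 0) {
    stop("T must be a single non-negative number", call. = FALSE)
  }
  mean(abs(predicted - actual) <= T)
}

#' Accuracy over a grid of tolerance thresholds
#'
#' One [tolerance_accuracy()] value per threshold; accuracy is
#' non-decreasing in the threshold since the indicator set only grows.
#'
#' @inheritParams tolerance_accuracy
#' @param thresholds Numeric vector of thresholds, seconds. The default grid
#'   spans 30 s to 105 s in 15 s steps.
#' @return An `accuracy_report`: data frame with columns `threshold_s` and
#'   `accuracy`, attribute `n` (evaluation count).
#' @export
accuracy_table <- function(predicted, actual,
                           thresholds = c(30, 45, 60, 75, 90, 105)) {
  acc <- vapply(thresholds, function(T) tolerance_accuracy(predicted, actual, T),
                numeric(1))
  out <- data.frame(threshold_s = thresholds, accuracy = acc)
  attr(out, "n") <- length(predicted)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Write an accuracy report (or a named list of them) as JSON
#'
#' Each report is serialized as `{ "n": ..., "accuracy": {"30": ..., ...} }`,
#' keyed by threshold.
#'
#' @param report An `accuracy_report`, or a (nested) named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_json <- function(report, path) {
  to_list <- function(r) {
    if (inherits(r, "accuracy_report")) {
      list(n = attr(r, "n"),
           accuracy = stats::setNames(as.list(r$accuracy),
                                      as.character(r$threshold_s)))
    } else {
      lapply(r, to_list)
    }
  }
  jsonlite::write_json(to_list(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Predicted total treatment duration
#'
#' PT and TT are predicted independently; the overall duration for a patient
#' is their sum, floored at a configurable minimum (a degenerate guard for
#' models extrapolating below plausible service times).
#'
#' @param pt_model,tt_model Fitted predictors (see [train_predictor()]).
#' @param newdata Feature data for prediction.
#' @param floor_s Minimum returned duration, seconds (default 120).
#' @return Numeric vector of total durations, seconds.
#' @export
predict_total_duration <- function(pt_model, tt_model, newdata,
                                   floor_s = 120) {
  if (!inherits(pt_model, "fitted_predictor") ||
      !inherits(tt_model, "fitted_predictor")) {
    stop("pt_model and tt_model must be fitted predictors", call. = FALSE)
  }
  total <- predict(pt_model, newdata) + predict(tt_model, newdata)
  n_clamped <- sum(total < floor_s)
  if (n_clamped > 0 && isTRUE(getOption("linacsched.verbose", FALSE))) {
    message("[predict] ", n_clamped, " total duration(s) below ", floor_s,
            " s clamped to the floor")
  }
  pmax(total, floor_s)
}
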